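#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties: `rho` is the Pearson
#' correlation of the rank vectors. The two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; for small samples (`n < 10`) an exact permutation
#' p-value can be requested instead. Pairs with missing values are
#' removed first (pairwise-complete).
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact If `TRUE` (only for `n < 10`), compute the p-value by
#'   full enumeration of rank permutations. Default `FALSE`.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "hetpet_input_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("Need at least 3 complete pairs.", class = "hetpet_input_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Correlation undefined for a constant vector.",
          class = "hetpet_degenerate")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n >= 10) {
      abort("Exact permutation p-value only supported for n < 10.",
            class = "hetpet_input_error")
    }
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- if (n > 2) 2 * stats::pt(Inf, n - 2, lower.tail = FALSE) else 1
      p <- max(p, .Machine$double.xmin)
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    }
  }
  tibble(rho = rho, p_value = p, n = n)
}

# all permutations of 1..n as a (n! x n) matrix; n is small (< 10)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Genomic x PET Spearman correlation grid
#'
#' Computes the Spearman correlation of each genomic feature (by
#' default MATH and GlycoS) with each PET feature (by default the six
#' metabolic features) over the patients present in both tables.
#' Missing values are handled by pairwise deletion per cell, and each
#' cell reports its own `n`.
#'
#' @param genomic,pet Data frames keyed by `patient_id` containing the
#'   respective feature columns.
#' @param genomic_features,pet_features Character vectors of column
#'   names to correlate.
#' @param patient_col Key column name, default `"patient_id"`.
#' @return A tibble of class `correlation_grid`: `feature_a`
#'   (genomic), `feature_b` (PET), `n`, `rho`, `p_value`.
#' @export
correlation_matrix <- function(genomic, pet,
                               genomic_features = c("math", "glycos"),
                               pet_features = c("suv_max", "suv_peak",
                                                "mtv_ml", "tlg",
                                                "entropy_bits", "cov"),
                               patient_col = "patient_id") {
  genomic <- as_tibble(genomic)
  pet <- as_tibble(pet)
  missing <- c(setdiff(genomic_features, names(genomic)),
               setdiff(pet_features, names(pet)))
  if (length(missing) > 0) {
    abort(paste0("Feature column(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "hetpet_input_error")
  }
  shared <- intersect(genomic[[patient_col]], pet[[patient_col]])
  if (length(shared) == 0) {
    abort("No patients shared between the genomic and PET tables.",
          class = "hetpet_patient_mismatch")
  }
  gi <- match(shared, genomic[[patient_col]])
  pi <- match(shared, pet[[patient_col]])
  grid <- tidyr::expand_grid(feature_a = genomic_features,
                             feature_b = pet_features)
  out <- purrr::pmap_dfr(grid, function(feature_a, feature_b) {
    res <- spearman_test(genomic[[feature_a]][gi], pet[[feature_b]][pi])
    tibble(feature_a = feature_a, feature_b = feature_b,
           n = res$n, rho = res$rho, p_value = res$p_value)
  })
  structure(out, class = c("correlation_grid", class(tibble())))
}
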