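#' Optimized survival cutoff by most-significant log-rank split
#'
#' Scans all candidate thresholds of a continuous feature (midpoints
#' between consecutive distinct sorted values) and returns the one whose
#' two-group split (value > cutoff = "high") maximizes the log-rank
#' chi-square, subject to both groups holding at least `min_group_frac`
#' of the cohort. This is the "optimized cutoff" stratification popular
#' in biomarker studies (e.g. Cutoff Finder).
#'
#' The reported p-value is the naive minimum log-rank p and is
#' optimistically biased by the maximal selection: the maximum of many
#' correlated chi-square statistics is not chi-square distributed. The
#' full scan is returned so users can apply maximally-selected-statistic
#' corrections; the result carries a `multiplicity_note` and the print
#' method displays it prominently.
#'
#' @param values Numeric feature vector, one per patient.
#' @inheritParams km_estimate
#' @param min_group_frac Minimum fraction of the cohort in each group;
#'   default 0.10.
#' @param feature_name Label used in output and plots.
#' @return An object of class `cutoff_result`: list with `feature_name`,
#'   `cutoff`, `chi_square`, `p_value`, `n_low`, `n_high`, `scan`
#'   (tibble of candidate cutoffs with their statistics) and
#'   `multiplicity_note`.
#' @export
optimal_cutoff <- function(values, time, event, min_group_frac = 0.10,
                           feature_name = "feature") {
  check_surv(time, event)
  if (length(values) != length(time)) {
    abort("`values` and `time` must have equal length.",
          class = "hetpet_input_error")
  }
  if (anyNA(values)) {
    abort("`values` must not contain missing data.",
          class = "hetpet_input_error")
  }
  v <- sort(unique(values))
  if (length(v) < 2) {
    abort("All feature values are equal; no cutoff exists.",
          class = "hetpet_no_cutoff")
  }
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(values)
  min_n <- max(1L, ceiling(min_group_frac * n))
  n_high <- vapply(cand, function(cc) sum(values > cc), integer(1))
  ok <- n_high >= min_n & (n - n_high) >= min_n
  if (!any(ok)) {
    abort("No candidate cutoff satisfies the group-size constraint.",
          class = "hetpet_no_cutoff")
  }
  cand <- cand[ok]
  n_high <- n_high[ok]
  chi <- vapply(cand, function(cc) {
    logrank_chisq(time, event, values > cc)[["chi"]]
  }, numeric(1))
  scan <- tibble(
    cutoff = cand,
    chi_square = chi,
    p_value = pchisq(chi, df = 1, lower.tail = FALSE),
    n_high = n_high,
    n_low = n - n_high
  )
  best <- which.max(chi)
  structure(
    list(
      feature_name = feature_name,
      cutoff = cand[best],
      chi_square = chi[best],
      p_value = scan$p_value[best],
      n_low = n - n_high[best],
      n_high = n_high[best],
      scan = scan,
      multiplicity_note = paste(
        "The reported p-value is the naive minimum over the cutoff scan",
        "and is optimistically biased by maximal selection; apply a",
        "maximally-selected-statistic correction before interpreting it."
      )
    ),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("Optimized cutoff for", x$feature_name, ":", signif(x$cutoff, 6), "\n")
  cat("  log-rank chi-square =", signif(x$chi_square, 5),
      ", naive p =", signif(x$p_value, 4), "\n")
  cat("  n_low =", x$n_low, ", n_high =", x$n_high,
      " (", nrow(x$scan), "candidates scanned )\n")
  cat("  NOTE:", x$multiplicity_note, "\n")
  invisible(x)
}

#' @method tidy cutoff_result
#' @export
tidy.cutoff_result <- function(x, ...) {
  x$scan
}

#' @method glance cutoff_result
#' @export
glance.cutoff_result <- function(x, ...) {
  tibble(
    feature_name = x$feature_name, cutoff = x$cutoff,
    chi_square = x$chi_square, p_value = x$p_value,
    n_low = x$n_low, n_high = x$n_high, n_candidates = nrow(x$scan)
  )
}

#' Dichotomize a feature at a cutoff
#'
#' Values strictly greater than the cutoff are labeled `"high"`, the
#' rest `"low"` (so a value exactly at the cutoff is "low", consistent
#' with "high" groups defined by `feature > cutoff`).
#'
#' @param values Numeric feature vector.
#' @param cutoff The threshold.
#' @return Character vector of `"low"` / `"high"` labels.
#' @export
dichotomize <- function(values, cutoff) {
  ifelse(values > cutoff, "high", "low")
}

#' Combine two low/high assignments into one risk group
#'
#' Combines dichotomized genetic and imaging heterogeneity groups:
#' a patient is `"low"` only when low in *both* inputs, and `"high"`
#' when high in at least one. Symmetric and monotone in its arguments.
#'
#' @param a,b Data frames with columns `patient_id` and `group`
#'   (`"low"`/`"high"`), covering the same patient set.
#' @return A tibble `patient_id`, `group` with the combined labels.
#' @export
combine_groups <- function(a, b) {
  for (x in list(a, b)) {
    if (!all(c("patient_id", "group") %in% names(x))) {
      abort("Assignments need `patient_id` and `group` columns.",
            class = "hetpet_input_error")
    }
    if (!all(x$group %in% c("low", "high"))) {
      abort("Group labels must be 'low' or 'high'.",
            class = "hetpet_input_error")
    }
  }
  if (anyDuplicated(a$patient_id) || anyDuplicated(b$patient_id) ||
      !setequal(a$patient_id, b$patient_id)) {
    abort("Assignments must cover the same patient set exactly once.",
          class = "hetpet_patient_mismatch")
  }
  m <- dplyr::inner_join(
    dplyr::rename(as_tibble(a), group_a = "group"),
    dplyr::rename(as_tibble(b), group_b = "group"),
    by = "patient_id"
  )
  dplyr::transmute(
    m, patient_id = .data$patient_id,
    group = ifelse(.data$group_a == "low" & .data$group_b == "low",
                   "low", "high")
  )
}
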