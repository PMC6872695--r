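# Independent oracles, written from first principles and kept separate
# from the package implementations they check.

# median by sorting, without stats::median
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# direct-arithmetic MATH: 100 * scaled MAD / median
oracle_math <- function(vafs, constant = 1.4826) {
  m <- sort_median(vafs)
  100 * constant * sort_median(abs(vafs - m)) / m
}

# log-rank chi-square via survival::survdiff (established library route)
oracle_logrank_chi <- function(time, event, group) {
  survival::survdiff(survival::Surv(time, event) ~ group)$chisq
}

# exhaustive cutoff scan using the survdiff oracle
oracle_best_cutoff <- function(values, time, event, min_group_frac = 0.10) {
  v <- sort(unique(values))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(values)
  min_n <- max(1, ceiling(min_group_frac * n))
  best <- NULL
  for (cc in cand) {
    hi <- values > cc
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    chi <- oracle_logrank_chi(time, event, hi)
    if (is.null(best) || chi > best$chi) best <- list(cutoff = cc, chi = chi)
  }
  best
}

# average ranks computed by counting, then Pearson by the sum formula
oracle_spearman_rho <- function(x, y) {
  cnt_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- cnt_rank(x); ry <- cnt_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# uniform random tumor phantom on its own grid (no generator code)
random_test_phantom <- function(dims = c(8, 8, 6), spacing = c(2, 2, 2)) {
  vox <- array(runif(prod(dims), 1, 10), dim = dims)
  mask <- array(FALSE, dim = dims)
  ctr <- dims / 2
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  r2 <- rowSums(((idx - rep(ctr, each = nrow(idx))) /
                   rep(dims / 2.5, each = nrow(idx)))^2)
  mask[idx[r2 <= 1, ]] <- TRUE
  list(volume = suv_volume(vox, spacing), mask = roi_mask(mask, spacing))
}

# simple exponential proportional-hazards survival simulator
sim_surv <- function(n, beta, x = NULL, base_rate = 0.002,
                     censor_rate = 0.3) {
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  lam <- base_rate * exp(beta * (x - mean(x)))
  t_ev <- rexp(n, lam)
  t_cs <- rexp(n, base_rate * censor_rate / (1 - censor_rate))
  data.frame(
    time = pmin(t_ev, t_cs),
    event = as.integer(t_ev <= t_cs),
    x = x
  )
}
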