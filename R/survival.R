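#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator of the survival function.
#' Censored observations leave the risk set without producing a step;
#' at tied times, events are handled before censorings (the standard
#' convention).
#'
#' @param time Positive follow-up times (e.g. overall survival in days).
#' @param event Event indicator: 1 = death from any cause, 0 = censored.
#' @return A tibble of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (the estimate just after that time). The curve starts at 1.
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  ut <- sort(unique(time))
  st <- sort(time)
  n <- length(time)
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    tibble(time = ut, n_risk = n_risk, n_event = n_event,
           n_censor = n_censor, survival = surv),
    class = c("km_curve", class(tibble())))
}

check_surv <- function(time, event) {
  if (length(time) != length(event) || length(time) == 0) {
    abort("`time` and `event` must be non-empty and equal length.",
          class = "hetpet_input_error")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    abort("Survival times must be positive and finite.",
          class = "hetpet_input_error")
  }
  if (!all(event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (event).",
          class = "hetpet_input_error")
  }
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival of two
#' groups: observed minus expected events in one group accumulated over
#' event times, variance from the hypergeometric distribution at each
#' event time, chi-square with 1 degree of freedom. Symmetric under
#' group relabeling.
#'
#' @inheritParams km_estimate
#' @param group A two-level grouping vector (factor, character or
#'   logical), same length as `time`.
#' @return An object of class `logrank_result`: a list with
#'   `chi_square`, `p_value`, `n_per_group`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- as.integer(factor(group))
  if (length(g) != length(time) || length(unique(g)) != 2) {
    abort("`group` must have exactly 2 levels.", class = "hetpet_input_error")
  }
  if (sum(event) == 0) {
    abort("No events in either group; log-rank test undefined.",
          class = "hetpet_undefined_test")
  }
  stats <- logrank_chisq(time, event, g == 1)
  structure(
    list(
      chi_square = stats[["chi"]],
      p_value = pchisq(stats[["chi"]], df = 1, lower.tail = FALSE),
      n_per_group = table(factor(group)),
      observed = stats[["o1"]],
      expected = stats[["e1"]]
    ),
    class = "logrank_result"
  )
}

# Core O/E/V accumulation for group-1 membership `in1` (logical).
# Returns c(chi, o1, e1, v). Vectorized over event times.
logrank_chisq <- function(time, event, in1) {
  ut <- sort(unique(time[event == 1]))
  st <- sort(time)
  st1 <- sort(time[in1])
  n <- length(time)
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  n1_risk <- length(st1) - findInterval(ut, st1, left.open = TRUE)
  et <- time[event == 1]
  d <- tabulate(match(et, ut), nbins = length(ut))
  d1 <- tabulate(match(et[in1[event == 1]], ut), nbins = length(ut))
  p1 <- n1_risk / n_risk
  e1 <- d * p1
  keep <- n_risk > 1
  v <- sum((d * p1 * (1 - p1) * (n_risk - d) / (n_risk - 1))[keep])
  o1 <- sum(d1)
  chi <- if (v > 0) (o1 - sum(e1))^2 / v else 0
  c(chi = chi, o1 = o1, e1 = sum(e1), v = v)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test (1 df): chi-square =", signif(x$chi_square, 5),
      ", p =", signif(x$p_value, 4), "\n")
  cat("Group sizes:", paste(names(x$n_per_group), as.integer(x$n_per_group),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(
    chi_square = x$chi_square,
    p_value = x$p_value,
    n_group1 = as.integer(x$n_per_group)[1],
    n_group2 = as.integer(x$n_per_group)[2]
  )
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox proportional-hazards model by partial-likelihood
#' maximization with the Efron tie approximation (delegated to
#' [survival::coxph()]). Character/factor covariates enter as
#' reference-coded indicators; tumor stage coded I < II < III < IV uses
#' level I as reference. Wald 95% confidence intervals and p-values are
#' reported per coefficient.
#'
#' @param data A data frame containing the time, event and covariate
#'   columns.
#' @param time,event Column names (strings) of the follow-up time and
#'   event indicator.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie-handling method, default `"efron"`.
#' @return An object of class `cox_fit`; use [tidy()] for the
#'   per-coefficient table and [glance()] for model-level summaries.
#' @export
cox_fit <- function(data, time = "time", event = "event", covariates,
                    ties = "efron") {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "hetpet_input_error")
  }
  df <- data[c(time, event, covariates)]
  n_before <- nrow(df)
  df <- df[complete.cases(df), , drop = FALSE]
  n_dropped <- n_before - nrow(df)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped for missing values.")
  }
  check_surv(df[[time]], df[[event]])
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.character(x)) {
      df[[cv]] <- factor(x)
      x <- df[[cv]]
    }
    if (length(unique(x)) < 2) {
      abort(sprintf("Covariate `%s` is constant.", cv),
            class = "hetpet_input_error")
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  n_events <- sum(df[[event]])
  n_terms <- ncol(stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = "+"))), df)) - 1
  if (n_events < n_terms) {
    abort(sprintf("Only %d events for %d model terms.", n_events, n_terms),
          class = "hetpet_insufficient_data")
  }
  converged <- TRUE
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|infinite|out of iterations", msg)) {
        converged <<- FALSE
        if (grepl("infinite", msg)) monotone <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  z <- qnorm(0.975)
  res <- tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    std_error = co[, "se(coef)"],
    hazard_ratio = exp(co[, "coef"]),
    ci95_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
    ci95_high = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"]
  )
  # monotone-likelihood screen: separated covariates blow up coefficients
  if (any(abs(res$estimate) > 15) || any(res$std_error > 100)) {
    monotone <- TRUE
    converged <- FALSE
  }
  structure(
    list(coefficients = res, n = nrow(df), n_events = n_events,
         n_dropped = n_dropped, converged = converged,
         monotone_likelihood = monotone, loglik = fit$loglik,
         fit = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$n_events, "\n")
  if (!x$converged) cat("WARNING: fit did not converge cleanly",
                        if (x$monotone_likelihood) "(monotone likelihood?)",
                        "\n")
  print(x$coefficients)
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  x$coefficients
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
    converged = x$converged, monotone_likelihood = x$monotone_likelihood,
    loglik = x$loglik[length(x$loglik)]
  )
}

#' Read a clinical table
#'
#' Reads a CSV/TSV clinical table with tolerant, case-insensitive header
#' matching. Recognized columns: patient/sample identifier
#' (`patient_id`, `case_id`, `bcr_patient_barcode`), overall-survival
#' time (`os_days`, `time`, `os_time`), vital status (`vital_status`,
#' `event`, `os_event`; `Dead`/`Alive` strings or 1/0), `age`, `sex`
#' (or `gender`), `stage`, and optional `glycos`. Rows with missing
#' time or status are dropped with a message (listwise deletion).
#'
#' @param path Path to a delimited file (delimiter sniffed from the
#'   extension: `.csv` comma, otherwise tab).
#' @return A tibble with normalized columns `patient_id`, `os_days`,
#'   `event` plus any of `age`, `sex`, `stage`, `glycos`.
#' @export
read_clinical <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  lookup <- c(
    patient_id = "patient_id", case_id = "patient_id",
    bcr_patient_barcode = "patient_id", sample_id = "patient_id",
    os_days = "os_days", time = "os_days", os_time = "os_days",
    time_days = "os_days",
    vital_status = "event", event = "event", os_event = "event",
    age = "age", sex = "sex", gender = "sex", stage = "stage",
    tumor_stage = "stage", glycos = "glycos"
  )
  lc <- tolower(names(raw))
  keep <- lc %in% names(lookup)
  out <- raw[keep]
  names(out) <- unname(lookup[lc[keep]])
  out <- out[!duplicated(names(out))]
  missing <- setdiff(c("patient_id", "os_days", "event"), names(out))
  if (length(missing) > 0) {
    abort(paste0("Clinical table missing: ", paste(missing, collapse = ", ")),
          class = "hetpet_input_error")
  }
  if (is.character(out$event)) {
    out$event <- as.integer(tolower(out$event) %in% c("dead", "deceased", "1"))
  }
  n0 <- nrow(out)
  out <- out[!is.na(out$os_days) & !is.na(out$event), , drop = FALSE]
  if (nrow(out) < n0) {
    message(n0 - nrow(out), " record(s) dropped for missing survival data.")
  }
  as_tibble(out)
}
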