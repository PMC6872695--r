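#' Run the end-to-end radiogenomic heterogeneity analysis
#'
#' Orchestrates the full pipeline on one cohort: per-sample MATH from
#' the variant table; the six PET features per tumor; the 2 x 6
#' genomic-PET Spearman grid; optimized log-rank cutoffs for MATH,
#' GlycoS and the two PET heterogeneity features; Kaplan-Meier curves
#' and log-rank tests for the single-feature and combined
#' (MATH + entropy, MATH + COV) risk groups; and the three Cox model
#' forms per genomic feature (unadjusted; adjusted for age, sex and
#' stage; mutually adjusted for the other genomic feature plus age,
#' sex and stage). Patient counts are logged at every join or drop.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{synthetic}{a [cohort_spec()] to simulate the cohort, or}
#'     \item{maf, clinical, image_dir}{paths to a MAF-style TSV,
#'       clinical CSV and a directory of `<id>_suv.nii.gz` /
#'       `<id>_mask.nii.gz` pairs,}
#'     \item{target_spacing}{feature-extraction grid in mm
#'       (default `c(2, 2, 2)` for synthetic cohorts,
#'       `c(4.7, 4.7, 3.3)` for file input),}
#'     \item{n_bins, bin_range}{entropy histogram settings (synthetic
#'       default: 64 bins over absolute SUV bounds `c(0, 25)`),}
#'     \item{min_variants, min_group_frac}{MATH and cutoff settings.}
#'   }
#' @param out_dir Optional directory; when given, every stage output is
#'   persisted there as TSV/JSON.
#' @return An object of class `analysis_report`: list with `features`,
#'   `correlations`, `cutoffs`, `groups`, `km`, `logrank`, `cox`,
#'   `attrition`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$synthetic)) {
      config$synthetic <- do.call(cohort_spec, config$synthetic[
        names(config$synthetic) %in% names(formals(cohort_spec))])
    }
  }
  synthetic <- !is.null(config$synthetic)
  target_spacing <- config$target_spacing %||%
    if (synthetic) c(2, 2, 2) else c(4.7, 4.7, 3.3)
  n_bins <- config$n_bins %||% 64
  bin_range <- config$bin_range %||% if (synthetic) c(0, 25) else NULL
  min_variants <- config$min_variants %||% 5
  min_group_frac <- config$min_group_frac %||% 0.10

  attrition <- list()
  note <- function(stage, n) {
    attrition[[stage]] <<- n
    message(sprintf("[%s] n = %d", stage, n))
  }

  if (synthetic) {
    cohort <- gen_cohort(config$synthetic)
    variants <- cohort$variants
    clinical <- cohort$clinical
    phantoms <- cohort$phantoms
  } else {
    variants <- read_maf(config$maf)
    clinical <- read_clinical(config$clinical)
    ids <- clinical$patient_id
    phantoms <- purrr::map(ids, function(id) {
      vp <- file.path(config$image_dir, paste0(id, "_suv.nii.gz"))
      mp <- file.path(config$image_dir, paste0(id, "_mask.nii.gz"))
      if (!file.exists(vp) || !file.exists(mp)) return(NULL)
      list(volume = read_suv_nifti(vp), mask = read_mask_nifti(mp))
    })
    names(phantoms) <- ids
    phantoms <- phantoms[!purrr::map_lgl(phantoms, is.null)]
  }
  note("clinical", nrow(clinical))
  if (nrow(clinical) < 20) {
    abort(sprintf(
      "Cohort of %d patient(s): at least 20 are required for cutoff %s",
      nrow(clinical), "stratification and model fitting."),
      class = "hetpet_validation_error")
  }

  math_tbl <- math_per_sample(variants, min_variants = min_variants)
  note("math_computed", sum(!math_tbl$excluded))

  pet <- purrr::map_dfr(phantoms, function(ph) {
    extract_pet_features(ph$volume, ph$mask,
                         target_spacing = target_spacing,
                         n_bins = n_bins, bin_range = bin_range)
  })
  pet$patient_id <- names(phantoms)
  note("pet_features", nrow(pet))

  features <- dplyr::rename(math_tbl, patient_id = "sample_id") |>
    dplyr::filter(!.data$excluded) |>
    dplyr::inner_join(pet, by = "patient_id") |>
    dplyr::inner_join(clinical, by = "patient_id")
  note("joined", nrow(features))

  correlations <- correlation_matrix(
    features[c("patient_id", "math", "glycos")],
    features[c("patient_id", "suv_max", "suv_peak", "mtv_ml", "tlg",
               "entropy_bits", "cov")]
  )

  cut_features <- c("math", "glycos", "entropy_bits", "cov")
  cutoffs <- purrr::map(setNames(cut_features, cut_features), function(f) {
    optimal_cutoff(features[[f]], features$os_days, features$event,
                   min_group_frac = min_group_frac, feature_name = f)
  })
  groups <- purrr::map(cutoffs, function(cr) {
    tibble(patient_id = features$patient_id,
           group = dichotomize(features[[cr$feature_name]], cr$cutoff))
  })
  groups$math_entropy <- combine_groups(groups$math, groups$entropy_bits)
  groups$math_cov <- combine_groups(groups$math, groups$cov)

  km <- purrr::map(groups, function(g) {
    gg <- g$group[match(features$patient_id, g$patient_id)]
    list(
      low = km_estimate(features$os_days[gg == "low"],
                        features$event[gg == "low"]),
      high = km_estimate(features$os_days[gg == "high"],
                         features$event[gg == "high"])
    )
  })
  logrank <- purrr::map(groups, function(g) {
    gg <- g$group[match(features$patient_id, g$patient_id)]
    logrank_test(features$os_days, features$event, gg)
  })

  clin_adj <- c("age", "sex", "stage")
  cox_forms <- list(
    math_unadjusted = "math",
    math_adjusted = c("math", clin_adj),
    math_mutually_adjusted = c("math", "glycos", clin_adj),
    glycos_unadjusted = "glycos",
    glycos_adjusted = c("glycos", clin_adj),
    glycos_mutually_adjusted = c("glycos", "math", clin_adj)
  )
  cox <- purrr::map(cox_forms, function(cv) {
    cox_fit(features, time = "os_days", event = "event", covariates = cv)
  })

  report <- structure(
    list(
      features = features,
      correlations = correlations,
      cutoffs = cutoffs,
      groups = groups,
      km = km,
      logrank = logrank,
      cox = cox,
      attrition = attrition
    ),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  patients analyzed:", nrow(x$features), "\n")
  cat("  correlations: MATH~entropy rho =",
      signif(x$correlations$rho[x$correlations$feature_a == "math" &
               x$correlations$feature_b == "entropy_bits"], 3), "\n")
  cat("  log-rank p: MATH =", signif(x$logrank$math$p_value, 3),
      "; MATH+entropy =", signif(x$logrank$math_entropy$p_value, 3),
      "; MATH+COV =", signif(x$logrank$math_cov$p_value, 3), "\n")
  hr <- tidy(x$cox$math_mutually_adjusted)
  hr <- hr[hr$term == "math", ]
  cat("  mutually adjusted MATH HR =", signif(hr$hazard_ratio, 4),
      "( p =", signif(hr$p_value, 3), ")\n")
  invisible(x)
}

#' Persist an analysis report
#'
#' Writes each stage output of [run_pipeline()] as a plain-text table
#' (`features.tsv`, `correlations.tsv`, `cutoffs.tsv`, `groups.tsv`,
#' `logrank.tsv`, `cox.tsv`) plus a machine-readable `report.json`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$features, file.path(dir, "features.tsv"))
  readr::write_tsv(report$correlations, file.path(dir, "correlations.tsv"))
  readr::write_tsv(purrr::map_dfr(report$cutoffs, glance),
                   file.path(dir, "cutoffs.tsv"))
  readr::write_tsv(
    purrr::imap_dfr(report$groups,
                    ~ dplyr::mutate(.x, grouping = .y, .before = 1)),
    file.path(dir, "groups.tsv"))
  readr::write_tsv(
    purrr::imap_dfr(report$logrank,
                    ~ dplyr::mutate(glance(.x), grouping = .y, .before = 1)),
    file.path(dir, "logrank.tsv"))
  readr::write_tsv(
    purrr::imap_dfr(report$cox,
                    ~ dplyr::mutate(tidy(.x), model = .y, .before = 1)),
    file.path(dir, "cox.tsv"))
  jsonlite::write_json(
    list(
      attrition = report$attrition,
      cutoffs = purrr::map(report$cutoffs, ~ glance(.x)),
      logrank = purrr::map(report$logrank, ~ glance(.x)),
      cox = purrr::map(report$cox, ~ tidy(.x))
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
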