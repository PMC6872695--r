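#' Specification of a synthetic radiogenomic cohort
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object, so a cohort is fully reproducible from its spec (identical
#' spec, identical cohort). The defaults emulate the structure of a
#' head-and-neck squamous cell carcinoma cohort: a clonal VAF cluster
#' near 0.45 with latent-heterogeneity-driven subclones; small tumors
#' (volumes lognormal, median 1.14 mL, clipped to 0.36-3.93 mL); stage
#' distribution skewed to III/IV (78%); about 3:1 male; exponential
#' baseline survival with median around 633 days; independent censoring.
#'
#' @param n_patients Cohort size.
#' @param clonal_vaf_center Center of the clonal VAF cluster, default 0.45.
#' @param clonal_vaf_sd SD of the clonal cluster, default 0.01.
#' @param subclone_count_range Integer range of subclonal clusters at
#'   full latent heterogeneity, default `c(1L, 3L)`.
#' @param subclone_vaf_spread Fraction of the clonal center spanned by
#'   subclonal cluster centers at full heterogeneity, default 0.75.
#' @param n_variants_mean Mean somatic variant count per tumor
#'   (Poisson), default 80.
#' @param depth_mean Mean sequencing depth per variant (Poisson),
#'   default 150 reads.
#' @param tumor_volume_range_ml Volume clip range in mL,
#'   default `c(0.36, 3.93)`.
#' @param tumor_volume_median_ml Median tumor volume in mL, default 1.14.
#' @param texture_heterogeneity Global scale in `[0, 1]` on the phantom
#'   speckle/hotspot amplitude, default 1.
#' @param phantom_spacing_mm Native phantom grid spacing, default
#'   1.5 mm isotropic.
#' @param coupling_rho Target rank coupling between the realized MATH
#'   and PET entropy of the cohort, default 0.5.
#' @param beta_math,beta_glycos,beta_entropy True log-hazard
#'   coefficients per unit of (realized) MATH, GlycoS and entropy.
#'   Defaults 0.03, 0.5 and 0 (no direct imaging effect).
#' @param stage_betas Log-hazard offsets for stages I-IV.
#' @param median_os_days Baseline median overall survival, default 633.
#' @param censor_rate Target fraction censored, default 0.3.
#' @param seed Integer seed; the generator is fully deterministic
#'   given the spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        clonal_vaf_center = 0.45,
                        clonal_vaf_sd = 0.01,
                        subclone_count_range = c(1L, 3L),
                        subclone_vaf_spread = 0.75,
                        n_variants_mean = 80,
                        depth_mean = 150,
                        tumor_volume_range_ml = c(0.36, 3.93),
                        tumor_volume_median_ml = 1.14,
                        texture_heterogeneity = 1,
                        phantom_spacing_mm = c(1.5, 1.5, 1.5),
                        coupling_rho = 0.5,
                        beta_math = 0.03,
                        beta_glycos = 0.5,
                        beta_entropy = 0,
                        stage_betas = c(I = 0, II = 0.15, III = 0.4,
                                        IV = 0.7),
                        median_os_days = 633,
                        censor_rate = 0.3,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    clonal_vaf_center = clonal_vaf_center,
    clonal_vaf_sd = clonal_vaf_sd,
    subclone_count_range = as.integer(subclone_count_range),
    subclone_vaf_spread = subclone_vaf_spread,
    n_variants_mean = n_variants_mean,
    depth_mean = depth_mean,
    tumor_volume_range_ml = tumor_volume_range_ml,
    tumor_volume_median_ml = tumor_volume_median_ml,
    texture_heterogeneity = texture_heterogeneity,
    phantom_spacing_mm = phantom_spacing_mm,
    coupling_rho = coupling_rho,
    beta_math = beta_math,
    beta_glycos = beta_glycos,
    beta_entropy = beta_entropy,
    stage_betas = stage_betas,
    median_os_days = median_os_days,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  frac_fields <- c("clonal_vaf_center", "clonal_vaf_sd",
                   "subclone_vaf_spread", "texture_heterogeneity",
                   "coupling_rho", "censor_rate")
  for (f in frac_fields) {
    if (!is.numeric(spec[[f]]) || spec[[f]] < 0 || spec[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f),
            class = "hetpet_spec_error")
    }
  }
  if (spec$censor_rate >= 1) {
    abort("`censor_rate` must be below 1.", class = "hetpet_spec_error")
  }
  if (spec$n_patients < 1) {
    abort("`n_patients` must be positive.", class = "hetpet_spec_error")
  }
  if (any(spec$tumor_volume_range_ml <= 0) ||
      diff(spec$tumor_volume_range_ml) <= 0) {
    abort("`tumor_volume_range_ml` must be a positive increasing range.",
          class = "hetpet_spec_error")
  }
  if (length(spec$stage_betas) != 4) {
    abort("`stage_betas` needs 4 values (stages I-IV).",
          class = "hetpet_spec_error")
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate a subclonal variant table for one tumor
#'
#' Draws somatic variants as a clonal VAF cluster near
#' `clonal_vaf_center` plus subclonal clusters at lower allele
#' fractions. The latent heterogeneity in `[0, 1]` controls the
#' subclonal fraction of variants and the spread of subclone centers,
#' so the realized MATH score increases with it on average; at
#' `latent_het = 0` all variants are clonal and MATH reflects only
#' binomial read-sampling noise. Read depths are Poisson around
#' `depth_mean`; alt counts are binomial at the true VAF.
#'
#' Runs under the caller's RNG state; seed outside (e.g. with
#' [withr::with_seed()]) for reproducibility.
#'
#' @param latent_het Latent heterogeneity in `[0, 1]`.
#' @param spec A [cohort_spec()].
#' @param sample_id Sample label for the output table.
#' @return A tibble in MAF-normalized form: `sample_id`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `t_ref_count`, `t_alt_count`.
#' @export
gen_variants <- function(latent_het, spec = cohort_spec(),
                         sample_id = "S1") {
  stopifnot(latent_het >= 0, latent_het <= 1)
  n_var <- max(10L, rpois(1, spec$n_variants_mean))
  k_max <- spec$subclone_count_range[2]
  k <- if (latent_het == 0) 0L else
    max(spec$subclone_count_range[1],
        as.integer(round(latent_het * k_max)))
  p_sub <- 0.65 * latent_het
  is_sub <- runif(n_var) < p_sub & k > 0
  centers <- if (k > 0) {
    lowest <- spec$clonal_vaf_center *
      (1 - spec$subclone_vaf_spread * (0.4 + 0.6 * latent_het))
    seq(spec$clonal_vaf_center * 0.75, lowest, length.out = k) +
      runif(k, -0.02, 0.02)
  } else numeric(0)
  true_vaf <- numeric(n_var)
  true_vaf[!is_sub] <- rnorm(sum(!is_sub), spec$clonal_vaf_center,
                             spec$clonal_vaf_sd)
  if (any(is_sub)) {
    cl <- sample.int(k, sum(is_sub), replace = TRUE)
    true_vaf[is_sub] <- rnorm(sum(is_sub), centers[cl], 0.015)
  }
  true_vaf <- pmin(pmax(true_vaf, 0.02), 0.95)
  depth <- pmax(20L, rpois(n_var, spec$depth_mean))
  alt <- rbinom(n_var, depth, true_vaf)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  tibble(
    sample_id = sample_id,
    chrom = as.character(sample.int(22, n_var, replace = TRUE)),
    pos = sample.int(2e8, n_var, replace = TRUE),
    ref_allele = ref,
    alt_allele = unname(alt_allele),
    t_ref_count = depth - alt,
    t_alt_count = alt
  )
}

#' Simulate a heterogeneous PET tumor phantom
#'
#' Builds an ellipsoidal tumor of approximately `target_volume_ml` on a
#' fine isotropic grid: a smooth base uptake blob (mild radial falloff),
#' multiplicative log-normal speckle whose amplitude grows with the
#' latent heterogeneity, and latent-driven secondary hot subregions.
#' Higher latent heterogeneity therefore yields wider intensity
#' distributions — higher COV and (with absolute-bound histogram
#' binning) higher entropy. Background uptake is near SUV 0.8.
#'
#' Runs under the caller's RNG state.
#'
#' @inheritParams gen_variants
#' @param target_volume_ml Target metabolic tumor volume in mL.
#' @return A list with elements `volume` ([suv_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
gen_phantom <- function(latent_het, target_volume_ml,
                        spec = cohort_spec()) {
  stopifnot(latent_het >= 0, latent_het <= 1, target_volume_ml > 0)
  sp <- spec$phantom_spacing_mm
  r0 <- (3 * target_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  aniso <- exp(rnorm(3, 0, 0.08))
  axes <- r0 * aniso / prod(aniso)^(1 / 3)
  margin <- 4L
  dims <- as.integer(ceiling(2 * axes / sp)) + 2L * margin
  ctr <- (dims + 1) / 2
  ix <- (seq_len(dims[1]) - ctr[1]) * sp[1] / axes[1]
  iy <- (seq_len(dims[2]) - ctr[2]) * sp[2] / axes[2]
  iz <- (seq_len(dims[3]) - ctr[3]) * sp[3] / axes[3]
  rho2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  mask <- rho2 <= 1
  suv0 <- runif(1, 5, 12)
  amp <- spec$texture_heterogeneity * latent_het
  base <- suv0 * (1 - 0.03 * rho2)
  speckle_sd <- 0.02 + 0.45 * amp
  vox <- base * exp(rnorm(length(base), -speckle_sd^2 / 2, speckle_sd))
  dim(vox) <- dims
  # secondary hot subregions
  n_hot <- rpois(1, 2 * amp)
  if (n_hot > 0) {
    fg <- which(mask, arr.ind = TRUE)
    for (h in seq_len(n_hot)) {
      c_h <- fg[sample.int(nrow(fg), 1), ]
      r_h <- runif(1, 2, 4)  # mm
      gain <- runif(1, 0.3, 0.8)
      d2 <- outer(outer(((seq_len(dims[1]) - c_h[1]) * sp[1])^2,
                        ((seq_len(dims[2]) - c_h[2]) * sp[2])^2, `+`),
                  ((seq_len(dims[3]) - c_h[3]) * sp[3])^2, `+`)
      vox <- vox * (1 + gain * exp(-d2 / (2 * r_h^2)))
    }
  }
  bg <- pmax(0.05, 0.8 + rnorm(length(vox), 0, 0.05))
  vox[!mask] <- bg[!mask]
  list(
    volume = suv_volume(vox, spacing = sp),
    mask = roi_mask(mask, spacing = sp)
  )
}

# Latent coupling calibration: the target rank correlation between the
# realized MATH and entropy is attenuated by read-sampling noise in the
# genomic arm and histogram-sampling noise in the imaging arm
# (calibration run: rank(MATH, latent) ~ 0.94, rank(entropy, latent)
# ~ 0.75, product ~ 0.71). The attenuation constant was fixed once from
# that run; the bivariate-normal latent correlation uses the exact
# Spearman-to-Pearson map r = 2 sin(pi * rho_s / 6).
latent_pearson_r <- function(coupling_rho, attenuation = 0.71) {
  rho_lat <- min(0.98, coupling_rho / attenuation)
  2 * sin(pi * rho_lat / 6)
}

#' Simulate a full synthetic radiogenomic cohort
#'
#' Generates, per patient: a coupled pair of latent heterogeneity
#' scores (genomic and imaging, rank-coupled at `coupling_rho`); a
#' subclonal variant table; a PET tumor phantom with volume drawn
#' lognormally (median `tumor_volume_median_ml`, clipped to
#' `tumor_volume_range_ml`); a GlycoS scalar linked to the latent
#' metabolic burden; demographics (age, sex, 4-level stage skewed to
#' III/IV); and overall survival from an exponential
#' proportional-hazards model with linear predictor
#' `beta_math * MATH + beta_glycos * GlycoS + beta_entropy * entropy +
#' stage effect` (covariates centered, so the baseline median survival
#' is `median_os_days`), with independent exponential censoring tuned
#' to `censor_rate`.
#'
#' The realized MATH and entropy (computed with the package's own
#' feature extractors at 2 mm grid and absolute-bound binning) are what
#' enter the hazard, so downstream model fits can be checked against
#' the true coefficients.
#'
#' @param spec A [cohort_spec()].
#' @param keep_phantoms Keep the per-patient volumes/masks in the
#'   result (memory-heavy for large cohorts). Default `TRUE`.
#' @return A list of class `synthetic_cohort`: `variants` (one table,
#'   all samples), `phantoms` (named list of volume/mask pairs, unless
#'   dropped), `clinical` (tibble with `patient_id`, `os_days`,
#'   `event`, `age`, `sex`, `stage`, `glycos`), `features` (realized
#'   per-patient MATH + PET features), and `truth` (latent scores,
#'   true betas, linear predictor).
#' @export
gen_cohort <- function(spec = cohort_spec(), keep_phantoms = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, gen_cohort_impl(spec, keep_phantoms))
}

gen_cohort_impl <- function(spec, keep_phantoms) {
  n <- spec$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  r <- latent_pearson_r(spec$coupling_rho)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  latent_g <- pnorm(z1)
  latent_i <- pnorm(z2)

  variants <- purrr::map2_dfr(latent_g, ids,
                              ~ gen_variants(.x, spec, sample_id = .y))
  math_tbl <- math_per_sample(variants)

  sdlog <- 0.55
  vol_ml <- pmin(pmax(stats::rlnorm(n, log(spec$tumor_volume_median_ml),
                                    sdlog),
                      spec$tumor_volume_range_ml[1]),
                 spec$tumor_volume_range_ml[2])
  phantoms <- purrr::map(seq_len(n), function(i) {
    gen_phantom(latent_i[i], vol_ml[i], spec)
  })
  names(phantoms) <- ids
  pet <- purrr::map_dfr(phantoms, function(ph) {
    extract_pet_features(ph$volume, ph$mask, target_spacing = c(2, 2, 2),
                         bin_range = c(0, 25))
  })
  pet$patient_id <- ids

  # GlycoS tracks the latent metabolic burden: part texture latent,
  # part (log) tumor volume, plus measurement noise
  glycos <- 0.8 + 0.6 * (latent_i - 0.5) +
    0.3 * (log(vol_ml) - mean(log(vol_ml))) + rnorm(n, 0, 0.2)
  age <- pmin(90, pmax(20, round(rnorm(n, 61, 12))))
  sex <- ifelse(runif(n) < 0.73, "male", "female")
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.10, 0.12, 0.25, 0.53))

  math <- math_tbl$math[match(ids, math_tbl$sample_id)]
  entropy <- pet$entropy_bits
  ctr <- function(x) x - mean(x, na.rm = TRUE)
  lp <- spec$beta_math * ctr(math) +
    spec$beta_glycos * ctr(glycos) +
    spec$beta_entropy * ctr(entropy) +
    ctr(unname(spec$stage_betas[stage]))
  lp[is.na(lp)] <- 0
  base_rate <- log(2) / spec$median_os_days
  lambda <- base_rate * exp(lp)
  t_event <- rexp(n, rate = lambda)
  # exponential censoring rate solved so the expected censored fraction,
  # mean(mu / (lambda_i + mu)), equals the target
  cens_rate <- if (spec$censor_rate > 0) {
    stats::uniroot(
      function(mu) mean(mu / (lambda + mu)) - spec$censor_rate,
      lower = 1e-12, upper = max(lambda) * 1e4, tol = 1e-12
    )$root
  } else 0
  t_cens <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  os_days <- pmax(1, pmin(t_event, t_cens))
  event <- as.integer(t_event <= t_cens)

  clinical <- tibble(
    patient_id = ids, os_days = os_days, event = event,
    age = age, sex = sex, stage = stage, glycos = glycos
  )
  features <- dplyr::left_join(
    dplyr::rename(math_tbl, patient_id = "sample_id"),
    pet, by = "patient_id"
  )
  features$glycos <- glycos
  structure(
    list(
      variants = variants,
      phantoms = if (keep_phantoms) phantoms else NULL,
      clinical = clinical,
      features = features,
      truth = tibble(
        patient_id = ids, latent_het_genomic = latent_g,
        latent_het_imaging = latent_i, target_volume_ml = vol_ml,
        math = math, entropy_bits = entropy, linear_predictor = lp
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", x$spec$n_patients,
      "patients, seed =", x$spec$seed, "\n")
  cat("  events:", sum(x$clinical$event), "; censored:",
      sum(1 - x$clinical$event), "\n")
  cat("  MATH range:", paste(signif(range(x$features$math, na.rm = TRUE), 3),
                             collapse = " - "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Persists a cohort in the interchange formats the analysis side
#' reads: one MAF-style TSV of variants, per-patient NIfTI volume/mask
#' pairs, a clinical CSV, and a ground-truth JSON.
#'
#' @param cohort A [gen_cohort()] result (with phantoms kept).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maf <- dplyr::rename(
    cohort$variants,
    Tumor_Sample_Barcode = "sample_id", Chromosome = "chrom",
    Start_Position = "pos", Reference_Allele = "ref_allele",
    Tumor_Seq_Allele2 = "alt_allele"
  )
  readr::write_tsv(maf, file.path(dir, "variants.maf.tsv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_tsv(cohort$features, file.path(dir, "features.tsv"))
  if (!is.null(cohort$phantoms)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(cohort$phantoms)) {
      write_nifti(cohort$phantoms[[id]]$volume,
                  file.path(img_dir, paste0(id, "_suv.nii.gz")))
      write_nifti(cohort$phantoms[[id]]$mask,
                  file.path(img_dir, paste0(id, "_mask.nii.gz")))
    }
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(spec = unclass(cohort$spec), truth = truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
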