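#' Conventional SUV features of a tumor ROI
#'
#' `suv_max()` is the hottest masked voxel; `suv_mean()` the mean over
#' masked voxels; `suv_peak()` the mean SUV over all voxels whose
#' centers lie within a 1 cm3 sphere (radius 6.2035 mm) centered at the
#' hottest masked voxel — the PERCIST-style convention. The sphere is
#' clipped to the volume bounds but not to the mask.
#'
#' @param volume An [suv_volume()].
#' @param mask An [roi_mask()] congruent with `volume`.
#' @return A single SUV value.
#' @export
suv_max <- function(volume, mask) {
  check_congruent(volume, mask)
  max(volume$voxels[mask$voxels])
}

#' @rdname suv_max
#' @export
suv_mean <- function(volume, mask) {
  check_congruent(volume, mask)
  mean(volume$voxels[mask$voxels])
}

#' @rdname suv_max
#' @param radius_mm Sphere radius in mm; default 6.2035 (a 1 cm3 sphere).
#' @export
suv_peak <- function(volume, mask, radius_mm = 6.2035) {
  check_congruent(volume, mask)
  dims <- dim(volume$voxels)
  sp <- volume$spacing
  masked <- which(mask$voxels, arr.ind = TRUE)
  vals <- volume$voxels[mask$voxels]
  hot <- masked[which.max(vals), ]  # first max in index order on ties
  # candidate index window around the hot voxel
  half <- ceiling(radius_mm / sp)
  rng <- lapply(1:3, function(a) {
    max(1, hot[a] - half[a]):min(dims[a], hot[a] + half[a])
  })
  grid <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- ((grid$i - hot[1]) * sp[1])^2 +
        ((grid$j - hot[2]) * sp[2])^2 +
        ((grid$k - hot[3]) * sp[3])^2
  inside <- d2 <= radius_mm^2
  idx <- cbind(grid$i, grid$j, grid$k)[inside, , drop = FALSE]
  mean(volume$voxels[idx])
}

#' Metabolic tumor volume (MTV)
#'
#' Foreground voxel count times the voxel volume, reported in mL.
#'
#' @param mask An [roi_mask()].
#' @param spacing Optional spacing override in mm; defaults to the
#'   mask's own spacing.
#' @return Volume in mL.
#' @export
mtv <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- if (is.null(spacing)) mask$spacing else as.numeric(spacing)
  sum(mask$voxels) * prod(sp) / 1000
}

#' Total lesion glycolysis (TLG)
#'
#' The product of the ROI's mean SUV and its metabolic tumor volume,
#' `TLG = SUVmean * MTV` (SUV x mL).
#'
#' @inheritParams suv_max
#' @inheritParams mtv
#' @return TLG in SUV x mL.
#' @export
tlg <- function(volume, mask, spacing = NULL) {
  suv_mean(volume, mask) * mtv(mask, spacing)
}

#' First-order histogram entropy of a tumor ROI
#'
#' Shannon entropy of the masked SUV histogram,
#' `-sum_i p(i) * log2(p(i) + eps)` with `eps = 2e-16`, where `p(i)` is
#' the fraction of masked voxels falling in intensity bin `i`. Empty
#' bins contribute 0. By default the `n_bins` equal-width bins span the
#' masked `[min, max]` range (entropy is then invariant to positive
#' rescaling of the SUVs); `bin_range` fixes absolute SUV bounds
#' instead, in which case narrow uptake distributions occupy few bins
#' and score low — the behavior of absolute-bound histogram settings in
#' clinical texture software. A constant ROI occupies a single bin and
#' scores (numerically) zero.
#'
#' @inheritParams suv_max
#' @param n_bins Number of histogram bins; default 64.
#' @param bin_range Optional length-2 numeric, absolute SUV bounds for
#'   the bins. Default `NULL` uses the masked min/max. Values outside
#'   the range are clamped into the edge bins.
#' @param eps Offset inside the logarithm; default `2e-16`.
#' @return Entropy in bits.
#' @export
histogram_entropy <- function(volume, mask, n_bins = 64, bin_range = NULL,
                              eps = 2e-16) {
  check_congruent(volume, mask)
  x <- volume$voxels[mask$voxels]
  p <- histogram_probs(x, n_bins, bin_range)
  p <- p[p > 0]
  -sum(p * log2(p + eps))
}

histogram_probs <- function(x, n_bins, bin_range = NULL) {
  if (is.null(bin_range)) {
    lo <- min(x); hi <- max(x)
  } else {
    lo <- bin_range[1]; hi <- bin_range[2]
  }
  if (hi <= lo) {
    # degenerate range: all mass in one bin
    return(c(1, rep(0, n_bins - 1)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(bin, nbins = n_bins) / length(x)
}

#' Coefficient of variation of ROI uptake
#'
#' Standard deviation of the masked SUVs divided by their mean. The
#' population SD (divide by N) is the default: COV here describes the
#' voxel-value distribution rather than estimating a sampling quantity.
#'
#' @inheritParams suv_max
#' @param type `"population"` (default) or `"sample"` SD.
#' @return Dimensionless COV, >= 0.
#' @export
suv_cov <- function(volume, mask, type = c("population", "sample")) {
  type <- match.arg(type)
  check_congruent(volume, mask)
  x <- volume$voxels[mask$voxels]
  m <- mean(x)
  if (m == 0) {
    abort("Mean SUV is zero; COV undefined.", class = "hetpet_degenerate")
  }
  n <- length(x)
  v <- sum((x - m)^2) / if (type == "population") n else max(1, n - 1)
  sqrt(v) / m
}

#' Extract the six metabolic features of a tumor
#'
#' Resamples the SUV volume and ROI mask to a common grid (trilinear
#' interpolation; mask re-binarized at 0.5) and computes the six
#' metabolic features used for heterogeneity analysis: SUVmax, SUVpeak,
#' MTV, TLG, first-order histogram entropy and COV (plus SUVmean, which
#' TLG is built from).
#'
#' @inheritParams suv_max
#' @inheritParams resample_trilinear
#' @inheritParams histogram_entropy
#' @param cov_type SD convention for COV, see [suv_cov()].
#' @param resample If `FALSE`, features are computed on the native grid
#'   (volume and mask must already be congruent and harmonized).
#' @return A one-row tibble: `suv_max`, `suv_peak`, `suv_mean`,
#'   `mtv_ml`, `tlg`, `entropy_bits`, `cov`.
#' @export
extract_pet_features <- function(volume, mask,
                                 target_spacing = c(4.7, 4.7, 3.3),
                                 n_bins = 64, bin_range = NULL,
                                 cov_type = "population",
                                 resample = TRUE) {
  if (resample) {
    volume <- resample_trilinear(volume, target_spacing)
    mask <- resample_mask(mask, target_spacing)
  }
  check_congruent(volume, mask)
  tibble(
    suv_max = suv_max(volume, mask),
    suv_peak = suv_peak(volume, mask),
    suv_mean = suv_mean(volume, mask),
    mtv_ml = mtv(mask),
    tlg = tlg(volume, mask),
    entropy_bits = histogram_entropy(volume, mask, n_bins, bin_range),
    cov = suv_cov(volume, mask, cov_type)
  )
}
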