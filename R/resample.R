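#' Trilinear resampling of an SUV volume
#'
#' Resamples a volume onto a new voxel grid by trilinear interpolation,
#' the standard harmonization step when PET scans from different
#' scanners are compared; the conventional common grid for head-and-neck
#' FDG PET is (4.7, 4.7, 3.3) mm. The output grid spans the same
#' physical extent as the input (voxel-edge to voxel-edge), with
#' `n_out = ceiling(n_in * spacing_in / spacing_out)` voxels per axis.
#' Sampling points beyond the input voxel centers are clamped to the
#' edge value (nearest extrapolation), so a constant volume is
#' reproduced exactly.
#'
#' @param volume An [suv_volume()].
#' @param target_spacing Length-3 positive numeric, target spacing in mm.
#'   Default `c(4.7, 4.7, 3.3)`.
#' @return An [suv_volume()] on the target grid.
#' @export
resample_trilinear <- function(volume, target_spacing = c(4.7, 4.7, 3.3)) {
  stopifnot(inherits(volume, "suv_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3 || any(target_spacing <= 0)) {
    abort("`target_spacing` must be 3 positive numbers (mm).",
          class = "hetpet_input_error")
  }
  dims <- dim(volume$voxels)
  if (any(dims == 1)) {
    warn("Axis with a single slice: interpolation collapses to lower order.")
  }
  sp <- volume$spacing
  extent <- dims * sp
  nd <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  vox <- interp3_grid(volume$voxels, sp, target_spacing, nd)
  # first output voxel center, in input-origin coordinates
  shift <- -sp / 2 + target_spacing / 2
  suv_volume(vox, spacing = target_spacing, origin = volume$origin + shift)
}

# Trilinear interpolation of `arr` (spacing sp) at the centers of an
# nd-sized grid with spacing tsp, both grids sharing the same physical
# corner. Continuous source index of output voxel j (0-based):
#   f_j = ((j + 0.5) * tsp - sp / 2) / sp
# clamped to [0, n - 1].
interp3_grid <- function(arr, sp, tsp, nd) {
  dims <- dim(arr)
  ax <- lapply(1:3, function(a) {
    f <- (((seq_len(nd[a]) - 0.5) * tsp[a]) - sp[a] / 2) / sp[a]
    f <- pmin(pmax(f, 0), dims[a] - 1)
    i0 <- pmin(floor(f), dims[a] - 1)
    w <- f - i0
    i1 <- pmin(i0 + 1, dims[a] - 1)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, w = w)
  })
  out <- array(0, dim = nd)
  # accumulate the 8 corner contributions with outer-product weights
  for (cx in 0:1) {
    ix <- if (cx == 0) ax[[1]]$i0 else ax[[1]]$i1
    wx <- if (cx == 0) 1 - ax[[1]]$w else ax[[1]]$w
    for (cy in 0:1) {
      iy <- if (cy == 0) ax[[2]]$i0 else ax[[2]]$i1
      wy <- if (cy == 0) 1 - ax[[2]]$w else ax[[2]]$w
      for (cz in 0:1) {
        iz <- if (cz == 0) ax[[3]]$i0 else ax[[3]]$i1
        wz <- if (cz == 0) 1 - ax[[3]]$w else ax[[3]]$w
        vals <- arr[ix, iy, iz, drop = FALSE]
        w3 <- outer(outer(wx, wy), wz)
        out <- out + vals * w3
      }
    }
  }
  out
}

#' Resample a binary ROI mask
#'
#' The binary field is interpolated trilinearly as 0/1 values and
#' re-binarized at 0.5, which preserves small-tumor volumes better than
#' nearest-neighbour assignment.
#'
#' @param mask An [roi_mask()].
#' @inheritParams resample_trilinear
#' @return An [roi_mask()] on the target grid.
#' @export
resample_mask <- function(mask, target_spacing = c(4.7, 4.7, 3.3)) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- mask$voxels
  mode(arr) <- "double"
  vol <- suppressWarnings(
    resample_trilinear(suv_volume(arr, mask$spacing, mask$origin),
                       target_spacing)
  )
  fg <- vol$voxels >= 0.5
  if (!any(fg)) {
    abort("ROI disappeared under resampling (sub-voxel tumor).",
          class = "hetpet_degenerate_roi")
  }
  roi_mask(fg, spacing = vol$spacing, origin = vol$origin)
}
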