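#' SUV volume container
#'
#' A minimal container for a 3D PET volume in body-weight standardized
#' uptake value (SUV) units: a numeric array plus voxel spacing in mm.
#' Voxel indices are 0-based in world-coordinate formulas; the world
#' position of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param voxels 3D numeric array of SUV values (finite).
#' @param spacing Length-3 positive numeric, voxel spacing `(dx, dy, dz)`
#'   in mm.
#' @param origin Length-3 numeric, world position of voxel (0,0,0) in mm.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array.", class = "hetpet_input_error")
  }
  if (any(dim(voxels) < 1)) {
    abort("Each axis needs at least 1 voxel.", class = "hetpet_input_error")
  }
  if (!all(is.finite(voxels))) {
    abort("All SUV values must be finite.", class = "hetpet_input_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).",
          class = "hetpet_input_error")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "suv_volume"
  )
}

#' Binary tumor ROI mask
#'
#' A binary region-of-interest mask congruent with an [suv_volume()]
#' grid (same array dimensions and spacing).
#'
#' @param voxels 3D logical (or 0/1) array; at least one foreground voxel.
#' @inheritParams suv_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array.", class = "hetpet_input_error")
  }
  mode(voxels) <- "logical"
  if (!any(voxels)) {
    abort("ROI mask has no foreground voxels.", class = "hetpet_degenerate_roi")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).",
          class = "hetpet_input_error")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "roi_mask"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; SUV range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; ", sum(x$voxels), " foreground voxels (",
      signif(mtv(x), 4), " mL)\n", sep = "")
  invisible(x)
}

check_congruent <- function(volume, mask) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    abort("Volume and mask grids are not congruent.",
          class = "hetpet_input_error")
  }
  invisible(TRUE)
}

#' Read / write SUV volumes and ROI masks as NIfTI
#'
#' Thin wrappers around RNifti. Spacing is taken from (written to) the
#' NIfTI `pixdim` header field; the array axis order is preserved.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_suv_nifti()` returns an [suv_volume()];
#'   `read_mask_nifti()` an [roi_mask()] (voxels > 0.5 are foreground).
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  suv_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_suv_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(as.array(img) > 0.5, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_suv_nifti
#' @param x An [suv_volume()] or [roi_mask()].
#' @export
write_nifti <- function(x, path) {
  arr <- x$voxels
  if (is.logical(arr)) {
    mode(arr) <- "integer"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
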