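#' Construct a contrast-phase CT volume
#'
#' A `phase_volume` holds one 3D intensity grid (HU-like units) together
#' with its voxel spacing and the contrast-phase label.  Axis order is
#' (x, y, z) with 1-based voxel indices; `spacing` is in millimetres in
#' the same axis order.  No resampling is ever performed: companion masks
#' must share the grid exactly.
#'
#' @param voxels 3D numeric array of intensities; all values finite.
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param phase one of `"arterial"`, `"portal_venous"`, `"parenchymal"`.
#' @return An object of class `phase_volume` with elements `voxels`,
#'   `spacing`, `phase`.
#' @seealso [roi_mask()], [extract_roi()], [read_volume()]
#' @export
phase_volume <- function(voxels, spacing = c(1, 1, 1),
                         phase = c("arterial", "portal_venous", "parenchymal")) {
  phase <- match.arg(phase)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, phase = phase),
            class = "phase_volume")
}

#' Construct a binary tumor ROI mask
#'
#' The mask shares the grid of its companion [phase_volume()] (same array
#' dimensions and spacing) and must contain at least one foreground voxel.
#'
#' @param voxels 3D array coercible to 0/1.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `roi_mask` with elements `voxels`
#'   (integer 0/1 array) and `spacing`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  vals <- unique(as.vector(voxels))
  if (!all(vals %in% c(0, 1)))
    stop("mask must be binary (0/1); found values: ",
         paste(utils::head(sort(vals), 5), collapse = ", "))
  if (!any(voxels == 1))
    stop("mask has no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = spacing), class = "roi_mask")
}

#' @export
print.phase_volume <- function(x, ...) {
  cat(sprintf("<phase_volume> %s, %s voxels, spacing %s mm\n", x$phase,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d foreground voxels\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop(sprintf("mask grid (%s) does not match volume grid (%s)",
                 paste(dim(mask$voxels), collapse = "x"),
                 paste(dim(volume$voxels), collapse = "x")))
  if (!isTRUE(all.equal(volume$spacing, mask$spacing, tolerance = 1e-6)))
    stop("mask spacing does not match volume spacing")
  invisible(TRUE)
}

#' Write / read volumes and masks as NIfTI-1
#'
#' Volumes and masks round-trip through gzipped NIfTI-1 files via the
#' RNifti backend; grid dimensions and voxel spacing are preserved.  On
#' reading a mask, values are coerced to 0/1 only when exactly two
#' distinct values `{0, v}` are present; anything else is rejected.
#'
#' @param volume,mask the object to write.
#' @param path file path (conventionally `.nii.gz`).
#' @param phase phase label to attach to a volume read from file.
#' @return `read_volume()` a [phase_volume()]; `read_mask()` a
#'   [roi_mask()]; the writers return `path` invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "phase_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path, phase = "portal_venous") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  phase_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[seq_len(3)], phase = phase)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  vals <- sort(unique(as.vector(vox)))
  if (length(vals) > 2L)
    stop(sprintf("mask file %s has %d distinct values (%s ...); expected {0, v}",
                 path, length(vals), paste(utils::head(vals, 3), collapse = ", ")))
  if (length(vals) == 2L) {
    if (vals[1] != 0)
      stop("mask file ", path, " has two values but neither is 0")
    vox <- (vox == vals[2]) + 0
  } else if (vals[1] != 0 && vals[1] != 1) {
    stop("constant mask file ", path, " with value ", vals[1])
  }
  roi_mask(vox, spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Extract the ROI voxel set from an aligned volume/mask pair
#'
#' Returns the intensities and integer voxel coordinates of every
#' mask-foreground voxel, together with the ROI bounding box.  The result
#' is the unit all intensity and texture features are computed from, and
#' is by construction invariant to voxel values outside the mask.
#'
#' @param volume a [phase_volume()].
#' @param mask an aligned [roi_mask()] (same grid and spacing).
#' @return An object of class `roi_patch`: `values` (intensities),
#'   `positions` (n x 3 integer matrix of voxel indices), `bounding_box`
#'   (2 x 3 matrix of index ranges), `spacing`.
#' @export
extract_roi <- function(volume, mask) {
  stopifnot(inherits(volume, "phase_volume"), inherits(mask, "roi_mask"))
  check_aligned(volume, mask)
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground voxels")
  structure(list(
    values = as.numeric(volume$voxels[idx]),
    positions = idx,
    bounding_box = apply(idx, 2, range),
    spacing = volume$spacing
  ), class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> %d voxels, intensity range [%.3g, %.3g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
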