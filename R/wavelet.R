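# One-level undecimated (stationary) 3D wavelet decomposition.
#
# Filters are the Coiflet-1 analysis pair rescaled to unit DC gain
# (low-pass taps sum to 1), so the LLL band of a constant volume is that
# constant and every band containing a high-pass factor of a constant is
# exactly zero.  Boundary handling is periodic.

coif1_lo <- c(-0.0156557281354645, -0.0727326195128539, 0.3848648468642029,
              0.8525720202122554, 0.3378976624578092, -0.0727326195128539) / sqrt(2)
coif1_hi <- c(0.0727326195128539, 0.3378976624578092, -0.8525720202122554,
              0.3848648468642029, 0.0727326195128539, -0.0156557281354645) / sqrt(2)

apply_filter_axis <- function(x, kernel, axis) {
  acc <- array(0, dim(x))
  for (k in seq_along(kernel)) {
    if (kernel[k] != 0) acc <- acc + kernel[k] * shift3d(x, axis, k - 1L)
  }
  acc
}

#' One-level undecimated 3D wavelet decomposition
#'
#' Applies the separable stationary (undecimated) wavelet transform along
#' the three axes of a volume, yielding all eight low-/high-pass
#' combinations `LLL ... HHH`, each the same shape as the input.  The
#' basis is Coiflet-1 with periodic boundary extension; the low-pass
#' filter is scaled to unit DC gain so `LLL` preserves local mean
#' intensity and acts as a smoother (it strictly reduces the variance of
#' white noise), while the seven bands with a high-pass factor vanish on
#' constant volumes.
#'
#' @param volume a [phase_volume()] or a 3D numeric array with at least 8
#'   voxels per axis.
#' @return Object of class `wavelet_bands`: a named list of eight 3D
#'   arrays, labels `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH` (letter k is
#'   the filter on axis k: L = low-pass, H = high-pass).
#' @export
undecimated_wavelet3d <- function(volume) {
  x <- if (inherits(volume, "phase_volume")) volume$voxels else as.array(volume)
  d <- dim(x)
  if (length(d) != 3L) stop("input must be a 3D array")
  if (any(d < 8L))
    stop("grid must be at least 8 voxels per axis for the length-6 filter")
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- vector("list", 8L)
  names(bands) <- labels
  for (lab in labels) {
    flags <- strsplit(lab, "")[[1]]
    y <- x
    for (axis in 1:3) {
      kern <- if (flags[axis] == "L") coif1_lo else coif1_hi
      y <- apply_filter_axis(y, kern, axis)
    }
    bands[[lab]] <- y
  }
  structure(bands, class = "wavelet_bands")
}

#' @export
print.wavelet_bands <- function(x, ...) {
  cat(sprintf("<wavelet_bands> 8 bands of %s voxels\n",
              paste(dim(x[[1]]), collapse = "x")))
  invisible(x)
}
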