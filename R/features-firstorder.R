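#' Quantize ROI intensities into gray levels
#'
#' Equal-width binning of the ROI intensity range `[min, max]` into
#' `n_bins` levels: the minimum maps to level 1, the maximum to level
#' `n_bins`.  A constant ROI maps every voxel to level 1 (degenerate-range
#' rule).  Because binning is range-based, all downstream texture features
#' are invariant to adding a constant to every ROI voxel.
#'
#' @param patch an `roi_patch` from [extract_roi()].
#' @param n_bins number of gray levels (>= 2); default 32.
#' @return Object of class `quantized_roi`: `levels` (integer per ROI
#'   voxel, in `1..n_bins`), `n_bins`, `positions` (bounding-box-local,
#'   1-based), `grid` (bounding-box array of levels, `NA` outside the
#'   ROI), `spacing`.
#' @export
quantize <- function(patch, n_bins = 32L) {
  stopifnot(inherits(patch, "roi_patch"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  v <- patch$values
  rng <- range(v)
  if (rng[2] > rng[1]) {
    lev <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  } else {
    lev <- rep(1L, length(v))
  }
  bb <- patch$bounding_box
  pos <- sweep(patch$positions, 2, bb[1, ] - 1L)   # 1-based in the bbox
  dims <- bb[2, ] - bb[1, ] + 1L
  grid <- array(NA_integer_, dims)
  grid[pos] <- as.integer(lev)
  structure(list(levels = as.integer(lev), n_bins = as.integer(n_bins),
                 positions = pos, grid = grid, spacing = patch$spacing),
            class = "quantized_roi")
}

#' First-order (histogram) intensity features
#'
#' Fourteen descriptors of the ROI intensity distribution.  Moments use
#' the population convention (denominator n); `entropy` (bits) and
#' `uniformity` are computed on the equal-width quantized histogram.
#' Degenerate rules: a constant ROI has variance 0, skewness 0,
#' kurtosis 0, entropy 0 and uniformity 1.
#'
#' @param patch an `roi_patch`.
#' @param n_bins histogram bins for entropy/uniformity (default 32).
#' @return Named numeric vector of length 14.
#' @export
intensity_features <- function(patch, n_bins = 32L) {
  v <- patch$values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  p <- tabulate(quantize(patch, n_bins)$levels, nbins = n_bins) / n
  p <- p[p > 0]
  c(mean = mu,
    median = stats::median(v),
    min = min(v),
    max = max(v),
    range = diff(range(v)),
    variance = m2,
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(v^2),
    rms = sqrt(mean(v^2)),
    mad = mean(abs(v - mu)),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2))
}

#' Shape and size features of a tumor ROI
#'
#' Eight morphological descriptors computed from the binary mask alone
#' (invariant to image intensities): physical volume, voxel-face surface
#' area, their ratio, sphericity and two compactness variants, spherical
#' disproportion, and the maximum 3D diameter (largest pairwise distance
#' between foreground voxel centers, in mm).
#'
#' `surface_mm2` counts exposed voxel faces (exact for axis-aligned
#' boxes).  Face counting overestimates the area of smooth surfaces by a
#' factor 3/2 (the average of `|nx|+|ny|+|nz|` over orientations), so the
#' dimensionless descriptors (sphericity, compactness, spherical
#' disproportion) use the isotropy-corrected estimate `2/3 * surface_mm2`;
#' a digitized sphere then scores sphericity close to the analytic 1.
#'
#' @param mask an [roi_mask()].
#' @return Named numeric vector of length 8: `volume_mm3`,
#'   `surface_mm2`, `surface_to_volume`, `sphericity`, `compactness1`,
#'   `compactness2`, `spherical_disproportion`, `max_diameter_mm`.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$voxels
  sp <- mask$spacing
  nvox <- sum(m)
  vol <- nvox * prod(sp)

  # exposed faces per axis: foreground voxels whose neighbor along the
  # axis (either way) is background or outside the grid
  d <- dim(m)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  surf <- 0
  for (axis in 1:3) {
    pad <- array(0L, dim = d + c(axis == 1, axis == 2, axis == 3) * 2L)
    idx <- lapply(1:3, function(a) seq_len(d[a]) + (a == axis))
    pad[idx[[1]], idx[[2]], idx[[3]]] <- m
    up <- shift3d(pad, axis, 1L)
    down <- shift3d(pad, axis, -1L)
    exposed <- sum(pad == 1L & up == 0L) + sum(pad == 1L & down == 0L)
    surf <- surf + exposed * face_area[axis]
  }

  r_equiv <- (3 * vol / (4 * pi))^(1 / 3)
  surf_c <- 2 / 3 * surf          # isotropy-corrected smooth-surface estimate
  out <- c(
    volume_mm3 = vol,
    surface_mm2 = surf,
    surface_to_volume = surf / vol,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / surf_c,
    compactness1 = vol / (sqrt(pi) * surf_c^1.5),
    compactness2 = 36 * pi * vol^2 / surf_c^3,
    spherical_disproportion = surf_c / (4 * pi * r_equiv^2),
    max_diameter_mm = max_diameter(m, sp)
  )
  out
}

# Maximum pairwise distance between foreground voxel centers (mm).
# Exact for moderate boundary sets; for very large ROIs the candidate set
# is first reduced to directional extreme points (deterministic Fibonacci
# sphere of projection directions), which preserves the diameter to
# voxel precision.
max_diameter <- function(m, sp) {
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(0)
  # restrict to boundary voxels (those with an exposed 6-face)
  nb <- neighbor_count6(m)
  bidx <- which(m == 1L & nb < 6L, arr.ind = TRUE)
  pts <- sweep(bidx, 2, sp, `*`)
  if (nrow(pts) > 3000L) {
    ndir <- 200L
    i <- seq_len(ndir)
    phi <- acos(1 - 2 * (i - 0.5) / ndir)
    theta <- pi * (1 + sqrt(5)) * i
    dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    proj <- pts %*% t(dirs)
    keep <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}
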