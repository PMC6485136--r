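# Scalar descriptors computed from the four texture matrices.
# Gray levels are indexed 1..n_bins; logs are base 2.

#' GLCM texture descriptors
#'
#' Twenty-two standard descriptors of the normalized, symmetrized
#' co-occurrence matrix.  Degenerate rules: with a single occupied level
#' the marginal variance is 0 and `correlation` is defined as 1;
#' information measures with zero marginal entropy are 0;
#' `inverse_variance` sums over off-diagonal entries only.
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(q) {
  P <- glcm_matrix(q, normalize = TRUE)
  nb <- nrow(P)
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)     # equal by symmetry
  mux <- sum(seq_len(nb) * px); muy <- sum(seq_len(nb) * py)
  sdx <- sqrt(sum((seq_len(nb) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(nb) - muy)^2 * py))
  nz <- P > 0

  # diagonal (difference) and cross-diagonal (sum) distributions
  pd <- vapply(0:(nb - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * nb), function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(nb - 1); ksum <- 2:(2 * nb)
  da <- sum(kd * pd)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- ent(px); HXY <- ent(as.vector(P))
  lpx <- matrix(px[seq_len(nb)], nb, nb)
  lpy <- t(lpx)
  HXY1 <- -sum(P[nz] * log2((lpx * lpy)[nz]))
  q2 <- lpx * lpy
  HXY2 <- -sum(q2[q2 > 0] * log2(q2[q2 > 0]))

  c(autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sdx > 0 && sdy > 0)
      (sum(i * j * P) - mux * muy) / (sdx * sdy) else 1,
    difference_average = da,
    difference_entropy = ent(pd),
    difference_variance = sum((kd - da)^2 * pd),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = HXY,
    homogeneity = sum(P / (1 + abs(i - j))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / nb^2)),
    idn = sum(P / (1 + abs(i - j) / nb)),
    imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    inverse_variance = sum((P / pmax((i - j)^2, 1))[i != j]),
    max_probability = max(P),
    sum_average = sum(ksum * ps),
    sum_entropy = ent(ps))
}

#' GLRLM texture descriptors
#'
#' Sixteen run-length statistics over the direction-aggregated run-length
#' matrix.  `run_percentage` divides the total run count by the number of
#' ROI voxels times the 13 directions (each voxel starts at most one run
#' per direction).
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(q) {
  R <- glrlm_matrix(q)
  Nr <- sum(R)
  Np <- length(q$levels)
  lev <- seq_len(nrow(R)); len <- seq_len(ncol(R))
  ri <- rowSums(R); rl <- colSums(R)
  Li <- matrix(lev, nrow(R), ncol(R))
  Ll <- matrix(len, nrow(R), ncol(R), byrow = TRUE)
  p <- R / Nr
  mu_l <- sum(Li * p); mu_r <- sum(Ll * p)
  pr <- p[p > 0]
  c(short_run_emphasis = sum(R / Ll^2) / Nr,
    long_run_emphasis = sum(R * Ll^2) / Nr,
    gray_level_nonuniformity = sum(ri^2) / Nr,
    gray_level_nonuniformity_normalized = sum(ri^2) / Nr^2,
    run_length_nonuniformity = sum(rl^2) / Nr,
    run_length_nonuniformity_normalized = sum(rl^2) / Nr^2,
    run_percentage = Nr / (Np * 13),
    gray_level_variance = sum((Li - mu_l)^2 * p),
    run_length_variance = sum((Ll - mu_r)^2 * p),
    run_entropy = -sum(pr * log2(pr)),
    low_gray_level_run_emphasis = sum(R / Li^2) / Nr,
    high_gray_level_run_emphasis = sum(R * Li^2) / Nr,
    short_run_low_gray_level_emphasis = sum(R / (Li^2 * Ll^2)) / Nr,
    short_run_high_gray_level_emphasis = sum(R * Li^2 / Ll^2) / Nr,
    long_run_low_gray_level_emphasis = sum(R * Ll^2 / Li^2) / Nr,
    long_run_high_gray_level_emphasis = sum(R * Li^2 * Ll^2) / Nr)
}

#' GLSZM texture descriptors
#'
#' Fourteen size-zone statistics over 26-connected equal-level zones.
#' `zone_percentage` is the zone count divided by the ROI voxel count.
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 14.
#' @export
glszm_features <- function(q) {
  Z <- glszm_matrix(q)
  Nz <- sum(Z)
  Np <- length(q$levels)
  lev <- seq_len(nrow(Z)); sz <- seq_len(ncol(Z))
  zi <- rowSums(Z); zs <- colSums(Z)
  Li <- matrix(lev, nrow(Z), ncol(Z))
  Ls <- matrix(sz, nrow(Z), ncol(Z), byrow = TRUE)
  p <- Z / Nz
  mu_l <- sum(Li * p); mu_s <- sum(Ls * p)
  pz <- p[p > 0]
  c(small_area_emphasis = sum(Z / Ls^2) / Nz,
    large_area_emphasis = sum(Z * Ls^2) / Nz,
    gray_level_nonuniformity = sum(zi^2) / Nz,
    gray_level_nonuniformity_normalized = sum(zi^2) / Nz^2,
    size_zone_nonuniformity = sum(zs^2) / Nz,
    size_zone_nonuniformity_normalized = sum(zs^2) / Nz^2,
    zone_percentage = Nz / Np,
    gray_level_variance = sum((Li - mu_l)^2 * p),
    zone_size_variance = sum((Ls - mu_s)^2 * p),
    zone_entropy = -sum(pz * log2(pz)),
    low_gray_level_zone_emphasis = sum(Z / Li^2) / Nz,
    high_gray_level_zone_emphasis = sum(Z * Li^2) / Nz,
    small_area_low_gray_level_emphasis = sum(Z / (Li^2 * Ls^2)) / Nz,
    small_area_high_gray_level_emphasis = sum(Z * Li^2 / Ls^2) / Nz)
}

#' NGTDM texture descriptors
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' neighborhood gray-tone difference table (26-voxel neighborhoods).
#' Degenerate rules: a single-level ROI has contrast, busyness,
#' complexity and strength 0; coarseness, whose definition diverges
#' there, is capped at 1e6.
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(q) {
  tb <- ngtdm_table(q)
  s <- tb$s; p <- tb$p
  N <- sum(tb$n)
  act <- which(p > 0)
  ngp <- length(act)
  lev <- seq_along(p)

  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse > 0) min(1 / denom_coarse, 1e6) else 1e6

  if (ngp <= 1 || N == 0) {
    return(c(coarseness = coarseness, contrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  }
  ii <- matrix(lev[act], ngp, ngp)
  jj <- t(ii)
  pi_ <- matrix(p[act], ngp, ngp)
  pj_ <- t(pi_)
  si <- matrix(s[act], ngp, ngp)
  sj <- t(si)

  contrast <- sum(pi_ * pj_ * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / N
  bus_den <- sum(abs(ii * pi_ - jj * pj_))
  busyness <- if (bus_den > 0) sum(p * s) / bus_den else 0
  complexity <- sum(abs(ii - jj) * (pi_ * si + pj_ * sj) / (pi_ + pj_)) / N
  strength <- if (sum(s) > 0) sum((pi_ + pj_) * (ii - jj)^2) / sum(s) else 0

  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
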