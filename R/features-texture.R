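# The four texture-matrix families, computed on a quantized ROI.
#
# Conventions (fixed and documented here once):
#  * 13 unique 3D direction offsets at Chebyshev distance 1; GLCM and
#    GLRLM accumulate counts over all 13 before descriptors are computed.
#  * GLCM is symmetrized (each pair counted both ways) and normalized.
#  * GLSZM zones are 26-connected components of equal gray level.
#  * NGTDM neighborhoods are the 26 surrounding voxels restricted to the
#    ROI; voxels with no ROI neighbor are excluded.
#  * Degenerate rules (never NaN): single-level ROIs give entropy 0,
#    GLCM correlation 1, information measures 0, NGTDM contrast /
#    busyness / strength 0 and coarseness capped at 1e6.

# the 13 unique 3D offsets (one representative per +/- direction pair)
direction_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
  as.matrix(offs[keep, , drop = FALSE])
}

# subarray views of `grid` displaced by `off`, clipped to the grid
offset_pairs <- function(grid, off) {
  d <- dim(grid)
  r1 <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(integer(0))
    lo:hi
  })
  if (any(lengths(r1) == 0L)) return(NULL)
  r2 <- lapply(1:3, function(a) r1[[a]] + off[a])
  a <- grid[r1[[1]], r1[[2]], r1[[3]]]
  b <- grid[r2[[1]], r2[[2]], r2[[3]]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

#' Gray-level co-occurrence matrix
#'
#' Co-occurrence counts accumulated over the 13 unique 3D directions at
#' distance 1, symmetrized (so the matrix equals its transpose) and, if
#' `normalize`, scaled to sum to 1.
#'
#' @param q a [quantize()]d ROI.
#' @param normalize return probabilities rather than counts.
#' @return `n_bins x n_bins` matrix.
#' @export
glcm_matrix <- function(q, normalize = TRUE) {
  nb <- q$n_bins
  offs <- direction_offsets()
  M <- matrix(0, nb, nb)
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(q$grid, offs[k, ])
    if (is.null(pr)) next
    tab <- tabulate((pr[, 1] - 1L) * nb + pr[, 2], nbins = nb * nb)
    M <- M + matrix(tab, nb, nb, byrow = TRUE)
  }
  M <- M + t(M)
  if (normalize && sum(M) > 0) M <- M / sum(M)
  M
}

#' Gray-level run-length matrix
#'
#' Counts of maximal same-level runs of ROI voxels, accumulated over the
#' 13 unique 3D directions; a gap in the ROI breaks a run.  Rows index
#' gray level, columns run length.
#'
#' @param q a [quantize()]d ROI.
#' @return `n_bins x max_run` count matrix.
#' @export
glrlm_matrix <- function(q) {
  pos <- q$positions
  lev <- q$levels
  offs <- direction_offsets()
  runs_level <- integer(0)
  runs_len <- integer(0)
  big <- max(dim(q$grid)) + 2L
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    a <- which(d != 0)[1]
    t <- pos[, a] * d[a]                       # strictly increasing along the ray
    other <- setdiff(1:3, a)
    key <- 0
    for (j in other) key <- key * (4 * big) + (pos[, j] - t * d[j] + 2 * big)
    o <- order(key, t)
    ks <- key[o]; ts <- t[o]; ls <- lev[o]
    newrun <- c(TRUE, ks[-1] != ks[-length(ks)] |
                      ts[-1] != ts[-length(ts)] + 1L |
                      ls[-1] != ls[-length(ls)])
    starts <- which(newrun)
    lens <- diff(c(starts, length(ks) + 1L))
    runs_level <- c(runs_level, ls[starts])
    runs_len <- c(runs_len, lens)
  }
  maxlen <- max(runs_len)
  nb <- q$n_bins
  matrix(tabulate((runs_len - 1L) * nb + runs_level, nbins = nb * maxlen),
         nb, maxlen)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of ROI voxels sharing one gray
#' level; entry (i, s) counts zones of level i and size s voxels.
#'
#' @param q a [quantize()]d ROI.
#' @return `n_bins x max_zone_size` count matrix.
#' @export
glszm_matrix <- function(q) {
  grid <- q$grid
  d <- dim(grid)
  n <- prod(d)
  lin <- which(!is.na(grid))
  # linear id per bbox voxel; edges between 26-adjacent equal-level voxels
  edges <- list()
  offs <- direction_offsets()
  id_grid <- array(NA_integer_, d)
  id_grid[lin] <- seq_along(lin)
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    r1 <- lapply(1:3, function(a) {
      lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
      if (lo > hi) return(integer(0))
      lo:hi
    })
    if (any(lengths(r1) == 0L)) next
    r2 <- lapply(1:3, function(a) r1[[a]] + off[a])
    a_lev <- grid[r1[[1]], r1[[2]], r1[[3]]]
    b_lev <- grid[r2[[1]], r2[[2]], r2[[3]]]
    a_id <- id_grid[r1[[1]], r1[[2]], r1[[3]]]
    b_id <- id_grid[r2[[1]], r2[[2]], r2[[3]]]
    ok <- !is.na(a_lev) & !is.na(b_lev) & a_lev == b_lev
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(a_id[ok], b_id[ok])
  }
  nv <- length(lin)
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(nv)]
  } else {
    comp <- seq_len(nv)
  }
  lev_vox <- grid[lin]
  zone_size <- tabulate(comp)
  zone_level <- lev_vox[match(seq_along(zone_size), comp)]
  nb <- q$n_bins
  matrix(tabulate((zone_size - 1L) * nb + zone_level,
                  nbins = nb * max(zone_size)),
         nb, max(zone_size))
}

#' Neighborhood gray-tone difference table
#'
#' For every ROI voxel with at least one ROI voxel among its 26
#' neighbors, the absolute difference between its level and the mean
#' level of those neighbors is accumulated per gray level.
#'
#' @param q a [quantize()]d ROI.
#' @return list with `s` (per-level summed absolute differences), `n`
#'   (per-level voxel counts), `p` (level probabilities among valid
#'   voxels).
#' @export
ngtdm_table <- function(q) {
  grid <- q$grid
  d <- dim(grid)
  val <- grid; val[is.na(grid)] <- 0L
  inroi <- !is.na(grid)
  # padded full 26-neighbor sums without wrap-around
  pd <- d + 2L
  vp <- array(0, pd); vp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- val
  cp <- array(0, pd); cp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- inroi
  nsum <- array(0, pd); ncnt <- array(0, pd)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- shift3d(vp, 1, dx); s <- shift3d(s, 2, dy); s <- shift3d(s, 3, dz)
    c2 <- shift3d(cp, 1, dx); c2 <- shift3d(c2, 2, dy); c2 <- shift3d(c2, 3, dz)
    nsum <- nsum + s
    ncnt <- ncnt + c2
  }
  nsum <- nsum[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  ncnt <- ncnt[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  valid <- inroi & ncnt > 0
  lev <- grid[valid]
  diffs <- abs(as.numeric(grid[valid]) - nsum[valid] / ncnt[valid])
  nb <- q$n_bins
  s <- numeric(nb)
  if (length(lev)) {
    agg <- rowsum(diffs, lev)
    s[as.integer(rownames(agg))] <- agg
  }
  nct <- tabulate(lev, nbins = nb)
  list(s = s, n = as.numeric(nct),
       p = if (sum(nct) > 0) nct / sum(nct) else as.numeric(nct))
}
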