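# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately written from the definitions, not by
# calling package internals, so oracle and implementation stay separate.

# --- fixtures -------------------------------------------------------------

# quantized_roi built directly from a level array (NA = outside ROI)
q_from_array <- function(lev_array, n_bins = max(lev_array, na.rm = TRUE)) {
  pos <- which(!is.na(lev_array), arr.ind = TRUE)
  structure(list(levels = as.integer(lev_array[pos]),
                 n_bins = as.integer(n_bins),
                 positions = pos, grid = lev_array,
                 spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

ball_mask <- function(r_vox, dim = 2L * r_vox + 5L, spacing = c(1, 1, 1)) {
  ax <- seq_len(dim) - (dim + 1) / 2
  dist2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  roi_mask((dist2 <= r_vox^2) + 0L, spacing)
}

# the 26 neighbor offsets / their 13 unique representatives
all_offsets26 <- local({
  g <- expand.grid(-1:1, -1:1, -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
})
unique_offsets13 <- all_offsets26[all_offsets26[, 3] > 0 |
  (all_offsets26[, 3] == 0 & (all_offsets26[, 2] > 0 |
   (all_offsets26[, 2] == 0 & all_offsets26[, 1] > 0))), ]

in_grid <- function(p, d) all(p >= 1L & p <= d)

# --- texture-matrix oracles (exhaustive enumeration) ----------------------

oracle_glcm <- function(lev, n_bins, normalize = TRUE) {
  d <- dim(lev)
  M <- matrix(0, n_bins, n_bins)
  pos <- which(!is.na(lev), arr.ind = TRUE)
  for (i in seq_len(nrow(pos))) {
    for (k in seq_len(nrow(all_offsets26))) {
      p2 <- pos[i, ] + all_offsets26[k, ]
      if (in_grid(p2, d) && !is.na(lev[p2[1], p2[2], p2[3]])) {
        a <- lev[pos[i, 1], pos[i, 2], pos[i, 3]]
        b <- lev[p2[1], p2[2], p2[3]]
        M[a, b] <- M[a, b] + 1
      }
    }
  }
  if (normalize && sum(M) > 0) M <- M / sum(M)
  M
}

oracle_glrlm <- function(lev, n_bins) {
  d <- dim(lev)
  runs <- list()
  for (k in seq_len(nrow(unique_offsets13))) {
    dir <- unique_offsets13[k, ]
    pos <- which(!is.na(lev), arr.ind = TRUE)
    for (i in seq_len(nrow(pos))) {
      p <- pos[i, ]
      prev <- p - dir
      v <- lev[p[1], p[2], p[3]]
      # run starts here iff the previous voxel is not an in-ROI same-level voxel
      starts <- !(in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
                    lev[prev[1], prev[2], prev[3]] == v)
      if (!starts) next
      len <- 1L
      np <- p + dir
      while (in_grid(np, d) && !is.na(lev[np[1], np[2], np[3]]) &&
               lev[np[1], np[2], np[3]] == v) {
        len <- len + 1L
        np <- np + dir
      }
      runs[[length(runs) + 1L]] <- c(v, len)
    }
  }
  runs <- do.call(rbind, runs)
  R <- matrix(0, n_bins, max(runs[, 2]))
  for (i in seq_len(nrow(runs))) R[runs[i, 1], runs[i, 2]] <-
      R[runs[i, 1], runs[i, 2]] + 1
  R
}

oracle_glszm <- function(lev, n_bins) {
  d <- dim(lev)
  pos <- which(!is.na(lev), arr.ind = TRUE)
  visited <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(nrow(pos))) {
    p0 <- pos[i, ]
    if (visited[p0[1], p0[2], p0[3]]) next
    v <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    visited[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(all_offsets26))) {
        q <- p + all_offsets26[k, ]
        if (in_grid(q, d) && !visited[q[1], q[2], q[3]] &&
              !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == v) {
          visited[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(v, size)
  }
  zones <- do.call(rbind, zones)
  Z <- matrix(0, n_bins, max(zones[, 2]))
  for (i in seq_len(nrow(zones))) Z[zones[i, 1], zones[i, 2]] <-
      Z[zones[i, 1], zones[i, 2]] + 1
  Z
}

oracle_ngtdm <- function(lev, n_bins) {
  d <- dim(lev)
  pos <- which(!is.na(lev), arr.ind = TRUE)
  s <- numeric(n_bins); n <- numeric(n_bins)
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    nb <- c()
    for (k in seq_len(nrow(all_offsets26))) {
      q <- p + all_offsets26[k, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]))
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    v <- lev[p[1], p[2], p[3]]
    s[v] <- s[v] + abs(v - mean(nb))
    n[v] <- n[v] + 1
  }
  list(s = s, n = n, p = if (sum(n) > 0) n / sum(n) else n)
}

# --- statistics oracles ----------------------------------------------------

# ICC(2,1) mean squares from a two-way lm fit (independent of the
# package's direct-sum computation)
oracle_icc21 <- function(test, retest) {
  n <- length(test)
  dat <- data.frame(y = c(test, retest),
                    subject = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  an <- anova(lm(y ~ subject + rater, data = dat))
  msr <- an["subject", "Mean Sq"]
  msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# all-pairs Harrell concordance
oracle_concordance <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # orient so a is the shorter observed time
    if (time[i] <= time[j]) { a <- i; b <- j } else { a <- j; b <- i }
    if (time[a] == time[b]) {
      usable <- FALSE   # tied observed times are never usable here
    } else usable <- event[a] == 1
    if (!usable) next
    den <- den + 1
    if (risk[a] > risk[b]) num <- num + 1
    else if (risk[a] == risk[b]) num <- num + 0.5
  }
  num / den
}

# Breslow log partial likelihood written from the definition
oracle_coxpl <- function(beta, x, time, event) {
  lp <- x * beta
  ll <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + lp[i] - log(sum(exp(lp[rs])))
  }
  ll
}

# step-by-step greedy mRMR with the closed-form Gaussian MI
oracle_mrmr <- function(X, y, k) {
  mi <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    r <- max(min(cor(a, b), 1 - 1e-12), -(1 - 1e-12))
    -0.5 * log(1 - r^2)
  }
  nms <- colnames(X)
  rel <- vapply(nms, function(f) mi(X[, f], y), numeric(1))
  chosen <- character(0)
  for (s in seq_len(k)) {
    cand <- setdiff(nms, chosen)
    crit <- vapply(cand, function(f) {
      red <- if (length(chosen))
        mean(vapply(chosen, function(g) mi(X[, f], X[, g]), numeric(1))) else 0
      rel[f] - red
    }, numeric(1))
    best <- crit == max(crit)
    chosen <- c(chosen, sort(cand[best])[1])
  }
  chosen
}
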