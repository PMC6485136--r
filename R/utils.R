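# Internal helpers shared across modules.

# Circularly shift a 3D array along one axis by `by` voxels (periodic wrap).
shift3d <- function(x, axis, by) {
  d <- dim(x)
  n <- d[axis]
  by <- ((by %% n) + n) %% n
  if (by == 0L) return(x)
  idx <- c(seq_len(n - by) + by, seq_len(by))
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

# Separable periodic convolution of a 3D array with one 1D kernel applied
# along every axis.  `origin` is the kernel tap aligned with the output
# voxel (1-based).
conv3d_separable <- function(x, kernel, origin = 1L) {
  for (axis in 1:3) {
    acc <- array(0, dim(x))
    for (k in seq_along(kernel)) {
      if (kernel[k] != 0)
        acc <- acc + kernel[k] * shift3d(x, axis, k - origin)
    }
    x <- acc
  }
  x
}

# Smooth white noise into a stationary Gaussian random field with unit
# variance and Gaussian correlation length `ell` (voxels).
gaussian_random_field <- function(dims, ell) {
  noise <- array(stats::rnorm(prod(dims)), dims)
  if (ell <= 0) return(noise)
  r <- max(1L, ceiling(2.5 * ell))
  k <- exp(-(seq(-r, r))^2 / (2 * ell^2))
  k <- k / sum(k)
  sm <- conv3d_separable(noise, k, origin = r + 1L)
  sm / sqrt(sum(k^2)^3)   # unit marginal variance after smoothing
}

# Deterministic child seed derived from a master seed and a stage label,
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run a glmnet call, silencing only its path-truncation warning
muffle_path_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("Numerical error at .*lambda value", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
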