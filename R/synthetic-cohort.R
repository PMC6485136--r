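#' Simulation configuration for synthetic ablation cohorts
#'
#' Bundles every knob of the synthetic cohort generator: cohort size,
#' covariate marginals, the Cox log-hazard coefficients that link
#' covariates and intra-tumor texture heterogeneity to recurrence, the
#' Weibull baseline hazard, the censoring mechanism, image geometry, and
#' the test-retest perturbation magnitudes.
#'
#' Covariate marginals default to the frequencies of a published HCC
#' ablation cohort: ~74% male, ~82% HBV etiology, BCLC stage A ~63%,
#' Child-Pugh class A ~95%, age ~N(57, 9) truncated to 18-75 years,
#' tumor diameter log-normal with median 3.3 cm (IQR 2.5-4.7), AFP
#' log-normal with median 14.2 ng/mL (IQR 3.6-144.3).
#'
#' Survival is Cox with Weibull baseline `S0(t) = exp(-(t/scale)^shape)`
#' (time in months) and censoring `min(Exp(rate) random censor,
#' administrative horizon)`; the 84-month default horizon reflects a
#' follow-up floor of more than 3 years.
#'
#' @param n_patients cohort size (>= 2).
#' @param seed integer master seed; fixes the cohort bit-for-bit.
#' @param covariate_marginals named list of category probability vectors
#'   and numeric-distribution parameter lists; see defaults.
#' @param beta_clinical named numeric vector of log-hazard coefficients on
#'   the clinical design columns (see [clinical_design()]); unnamed
#'   covariates get 0.
#' @param gamma_texture log-hazard coefficient on the latent per-patient
#'   heterogeneity score (standard-normal scale).
#' @param weibull_shape,weibull_scale baseline Weibull parameters (> 0);
#'   scale in months.
#' @param censor_horizon administrative censoring horizon in months
#'   (`Inf` disables it).
#' @param censor_rate rate of the exponential random-censoring time per
#'   month (0 disables random censoring).
#' @param volume_dim edge length of the cubic image grid (voxels).
#' @param spacing isotropic voxel spacing in mm.
#' @param retest_noise_sd additive intensity noise (HU) applied to the
#'   retest copy of a scan.
#' @param retest_mask_voxels maximum boundary perturbation depth (voxels)
#'   of the retest re-segmentation; 0 disables it.
#' @param retest_flip_prob per-voxel flip probability on each boundary
#'   layer during retest mask perturbation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 184L,
                       seed = 1L,
                       covariate_marginals = default_marginals(),
                       beta_clinical = c(bclc_B = log(2.1), child_pugh_B = log(2.1)),
                       gamma_texture = 0.8,
                       weibull_shape = 1.1,
                       weibull_scale = 20,
                       censor_horizon = 84,
                       censor_rate = 1 / 60,
                       volume_dim = 64L,
                       spacing = 1,
                       retest_noise_sd = 5,
                       retest_mask_voxels = 1L,
                       retest_flip_prob = 0.2) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (weibull_shape <= 0 || weibull_scale <= 0)
    stop("Weibull shape and scale must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  m <- default_marginals()
  m[names(covariate_marginals)] <- covariate_marginals
  for (nm in names(m)) {
    if (is.numeric(m[[nm]]) && !is.null(names(m[[nm]]))) {
      p <- m[[nm]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("marginal probabilities for '", nm, "' must be >= 0 and sum to 1")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    covariate_marginals = m, beta_clinical = beta_clinical,
    gamma_texture = gamma_texture,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    censor_horizon = censor_horizon, censor_rate = censor_rate,
    volume_dim = as.integer(volume_dim), spacing = spacing,
    retest_noise_sd = retest_noise_sd,
    retest_mask_voxels = as.integer(retest_mask_voxels),
    retest_flip_prob = retest_flip_prob
  ), class = "sim_config")
}

#' Default covariate marginal distributions
#'
#' Category frequencies follow the training cohort of a published HCC
#' ablation series; continuous covariates are parameterised to match its
#' reported medians and interquartile ranges.
#'
#' @return Named list of marginal specifications.
#' @export
default_marginals <- function() {
  list(
    gender   = c(male = 0.736, female = 0.264),
    # age: normal(57, 9) truncated to the 18-75 eligibility window
    age      = list(mean = 57, sd = 9, lower = 18, upper = 75),
    # diameter (cm): log-normal, median 3.3, IQR 2.5-4.7
    tumor_diameter = list(meanlog = log(3.3), sdlog = log(4.7 / 2.5) / (2 * 0.6745)),
    grade    = c(I = 0.240, II = 0.512, III = 0.248),
    # AFP (ng/mL): log-normal, median 14.2, IQR 3.6-144.3
    afp      = list(meanlog = log(14.2), sdlog = log(144.3 / 3.6) / (2 * 0.6745)),
    etiology = c(alcohol = 0.054, HCV = 0.109, HBV = 0.821, `HBV+HCV` = 0.016),
    ecog     = c(`0` = 0.023, `1` = 0.977),
    ck19     = c(`0` = 0.829, `1` = 0.132, `2` = 0.008, `3` = 0.031),
    gpc3     = c(`0` = 0.310, `1` = 0.364, `3` = 0.194, `4` = 0.132),
    hbsag    = c(`0` = 0.574, `1` = 0.295, `2` = 0.093, `3` = 0.038),
    hbcag    = c(`0` = 0.938, `1` = 0.054, `2` = 0.008),
    child_pugh = c(A = 0.946, B = 0.054),
    bclc     = c(A = 0.628, B = 0.372),
    ablation = c(RFA = 0.667, MWA = 0.209, `CRYO-A` = 0.124)
  )
}

draw_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate recurrence-free survival times from a Cox-Weibull model
#'
#' Inverse-transform sampling: the event time is
#' `scale * (-log(U) / exp(lp))^(1/shape)` so the configured linear
#' predictor `lp` acts multiplicatively on the baseline hazard, i.e. the
#' proportional-hazards assumption holds by construction.  The observed
#' time is the minimum of the event time, an exponential random censoring
#' time, and the administrative horizon; the event indicator is 1 iff the
#' event time is the smallest.
#'
#' Uses the current R random-number stream; seed it (or call from
#' [generate_cohort()], which does) for reproducibility.
#'
#' @param linear_predictor numeric vector of Cox linear predictors
#'   (finite).
#' @param config a [sim_config()] supplying the Weibull baseline and
#'   censoring mechanism.
#' @return A data.frame with columns `rfs_time` (months, > 0) and
#'   `event` (0 censored / 1 recurrence).
#' @export
simulate_rfs <- function(linear_predictor, config) {
  if (!all(is.finite(linear_predictor)))
    stop("linear predictor must be finite")
  n <- length(linear_predictor)
  u <- stats::runif(n)
  t_event <- config$weibull_scale *
    (-log(u) / exp(linear_predictor))^(1 / config$weibull_shape)
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(n, rate = config$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, config$censor_horizon)
  data.frame(rfs_time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# Draw one tumor image set: shared ROI mask + three phase volumes whose
# intra-ROI texture is a Gaussian random field with patient-specific
# variance (sigma) and correlation length (ell).
simulate_patient_images <- function(config, sigma, ell, diameter_cm, enh_offset) {
  d <- config$volume_dim
  sp <- config$spacing
  dims <- c(d, d, d)
  centre <- (d + 1) / 2

  # ellipsoid radii (mm) jittered per axis, clamped to fit the grid
  r_mm <- pmin(diameter_cm * 10 / 2 * stats::runif(3, 0.85, 1.15),
               (d * sp) / 2 - 3 * sp)
  r_mm <- pmax(r_mm, 2 * sp)
  ax <- (seq_len(d) - centre) * sp
  dist2 <- outer(outer((ax / r_mm[1])^2, (ax / r_mm[2])^2, `+`),
                 (ax / r_mm[3])^2, `+`)
  # low-frequency radial perturbation lobes the boundary
  bump <- gaussian_random_field(dims, ell = 4)
  mask_arr <- (sqrt(dist2) <= 1 + 0.06 * bump) + 0L
  if (!any(mask_arr == 1L)) {  # degenerate jitter; fall back to pure ellipsoid
    mask_arr <- (dist2 <= 1) + 0L
  }
  mask <- roi_mask(mask_arr, spacing = rep(sp, 3))

  base <- 70 + 8 * gaussian_random_field(dims, ell = 3)  # liver-like background
  offsets <- c(arterial = 60, portal_venous = 25, parenchymal = 10)
  vols <- lapply(names(offsets), function(ph) {
    tex <- sigma * gaussian_random_field(dims, ell = ell)
    vox <- base + mask_arr * (offsets[[ph]] + enh_offset + tex)
    phase_volume(vox, spacing = rep(sp, 3), phase = ph)
  })
  names(vols) <- names(offsets)
  list(mask = mask, volumes = vols)
}

#' Generate a synthetic ablation cohort
#'
#' Draws `n_patients` records with clinical covariates at the configured
#' marginals, one tumor ROI mask shared by three contrast-phase volumes
#' per patient, a latent per-patient heterogeneity score (the texture
#' variance of the intra-ROI Gaussian random field, on a standard-normal
#' scale) and Cox-Weibull recurrence-free survival whose linear predictor
#' is `clinical design %*% beta_clinical + gamma_texture * heterogeneity`.
#' Fixing `config$seed` makes the whole cohort bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param images if `FALSE`, skip image synthesis (records only; faster
#'   for purely statistical simulations).
#' @return A list of class `ablarec_cohort`; each element is a patient
#'   with `record` (one-row data.frame), `volumes` (named list of three
#'   [phase_volume()]), `mask` ([roi_mask()]), and `heterogeneity`.
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$covariate_marginals

  rec <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(rnorm_trunc(n, m$age$mean, m$age$sd, m$age$lower, m$age$upper), 1),
    gender = draw_cat(n, m$gender),
    tumor_diameter = round(stats::rlnorm(n, m$tumor_diameter$meanlog,
                                         m$tumor_diameter$sdlog), 1),
    grade = draw_cat(n, m$grade),
    afp = round(stats::rlnorm(n, m$afp$meanlog, m$afp$sdlog), 1),
    etiology = draw_cat(n, m$etiology),
    ecog = as.integer(draw_cat(n, m$ecog)),
    ck19 = as.integer(draw_cat(n, m$ck19)),
    gpc3 = as.integer(draw_cat(n, m$gpc3)),
    hbsag = as.integer(draw_cat(n, m$hbsag)),
    hbcag = as.integer(draw_cat(n, m$hbcag)),
    child_pugh = draw_cat(n, m$child_pugh),
    bclc = draw_cat(n, m$bclc),
    ablation = draw_cat(n, m$ablation),
    stringsAsFactors = FALSE
  )

  heterogeneity <- stats::rnorm(n)
  X <- clinical_design(rec)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  common <- intersect(names(config$beta_clinical), names(beta))
  beta[common] <- config$beta_clinical[common]
  lp <- as.numeric(X %*% beta) + config$gamma_texture * heterogeneity
  surv <- simulate_rfs(lp, config)
  rec$rfs_time <- surv$rfs_time
  rec$event <- surv$event

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- list(record = rec[i, , drop = FALSE],
                heterogeneity = heterogeneity[i],
                linear_predictor = lp[i])
    if (images) {
      sigma <- 25 * exp(0.35 * heterogeneity[i])
      ell <- 1.2 + 0.6 * stats::pnorm(heterogeneity[i])
      enh <- stats::rnorm(1, 0, 15)
      img <- simulate_patient_images(config, sigma, ell,
                                     rec$tumor_diameter[i], enh)
      pat$mask <- img$mask
      pat$volumes <- img$volumes
    }
    cohort[[i]] <- pat
  }
  structure(cohort, class = "ablarec_cohort", config = config)
}

#' @export
print.ablarec_cohort <- function(x, ...) {
  cat(sprintf("<ablarec_cohort> %d patients, %d with images\n", length(x),
              sum(vapply(x, function(p) !is.null(p$volumes), logical(1)))))
  invisible(x)
}

#' Collect the per-patient clinical table of a cohort
#'
#' @param cohort an `ablarec_cohort` (or the list of patients from one).
#' @return A data.frame with one row per patient: covariates plus
#'   `rfs_time` (months) and `event`.
#' @export
clinical_table <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}

#' Numeric design matrix for the clinical covariates
#'
#' Encodes the standard candidate covariates for the clinical Cox screen:
#' continuous covariates as-is (AFP on the log10 scale), ordinal scores as
#' integers, and two-level factors as indicators (`gender_male`,
#' `hbv_positive` for HBV-containing etiology, `child_pugh_B`, `bclc_B`).
#'
#' @param records clinical data.frame as returned by [clinical_table()].
#' @return Numeric matrix, one row per patient, named columns.
#' @export
clinical_design <- function(records) {
  grade_num <- match(records$grade, c("I", "II", "III"))
  cbind(
    gender_male = as.numeric(records$gender == "male"),
    age = records$age,
    tumor_diameter = records$tumor_diameter,
    grade = grade_num,
    log_afp = log10(pmax(records$afp, 0.1)),
    hbv_positive = as.numeric(records$etiology %in% c("HBV", "HBV+HCV")),
    ecog = records$ecog,
    ck19 = records$ck19,
    gpc3 = records$gpc3,
    hbsag = records$hbsag,
    hbcag = records$hbcag,
    child_pugh_B = as.numeric(records$child_pugh == "B"),
    bclc_B = as.numeric(records$bclc == "B")
  )
}

#' Perturb a scan/segmentation pair into a synthetic retest copy
#'
#' Emulates re-segmentation of the same scan: the returned volume is the
#' input plus white intensity noise (`retest_noise_sd`), and the returned
#' mask has its boundary randomly eroded/dilated voxel-layer by
#' voxel-layer, up to `retest_mask_voxels` layers deep (each boundary
#' voxel flips with probability `retest_flip_prob`; 6-connected boundary).
#'
#' @param volume a [phase_volume()].
#' @param mask its aligned [roi_mask()].
#' @param config a [sim_config()] supplying the perturbation magnitudes.
#' @param seed optional integer seed for this perturbation.
#' @return `list(volume = , mask = )` — the retest pair.
#' @export
make_retest_pair <- function(volume, mask, config, seed = NULL) {
  check_aligned(volume, mask)
  if (!is.null(seed)) set.seed(seed)
  vox <- volume$voxels
  if (config$retest_noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, config$retest_noise_sd)
  m <- mask$voxels
  if (config$retest_mask_voxels > 0L && config$retest_flip_prob > 0) {
    for (iter in seq_len(config$retest_mask_voxels)) {
      nb <- neighbor_count6(m)
      inner_boundary <- which(m == 1L & nb < 6L)
      outer_boundary <- which(m == 0L & nb > 0L)
      flip_in <- inner_boundary[stats::runif(length(inner_boundary)) <
                                  config$retest_flip_prob]
      flip_out <- outer_boundary[stats::runif(length(outer_boundary)) <
                                   config$retest_flip_prob]
      m[flip_in] <- 0L
      m[flip_out] <- 1L
    }
    if (!any(m == 1L))
      stop("retest perturbation emptied the mask")
  }
  list(volume = phase_volume(vox, volume$spacing, volume$phase),
       mask = roi_mask(m, mask$spacing))
}

# number of 6-connected foreground neighbors per voxel (zero-padded edges)
neighbor_count6 <- function(m) {
  d <- dim(m)
  acc <- array(0L, d)
  pad_shift <- function(a, axis, by) {
    s <- shift3d(a, axis, by)
    # zero out the wrapped-around slab
    if (by == 1L) {
      switch(axis, s[d[1], , ] <- 0L, s[, d[2], ] <- 0L, s[, , d[3]] <- 0L)
    } else {
      switch(axis, s[1, , ] <- 0L, s[, 1, ] <- 0L, s[, , 1] <- 0L)
    }
    s
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    acc <- acc + pad_shift(m, axis, by)
  acc
}

#' Dice overlap of two aligned binary masks
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return `2|A∩B| / (|A|+|B|)`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a$voxels), dim(b$voxels)))
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (sum(a$voxels) + sum(b$voxels))
}

#' Randomly split a cohort into training and validation sets
#'
#' Simple random partition (no stratification), reproducible by seed.
#'
#' @param cohort an `ablarec_cohort`.
#' @param n_train,n_val subset sizes; must sum to the cohort size.
#' @param seed integer seed for the partition.
#' @return `list(train = , validation = )`, both `ablarec_cohort`s.
#' @export
split_cohort <- function(cohort, n_train, n_val, seed = 1L) {
  n <- length(cohort)
  if (n_train + n_val != n)
    stop(sprintf("n_train + n_val = %d but cohort has %d patients",
                 n_train + n_val, n))
  if (n_train < 1 || n_val < 1) stop("both subsets must be non-empty")
  set.seed(seed)
  idx <- sample.int(n, n_train)
  cfg <- attr(cohort, "config")
  out <- list(
    train = structure(cohort[idx], class = "ablarec_cohort", config = cfg),
    validation = structure(cohort[-idx], class = "ablarec_cohort", config = cfg)
  )
  out
}
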