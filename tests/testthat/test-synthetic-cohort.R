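test_that("generate_cohort is seed-deterministic and structurally complete", {
  cfg <- sim_config(n_patients = 4L, seed = 7L, volume_dim = 16L, spacing = 2)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_length(c1, 4L)
  expect_identical(clinical_table(c1), clinical_table(c2))
  expect_identical(c1[[2]]$volumes$arterial$voxels, c2[[2]]$volumes$arterial$voxels)
  for (p in c1) {
    expect_named(p$volumes, c("arterial", "portal_venous", "parenchymal"))
    expect_identical(dim(p$mask$voxels), dim(p$volumes$arterial$voxels))
    expect_gte(sum(p$mask$voxels), 1)
    expect_true(all(p$record$rfs_time > 0))
    expect_true(p$record$event %in% 0:1)
  }
  expect_error(sim_config(n_patients = 1), ">= 2")
  expect_error(sim_config(covariate_marginals = list(gender = c(male = 0.7, female = 0.7))),
               "sum to 1")
})

test_that("covariate marginals converge to the configured frequencies", {
  cfg <- sim_config(n_patients = 10000L, seed = 13L)
  tab <- clinical_table(generate_cohort(cfg, images = FALSE))
  p0 <- 0.736
  male_frac <- mean(tab$gender == "male")
  expect_lt(abs(male_frac - p0), 3 * sqrt(p0 * (1 - p0) / nrow(tab)))
  hbv_frac <- mean(tab$etiology %in% c("HBV", "HBV+HCV"))
  expect_lt(abs(hbv_frac - 0.837), 3 * sqrt(0.837 * 0.163 / nrow(tab)))
  expect_equal(median(tab$tumor_diameter), 3.3, tolerance = 0.1)
  expect_true(all(tab$age >= 18 & tab$age <= 75))
})

test_that("simulate_rfs reproduces the Weibull baseline and censoring rules", {
  cfg <- sim_config(n_patients = 2L, weibull_shape = 1.3, weibull_scale = 18,
                    censor_rate = 0, censor_horizon = Inf)
  set.seed(31)
  s <- simulate_rfs(rep(0, 20000), cfg)
  expect_true(all(s$event == 1))   # no censoring mechanism, all events
  ks <- suppressWarnings(stats::ks.test(s$rfs_time, function(q)
    1 - exp(-(q / 18)^1.3)))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_rfs(c(0, Inf), cfg), "finite")
})

test_that("Cox fits on simulated cohorts recover the configured betas", {
  cfg <- sim_config(n_patients = 2000L, seed = 17L,
                    beta_clinical = c(bclc_B = log(2.1), child_pugh_B = log(2.1)),
                    gamma_texture = 0.8)
  coh <- generate_cohort(cfg, images = FALSE)
  tab <- clinical_table(coh)
  X <- cbind(clinical_design(tab)[, c("bclc_B", "child_pugh_B")],
             heterogeneity = vapply(coh, `[[`, 0, "heterogeneity"))
  fit <- cox_fit(X, tab$rfs_time, tab$event)
  b <- setNames(fit$coefficients$beta, fit$coefficients$name)
  expect_lt(abs(b[["bclc_B"]] - log(2.1)), 0.15)
  expect_lt(abs(b[["child_pugh_B"]] - log(2.1)), 0.15)
  expect_lt(abs(b[["heterogeneity"]] - 0.8), 0.15)

  # two-group parameter recovery at beta = log 2
  set.seed(41)
  g <- rep(0:1, each = 1000)
  s <- simulate_rfs(g * log(2), cfg)
  f2 <- cox_fit(cbind(group = g), s$rfs_time, s$event)
  expect_lt(abs(f2$coefficients$beta - log(2)), 0.1)

  # configured censoring fraction is reproduced
  cfrac <- mean(tab$event == 0)
  # expectation under the fitted config, checked loosely via binomial SD
  expect_lt(abs(cfrac - mean(clinical_table(
    generate_cohort(sim_config(n_patients = 2000L, seed = 18L),
                    images = FALSE))$event == 0)),
    3 * sqrt(cfrac * (1 - cfrac) / 2000) + 0.02)
})

test_that("higher image heterogeneity implies more early recurrence", {
  cfg <- sim_config(n_patients = 2000L, seed = 19L, gamma_texture = 0.8)
  coh <- generate_cohort(cfg, images = FALSE)
  tab <- clinical_table(coh)
  h <- vapply(coh, `[[`, 0, "heterogeneity")
  ter <- cut(h, quantile(h, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
             labels = c("low", "mid", "high"))
  rec2y <- function(sel) mean(tab$event[sel] == 1 & tab$rfs_time[sel] <= 24)
  expect_gt(rec2y(ter == "high"), rec2y(ter == "low"))
})

test_that("retest pairs perturb gently and deterministically", {
  cfg <- sim_config(n_patients = 2L, seed = 23L, volume_dim = 32L, spacing = 1)
  coh <- generate_cohort(cfg)
  p <- coh[[1]]

  # null perturbation returns an identical pair
  cfg0 <- cfg; cfg0$retest_noise_sd <- 0; cfg0$retest_mask_voxels <- 0L
  pr0 <- make_retest_pair(p$volumes$arterial, p$mask, cfg0, seed = 1)
  expect_identical(pr0$volume$voxels, p$volumes$arterial$voxels)
  expect_identical(pr0$mask$voxels, p$mask$voxels)

  # default perturbation keeps Dice high on a ~1000-voxel ROI
  mask <- ball_mask(6.2, dim = 20L)
  expect_gte(sum(mask$voxels), 900)
  vol <- phase_volume(array(rnorm(20^3, 100, 10), c(20, 20, 20)),
                      phase = "arterial")
  dices <- vapply(1:10, function(s)
    dice_overlap(mask, make_retest_pair(vol, mask, cfg, seed = s)$mask),
    numeric(1))
  expect_true(all(dices >= 0.85))
  expect_true(all(dices < 1))

  pr1 <- make_retest_pair(vol, mask, cfg, seed = 9)
  pr2 <- make_retest_pair(vol, mask, cfg, seed = 9)
  expect_identical(pr1$mask$voxels, pr2$mask$voxels)
})

test_that("split_cohort partitions reproducibly", {
  cfg <- sim_config(n_patients = 184L, seed = 7L)
  coh <- generate_cohort(cfg, images = FALSE)
  sp <- split_cohort(coh, 129, 55, seed = 3)
  expect_length(sp$train, 129)
  expect_length(sp$validation, 55)
  ids <- c(clinical_table(sp$train)$patient_id,
           clinical_table(sp$validation)$patient_id)
  expect_setequal(ids, clinical_table(coh)$patient_id)
  expect_identical(anyDuplicated(ids), 0L)
  sp2 <- split_cohort(coh, 129, 55, seed = 3)
  expect_identical(clinical_table(sp2$train)$patient_id,
                   clinical_table(sp$train)$patient_id)
  expect_error(split_cohort(coh, 100, 55, seed = 1), "cohort has")
})
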