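test_that("Harrell C equals the all-pairs oracle and hits its anchors", {
  set.seed(81)
  for (r in 1:5) {
    n <- 30
    risk <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.7)
    risk[sample(n, 4)] <- risk[1]        # ties in risk
    expect_equal(harrell_c(risk, time, event),
                 oracle_concordance(risk, time, event))
  }
  # perfect monotone predictor
  t0 <- sort(rexp(200))
  expect_equal(harrell_c(-t0, t0, rep(1, 200)), 1)
  expect_equal(harrell_c(t0, t0, rep(1, 200)), 0)
  # invariance under strictly monotone transforms of the risk score
  set.seed(82)
  risk <- rnorm(50); time <- rexp(50); event <- rbinom(50, 1, 0.6)
  expect_equal(harrell_c(exp(risk), time, event),
               harrell_c(risk, time, event))
  expect_error(harrell_c(c(1, 2), c(5, 5), c(1, 1)), "usable")
})

test_that("random risk scores give C near one half", {
  set.seed(83)
  cs <- vapply(1:20, function(r) {
    n <- 2000
    time <- rexp(n, 0.05)
    cens <- rexp(n, 0.05 * 0.3 / 0.7)
    harrell_c(rnorm(n), pmin(time, cens), as.numeric(time <= cens))
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("bootstrap CIs are seeded, cover, and narrow with n", {
  set.seed(84)
  x <- rnorm(100, 5)
  ci1 <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, B = 500, seed = 9)
  ci2 <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, B = 500, seed = 9)
  expect_identical(ci1[c("low", "high")], ci2[c("low", "high")])
  expect_true(ci1$low <= mean(x) && mean(x) <= ci1$high)
  # constant metric collapses the interval
  ci0 <- bootstrap_ci(function(idx) 4.2, n = 50, B = 100, seed = 1)
  expect_equal(ci0$low, 4.2)
  expect_equal(ci0$high, 4.2)
  # width shrinks roughly like 1/sqrt(n)
  y <- rnorm(1000, 5)
  ci_big <- bootstrap_ci(function(idx) mean(y[idx]), n = 1000, B = 500, seed = 9)
  expect_lt(ci_big$high - ci_big$low, ci1$high - ci1$low)
})

test_that("likelihood-ratio comparison of nested Cox models behaves", {
  set.seed(85)
  n <- 300
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  s <- simulate_rfs(X[, 1], sim_config(n_patients = 2L))
  small <- cox_fit(X[, "a", drop = FALSE], s$rfs_time, s$event)
  large <- cox_fit(X, s$rfs_time, s$event)
  cmp <- lrt_compare(small, large)
  expect_equal(cmp$df, 2)
  cmp_same <- lrt_compare(small, small)
  expect_equal(cmp_same$statistic, 0)
  expect_equal(cmp_same$p, 1)
  expect_error(lrt_compare(large, small), "not nested")

  # adding a strong signature to a weak clinical model is detected
  hits <- 0
  for (r in 1:50) {
    set.seed(8500 + r)
    clin <- rbinom(n, 1, 0.4)
    sig <- rnorm(n)
    s <- simulate_rfs(0.3 * clin + 0.9 * sig, sim_config(n_patients = 2L))
    f1 <- cox_fit(cbind(clin = clin), s$rfs_time, s$event)
    f2 <- cox_fit(cbind(clin = clin, sig = sig), s$rfs_time, s$event)
    if (lrt_compare(f1, f2)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * 50)
})

# helper: well-specified predictions from a known Weibull-Cox model
true_model_data <- function(n, miscalibrate = FALSE) {
  cfg <- sim_config(n_patients = 2L, weibull_shape = 1.1, weibull_scale = 20,
                    censor_rate = 1 / 60, censor_horizon = 84)
  lp <- rnorm(n, 0, 0.8)
  s <- simulate_rfs(lp, cfg)
  pred <- exp(-(24 / 20)^1.1 * exp(lp))
  if (miscalibrate) pred <- pred / 2
  list(pred = pred, time = s$rfs_time, event = s$event)
}

test_that("survival Hosmer-Lemeshow accepts the truth and rejects miscalibration", {
  set.seed(86)
  ok <- 0
  for (r in 1:50) {
    d <- true_model_data(1000)
    if (hl_survival(d$pred, d$time, d$event, n_groups = 10, t = 24)$p > 0.05)
      ok <- ok + 1
  }
  expect_gte(ok, 0.8 * 50)

  bad <- 0
  for (r in 1:50) {
    d <- true_model_data(1000, miscalibrate = TRUE)
    if (hl_survival(d$pred, d$time, d$event, n_groups = 10, t = 24)$p < 0.05)
      bad <- bad + 1
  }
  expect_gte(bad, 0.9 * 50)

  # groups partition the cohort with near-equal sizes
  d <- true_model_data(503)
  hl <- hl_survival(d$pred, d$time, d$event, n_groups = 10, t = 24)
  expect_equal(sum(hl$table$n), 503)
  expect_lte(diff(range(hl$table$n)), 1)
  expect_equal(hl$df, 8)
})

test_that("calibration tables track the diagonal under the true model", {
  set.seed(87)
  ok <- 0
  for (r in 1:20) {
    d <- true_model_data(1000)
    tab <- calibration_table(d$pred, d$time, d$event, t = 24, n_groups = 5)
    if (max(abs(tab$mean_predicted - tab$observed_km)) <= 0.1) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * 20)
  d <- true_model_data(200)
  tab <- calibration_table(d$pred, d$time, d$event, t = 24)
  expect_equal(sum(tab$n), 200)
  tab2 <- calibration_table(d$pred, d$time, d$event, t = 24)
  expect_identical(tab, tab2)
})

test_that("nomogram predictions equal direct Cox predictions", {
  set.seed(88)
  n <- 150
  X <- cbind(stage = rbinom(n, 1, 0.4), sig = rnorm(n))
  s <- simulate_rfs(0.7 * X[, 1] + 0.5 * X[, 2], sim_config(n_patients = 2L))
  fit <- cox_fit(X, s$rfs_time, s$event)
  nom <- build_nomogram(fit, X)

  # the widest predictor spans exactly 0-100 points; all points in range
  pts <- nomogram_points(nom, X)
  expect_equal(max(nom$point_range), 100)
  expect_true(all(pts$points >= -1e-9 & pts$points <= 100 + 1e-9))
  # a patient at reference values scores zero total points
  ref <- X[1, , drop = FALSE]
  ref[1, ] <- c(X[which.min(nom$beta["stage"] * X[, "stage"]), "stage"],
                X[which.min(nom$beta["sig"] * X[, "sig"]), "sig"])
  expect_equal(nomogram_points(nom, ref)$total, 0, tolerance = 1e-9)
  # total points are affine in the Cox linear predictor
  lp <- as.numeric(X %*% fit$coefficients$beta)
  expect_gt(abs(cor(pts$total, lp)), 1 - 1e-12)

  # single-predictor model: nomogram S(t) equals survfit's direct prediction
  fit1 <- cox_fit(X[, "sig", drop = FALSE], s$rfs_time, s$event)
  nom1 <- build_nomogram(fit1, X[, "sig", drop = FALSE])
  new <- X[3:7, "sig", drop = FALSE]
  for (t0 in c(12, 24)) {
    direct <- summary(survival::survfit(fit1$fit,
                                        newdata = data.frame(sig = new[, 1])),
                      times = t0)$surv
    expect_equal(unname(predict_rfs(nom1, new, t = t0)), as.numeric(direct),
                 tolerance = 1e-6)
  }
  # survival decreases with horizon for every patient
  s12 <- predict_rfs(nom, X, t = 12)
  s24 <- predict_rfs(nom, X, t = 24)
  s36 <- predict_rfs(nom, X, t = 36)
  expect_true(all(s12 >= s24 & s24 >= s36))
  expect_error(predict_rfs(nom, X, t = 1e6), "outside")
})

test_that("evaluate_all reports all models on both datasets reproducibly", {
  set.seed(89)
  n <- 120
  mk <- function() {
    lp <- rnorm(n)
    s <- simulate_rfs(lp, sim_config(n_patients = 2L))
    list(lp = lp, time = s$rfs_time, event = s$event)
  }
  tr <- mk(); va <- mk()
  models <- list(
    good = list(train = tr$lp, validation = va$lp),
    random = list(train = rnorm(n), validation = rnorm(n)))
  rep1 <- evaluate_all(models, list(time = tr$time, event = tr$event),
                       list(time = va$time, event = va$event), B = 100, seed = 4)
  rep2 <- evaluate_all(models, list(time = tr$time, event = tr$event),
                       list(time = va$time, event = va$event), B = 100, seed = 4)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 4)
  expect_true(all(rep1$ci_low <= rep1$c_index & rep1$c_index <= rep1$ci_high))
  expect_true(all(rep1$c_index >= 0 & rep1$c_index <= 1))
  good_val <- rep1$c_index[rep1$model == "good" & rep1$dataset == "validation"]
  rand_val <- rep1$c_index[rep1$model == "random" & rep1$dataset == "validation"]
  expect_gt(good_val, rand_val)
})

test_that("a strong imaging signature lifts the combined model over clinical", {
  # feature-level emulation of the image-signal-dominant regime
  set.seed(90)
  wins <- 0
  for (r in 1:25) {
    n <- 200
    clin <- rbinom(n, 1, 0.4)
    h <- rnorm(n)                       # latent heterogeneity
    sig <- h + rnorm(n, 0, 0.5)         # radiomics signature tracks it
    s <- simulate_rfs(0.3 * clin + 0.9 * h, sim_config(n_patients = 2L))
    tr <- 1:140; va <- 141:200
    f_cl <- cox_fit(cbind(clin = clin[tr]), s$rfs_time[tr], s$event[tr])
    f_cb <- cox_fit(cbind(clin = clin, sig = sig)[tr, ], s$rfs_time[tr], s$event[tr])
    b_cl <- f_cl$coefficients$beta
    b_cb <- setNames(f_cb$coefficients$beta, f_cb$coefficients$name)
    c_cl <- harrell_c(clin[va] * b_cl, s$rfs_time[va], s$event[va])
    c_cb <- harrell_c(cbind(clin = clin, sig = sig)[va, ] %*% b_cb,
                      s$rfs_time[va], s$event[va])
    if (c_cb > c_cl) wins <- wins + 1
  }
  expect_gte(wins, 0.8 * 25)
})
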