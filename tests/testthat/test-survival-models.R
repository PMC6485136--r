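# Cox machinery checks against independently coded oracles: a grid-search
# partial-likelihood maximizer, direct-summation likelihood evaluation,
# and a hand log-rank tabulation.

hand8 <- data.frame(
  time = c(2, 4, 5, 7, 9, 12, 14, 20),
  event = c(1, 1, 0, 1, 1, 0, 1, 1),
  x = c(1, 1, 0, 1, 0, 1, 0, 0))

test_that("cox_fit maximizes the Breslow partial likelihood", {
  fit <- cox_fit(cbind(x = hand8$x), hand8$time, hand8$event)
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, oracle_coxpl, numeric(1),
               x = hand8$x, time = hand8$time, event = hand8$event)
  expect_equal(fit$coefficients$beta, grid[which.max(pl)], tolerance = 1e-3)
  expect_equal(fit$loglik, max(pl), tolerance = 1e-6)
  # the likelihood function evaluated at 0 equals the null value
  expect_equal(cox_loglik(cbind(hand8$x), hand8$time, hand8$event, 0),
               fit$null_loglik)
  # fitted betas are a local maximum of the package's own likelihood
  for (eps in c(-0.05, 0.05))
    expect_lt(cox_loglik(cbind(hand8$x), hand8$time, hand8$event,
                         fit$coefficients$beta + eps), fit$loglik)
})

test_that("cox_fit under the null covers zero and flags degenerate fits", {
  set.seed(61)
  n <- 2000
  x <- rnorm(n)
  time <- rexp(n); event <- rbinom(n, 1, 0.7)
  fit <- cox_fit(cbind(x = x), time, event)
  expect_lt(abs(fit$coefficients$beta), 0.1)
  expect_true(fit$coefficients$ci_low < 1 & 1 < fit$coefficients$ci_high)
  expect_error(cox_fit(cbind(x = rep(1, 10)), rexp(10), rep(1, 10)), "constant")
  # monotone likelihood (perfect separation in time) is flagged
  expect_error(
    cox_fit(cbind(x = c(1, 1, 1, 1, 0, 0, 0, 0)),
            c(1, 2, 3, 4, 10, 11, 12, 13), rep(1, 8)),
    "converge")
})

test_that("LASSO path shrinks fully above lambda_max and matches cox_fit at 0", {
  set.seed(62)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  lp <- 0.8 * X[, 1] - 0.5 * X[, 2]
  s <- simulate_rfs(lp, sim_config(n_patients = 2L))
  path <- lasso_cox_path(X, s$rfs_time, s$event)
  expect_true(all(path$beta[, 1] == 0))   # at lambda_max everything is zero
  expect_true(all(colSums(path$beta != 0) ==
                  colSums(abs(path$beta) > 0)))  # exact zeros are exact

  b0 <- lasso_cox_path(X, s$rfs_time, s$event,
                       lambdas = c(path$lambda_max, 1e-4, 0))
  unpen <- cox_fit(X, s$rfs_time, s$event)
  expect_equal(unname(b0$beta[, 3]), unpen$coefficients$beta, tolerance = 1e-3)
  expect_error(lasso_cox_path(X, s$rfs_time, rep(0, n)), "all-censored")
})

test_that("cross-validated penalty choice is deterministic and sane", {
  set.seed(63)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  lp <- X[, 1] - 0.8 * X[, 2]
  s <- simulate_rfs(lp, sim_config(n_patients = 2L))
  cv1 <- cv_select_lambda(X, s$rfs_time, s$event)
  cv2 <- cv_select_lambda(X, s$rfs_time, s$event)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_identical(cv1$cv_loglik, cv2$cv_loglik)
  path <- lasso_cox_path(X, s$rfs_time, s$event)
  sig <- build_signature(path, cv1$lambda, X)
  expect_true(all(c("f1", "f2") %in% sig$features))
})

test_that("CV on pure noise rarely selects more than one feature", {
  set.seed(64)
  wins <- 0
  for (r in 1:25) {
    n <- 100
    X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
    s <- simulate_rfs(rep(0, n), sim_config(n_patients = 2L))
    cv <- cv_select_lambda(X, s$rfs_time, s$event, nfolds = 10)
    path <- lasso_cox_path(X, s$rfs_time, s$event)
    nnz <- sum(glmnet::coef.glmnet(path$fit, s = cv$lambda) != 0)
    if (nnz <= 1) wins <- wins + 1
  }
  expect_gte(wins, 0.8 * 25)
})

test_that("signature scoring, cutoff, and stratification follow the definitions", {
  set.seed(65)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  s <- simulate_rfs(X[, 1], sim_config(n_patients = 2L))
  path <- lasso_cox_path(X, s$rfs_time, s$event)
  sig <- build_signature(path, path$lambdas[30], X, phase = "arterial")
  sc <- score_signature(sig, X)
  # score is the plain dot product of stored coefficients and features
  expect_equal(sc, as.numeric(X[, sig$features, drop = FALSE] %*% sig$coefficients))
  expect_equal(sig$median_cutoff, median(sc))
  # zero-coefficient features do not affect the score
  X2 <- X; zero_feats <- setdiff(colnames(X), sig$features)
  if (length(zero_feats)) {
    X2[, zero_feats] <- 99
    expect_equal(score_signature(sig, X2), sc)
  }

  grp <- median_stratify(sc, sig$median_cutoff)
  expect_equal(sum(grp == "high") + sum(grp == "low"), 60)
  # all-tied scores go entirely to high risk (>= rule)
  expect_true(all(median_stratify(rep(1, 5), 1) == "high"))
  # 129 distinct scores split 65 high / 64 low at their median
  set.seed(66)
  sc129 <- rnorm(129)
  g <- median_stratify(sc129, median(sc129))
  expect_equal(as.vector(table(g)[c("high", "low")]), c(65, 64))
})

test_that("KM estimator and log-rank test match hand computation", {
  # no censoring: KM equals the empirical survival function
  t0 <- c(1, 2, 3, 4, 5)
  km <- km_estimate(t0, rep(1, 5))
  expect_equal(km$surv, 1 - ecdf(t0)(t0))
  expect_true(all(diff(km$surv) <= 0) && km$surv[1] <= 1)

  # 6-patient hand example: times 1..6, events 1,1,0,1,0,1, groups A,B,A,B,A,B
  tt <- 1:6; ev <- c(1, 1, 0, 1, 0, 1); gr <- rep(c("A", "B"), 3)
  # hand tabulation of observed - expected for group A:
  # t=1: nA=3,nB=3, d=1 (A) -> O-E = 1 - 3/6
  # t=2: nA=2,nB=3, d=1 (B) -> O-E = 0 - 2/5
  # t=4: nA=1,nB=2, d=1 (B) -> O-E = 0 - 1/3
  # t=6: nA=0,nB=1, d=1 (B) -> O-E = 0 - 0
  oe <- (1 - 3 / 6) + (0 - 2 / 5) + (0 - 1 / 3)
  vr <- (3 * 3 * 1 * 5) / (36 * 5) + (2 * 3 * 1 * 4) / (25 * 4) +
    (1 * 2 * 1 * 2) / (9 * 2)
  lr <- logrank_test(tt, ev, gr)
  expect_equal(lr$chisq, oe^2 / vr, tolerance = 1e-10)
  expect_equal(lr$df, 1)

  # identical groups give a null statistic
  lr0 <- logrank_test(rep(tt, 2), rep(ev, 2), rep(c("A", "B"), each = 6))
  expect_equal(lr0$chisq, 0, tolerance = 1e-10)
  expect_gt(lr0$p, 0.99)
})

test_that("log-rank p-values are approximately uniform under permutation", {
  set.seed(67)
  p <- vapply(1:200, function(i) {
    tt <- rexp(40); ev <- rbinom(40, 1, 0.8); gr <- sample(rep(0:1, 20))
    logrank_test(tt, ev, gr)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("clinical screen applies both thresholds and recovers true factors", {
  # Stage-1 gate: a covariate with univariable p >= 0.10 never enters stage 2
  set.seed(68)
  n <- 300
  x_signal <- rbinom(n, 1, 0.4)
  x_null <- rnorm(n)
  s <- simulate_rfs(1.2 * x_signal, sim_config(n_patients = 2L))
  scr <- clinical_screen(cbind(signal = x_signal, null = x_null),
                         s$rfs_time, s$event)
  uni_null_p <- scr$univariable$p[scr$univariable$name == "null"]
  if (uni_null_p >= 0.10) expect_false("null" %in% scr$covariates)
  expect_true("signal" %in% scr$covariates)

  # recovery across seeds: planted stage/class factors at published scale
  hits <- 0
  for (r in 1:50) {
    cfg <- sim_config(n_patients = 500L, seed = 1000L + r,
                      beta_clinical = c(bclc_B = log(4.834),
                                        child_pugh_B = log(2.762)),
                      gamma_texture = 0)
    tab <- clinical_table(generate_cohort(cfg, images = FALSE))
    scr <- clinical_screen(clinical_design(tab), tab$rfs_time, tab$event)
    if (all(c("bclc_B", "child_pugh_B") %in% scr$covariates)) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * 50)
})

test_that("all-null covariates are retained at roughly the nominal rate", {
  set.seed(69)
  kept <- 0; total <- 0
  for (r in 1:40) {
    n <- 500
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("z", 1:4)))
    s <- simulate_rfs(rep(0, n), sim_config(n_patients = 2L))
    scr <- clinical_screen(X, s$rfs_time, s$event)
    kept <- kept + length(scr$covariates)
    total <- total + 4
  }
  # per-covariate retention needs p<0.10 then p<0.05: well below 10%
  expect_lt(kept / total, 0.10)
  expect_gt(kept / total, 0.001)
})
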