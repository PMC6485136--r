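# Discrimination (Harrell C + bootstrap CIs), nested-model comparison,
# survival-adapted calibration, and the points-based nomogram.

#' Harrell concordance index
#'
#' Fraction of usable patient pairs in which the higher-risk patient
#' fails first.  A pair is usable iff the shorter observed time ends in
#' an event (pairs with tied event times are not usable); pairs tied on
#' the risk score count 1/2.  Computed through
#' `survival::concordance`; 1 is perfect discrimination, 0.5 is chance.
#'
#' @param risk per-patient risk score (higher = worse prognosis).
#' @param time,event survival outcome.
#' @return C-index in `[0, 1]`.
#' @export
harrell_c <- function(risk, time, event) {
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  cnt <- cc$count
  usable <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  if (usable == 0) stop("no usable pairs (all times censored or tied)")
  unname((cnt["concordant"] + 0.5 * cnt["tied.x"]) / usable)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement `B` times and returns the 2.5 and
#' 97.5 percentiles of the metric.  A resample on which the metric is
#' undefined (error or non-finite) is redrawn and counted, with the
#' number of redraws capped at `B`.
#'
#' @param metric_fn function(indices) -> scalar metric on the resampled
#'   patients.
#' @param n number of patients to resample from.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; fixes the interval exactly.
#' @param level confidence level (default 0.95).
#' @return list: `low`, `high`, `values` (the B metric values),
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, n, B = 1000L, seed = 1L, level = 0.95) {
  if (B < 2) stop("B must be >= 2")
  set.seed(seed)
  vals <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric_fn(idx), error = function(e) NA_real_)
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
      if (redrawn > B) stop("metric undefined on too many bootstrap resamples")
    }
    vals[b] <- v
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  list(low = qs[1], high = qs[2], values = vals, n_redrawn = redrawn)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The analysis-of-deviance test between two nested Cox models fit on
#' the same patients: twice the gain in log partial likelihood referred
#' to a chi-square with as many degrees of freedom as added parameters.
#'
#' @param smaller,larger [cox_fit()] results; the smaller model's
#'   covariates must be a subset of the larger's, fit on identical
#'   patients.
#' @return list: `statistic`, `df`, `p`.
#' @export
lrt_compare <- function(smaller, larger) {
  stopifnot(inherits(smaller, "ablarec_cox"), inherits(larger, "ablarec_cox"))
  if (smaller$n != larger$n || smaller$n_event != larger$n_event)
    stop("models were not fit on identical patients")
  if (!all(smaller$coefficients$name %in% larger$coefficients$name))
    stop("models are not nested")
  df <- nrow(larger$coefficients) - nrow(smaller$coefficients)
  stat <- max(0, 2 * (larger$loglik - smaller$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

# equal-count risk groups (sizes differ by at most 1), by ascending value
quantile_groups <- function(values, n_groups) {
  n <- length(values)
  ceiling(rank(values, ties.method = "first") * n_groups / n)
}

#' Survival-adapted Hosmer-Lemeshow calibration test
#'
#' Patients are split into `n_groups` equal-count groups by predicted
#' survival at the horizon; per group the Kaplan-Meier observed survival
#' at `t` is compared with the mean predicted survival, standardised by
#' the Greenwood variance, and the squared standardised differences are
#' summed into a chi-square statistic with `n_groups - 2` degrees of
#' freedom.  Groups whose Greenwood variance is zero (no events before
#' `t`) fall back to a binomial variance with a half-count continuity
#' guard.
#'
#' @param pred_surv predicted survival probability at `t`, per patient.
#' @param time,event observed outcome.
#' @param n_groups number of risk groups (default 10).
#' @param t horizon, within the observed follow-up range.
#' @return list: `statistic`, `df`, `p`, `table` (per-group predicted,
#'   observed and variance).
#' @export
hl_survival <- function(pred_surv, time, event, n_groups = 10L, t) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (t <= 0 || t > max(time)) stop("horizon outside the observed time range")
  grp <- quantile_groups(pred_surv, n_groups)
  stat <- 0
  rows <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    sel <- grp == g
    ng <- sum(sel)
    if (sum(time[sel] >= t) == 0 && sum(event[sel] & time[sel] <= t) == 0)
      stop(sprintf("risk group %d has no patients at risk at t = %g", g, t))
    km <- km_estimate(time[sel], event[sel])
    ob <- km_at(km, t)
    v <- ob$var
    if (!is.finite(v) || v <= 0)
      v <- (ob$surv * (1 - ob$surv) + 0.5 / ng) / ng
    mp <- mean(pred_surv[sel])
    stat <- stat + (ob$surv - mp)^2 / v
    rows[[g]] <- data.frame(group = g, n = ng, mean_predicted = mp,
                            observed_km = ob$surv, greenwood_var = ob$var)
  }
  df <- n_groups - 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = do.call(rbind, rows))
}

#' Points-based nomogram for a Cox model
#'
#' Maps each predictor to a 0-100 point scale: a predictor's points are
#' its hazard contribution `beta_j * x_j` above the training minimum,
#' scaled so the predictor with the widest observed contribution range
#' spans exactly 0-100.  Total points are therefore an affine function
#' of the Cox linear predictor, which the Breslow baseline converts to
#' recurrence-free survival probabilities at the requested horizons.
#'
#' @param fit an [cox_fit()] result for the combined model.
#' @param X the training design matrix the model was fit on (defines the
#'   point ranges and the baseline centering).
#' @param horizons survival horizons in months (default 12, 24, 36).
#' @return Object of class `ablarec_nomogram`.
#' @export
build_nomogram <- function(fit, X, horizons = c(12, 24, 36)) {
  stopifnot(inherits(fit, "ablarec_cox"))
  X <- as.matrix(X)
  beta <- stats::setNames(fit$coefficients$beta, fit$coefficients$name)
  X <- X[, names(beta), drop = FALSE]
  contrib <- sweep(X, 2, beta, `*`)
  c_min <- apply(contrib, 2, min)
  c_rng <- apply(contrib, 2, max) - c_min
  K <- max(c_rng)
  if (K <= 0) stop("all predictors are constant; nomogram undefined")
  bh <- survival::basehaz(fit$fit, centered = TRUE)
  structure(list(
    beta = beta, contrib_min = c_min, scale = K,
    lp_ref = sum(c_min), lp_center = sum(beta * colMeans(X)),
    basehaz = bh, horizons = horizons,
    point_range = 100 * c_rng / K,
    max_time = max(bh$time)), class = "ablarec_nomogram")
}

#' @export
print.ablarec_nomogram <- function(x, ...) {
  cat("<ablarec_nomogram>\n  predictor point ranges:\n")
  print(round(x$point_range, 1))
  invisible(x)
}

#' Per-predictor and total nomogram points
#'
#' @param nomogram an [build_nomogram()] result.
#' @param X design matrix of patients to score.
#' @return list: `points` (patients x predictors), `total` (vector).
#' @export
nomogram_points <- function(nomogram, X) {
  X <- as.matrix(X)[, names(nomogram$beta), drop = FALSE]
  contrib <- sweep(X, 2, nomogram$beta, `*`)
  pts <- sweep(contrib, 2, nomogram$contrib_min) * 100 / nomogram$scale
  list(points = pts, total = rowSums(pts))
}

#' Predict recurrence-free survival from a nomogram
#'
#' Converts total points back to the Cox linear predictor and evaluates
#' `S(t | x) = S0(t)^exp(lp - lp_center)` with the Breslow baseline at
#' the requested horizon.
#'
#' @param nomogram an [build_nomogram()] result.
#' @param X design matrix of patients (or use `total_points`).
#' @param t horizon in months; must not exceed the observed time range.
#' @param total_points alternatively, pre-computed total points.
#' @return Vector of survival probabilities at `t`.
#' @export
predict_rfs <- function(nomogram, X = NULL, t, total_points = NULL) {
  if (t <= 0 || t > nomogram$max_time)
    stop(sprintf("horizon t = %g outside the observed time range (0, %g]",
                 t, nomogram$max_time))
  if (is.null(total_points)) {
    if (is.null(X)) stop("supply X or total_points")
    total_points <- nomogram_points(nomogram, X)$total
  }
  lp <- nomogram$lp_ref + total_points * nomogram$scale / 100
  idx <- findInterval(t, nomogram$basehaz$time)
  H0 <- if (idx == 0) 0 else nomogram$basehaz$hazard[idx]
  exp(-H0 * exp(lp - nomogram$lp_center))
}

#' Calibration table: predicted vs KM-observed survival by risk group
#'
#' @param pred_surv predicted survival probability at `t`, per patient.
#' @param time,event observed outcome.
#' @param t horizon.
#' @param n_groups number of equal-count risk groups (default 5).
#' @return data.frame (class `calibration_table`): per group `n`,
#'   `mean_predicted`, `observed_km`, `se` (Greenwood), ready to plot
#'   against the diagonal.
#' @export
calibration_table <- function(pred_surv, time, event, t, n_groups = 5L) {
  if (t <= 0 || t > max(time)) stop("horizon outside the observed time range")
  grp <- quantile_groups(pred_surv, n_groups)
  rows <- lapply(seq_len(n_groups), function(g) {
    sel <- grp == g
    km <- km_estimate(time[sel], event[sel])
    ob <- km_at(km, t)
    data.frame(group = g, n = sum(sel), mean_predicted = mean(pred_surv[sel]),
               observed_km = ob$surv, se = sqrt(ob$var))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Discrimination report for a set of risk models
#'
#' For every model, computes the Harrell C-index with a percentile
#' bootstrap confidence interval on the training and validation sets
#' (validation scores come from frozen training coefficients).
#'
#' @param risk_models named list; each element has numeric vectors
#'   `train` and `validation` of per-patient risk scores.
#' @param train_outcome,val_outcome lists with `time` and `event`.
#' @param B bootstrap resamples (default 1000).
#' @param seed master seed for the bootstrap.
#' @return data.frame: `model`, `dataset`, `c_index`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
evaluate_all <- function(risk_models, train_outcome, val_outcome,
                         B = 1000L, seed = 1L) {
  rows <- list()
  for (nm in names(risk_models)) {
    for (ds in c("train", "validation")) {
      risk <- risk_models[[nm]][[ds]]
      oc <- if (ds == "train") train_outcome else val_outcome
      ci <- bootstrap_ci(function(idx)
        harrell_c(risk[idx], oc$time[idx], oc$event[idx]),
        n = length(risk), B = B,
        seed = derive_seed(seed, paste0("cindex_", nm, "_", ds)))
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, dataset = ds,
        c_index = harrell_c(risk, oc$time, oc$event),
        ci_low = ci$low, ci_high = ci$high, n = length(risk),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Median-split group RFS summaries
#'
#' For each risk group and horizon: the median (IQR) of follow-up
#' truncated at the horizon and the number (%) of recurrences observed
#' by the horizon, plus the two-group log-rank test over the full
#' follow-up.
#'
#' @param time,event outcome; `group` a [median_stratify()] factor.
#' @param horizons months (default 12, 24, 36).
#' @return list: `table` (data.frame), `logrank` ([logrank_test()]).
#' @export
group_rfs_summary <- function(time, event, group, horizons = c(12, 24, 36)) {
  rows <- list()
  for (g in levels(group)) {
    sel <- group == g
    for (h in horizons) {
      tt <- pmin(time[sel], h)
      q <- stats::quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)
      rec <- sum(event[sel] == 1 & time[sel] <= h)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, horizon = h, n = sum(sel),
        median_rfs = q[2], iqr_low = q[1], iqr_high = q[3],
        n_recurrence = rec, pct_recurrence = 100 * rec / sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       logrank = logrank_test(time, event, group))
}
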