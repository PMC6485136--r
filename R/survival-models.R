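# Cox machinery: unpenalized fits (survival::coxph, Breslow ties),
# LASSO-penalized fits with cross-validated penalty (glmnet, Cox family),
# radiomics signature construction, median-split Kaplan-Meier
# stratification, and the two-stage clinical covariate screen.

#' Breslow log partial likelihood by direct summation
#'
#' Evaluates the Cox log partial likelihood with Breslow handling of tied
#' event times at an arbitrary coefficient vector.  Used for
#' likelihood-ratio comparisons and as a transparent reference for the
#' fitted models.
#'
#' @param X covariate matrix (n x p).
#' @param time,event survival outcome.
#' @param beta coefficient vector (length p).
#' @return Scalar log partial likelihood.
#' @export
cox_loglik <- function(X, time, event, beta) {
  lp <- as.numeric(as.matrix(X) %*% beta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(lp[d]) - length(d) * log(sum(exp(lp[risk])))
  }
  ll
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Breslow-ties partial-likelihood maximization via `survival::coxph`,
#' with per-coefficient hazard ratios, Wald 95% confidence intervals and
#' p-values.  Monotone-likelihood problems (a coefficient drifting to
#' infinity) are raised as errors rather than returned silently.
#'
#' @param X covariate matrix with column names; no constant column.
#' @param time,event survival outcome (>= 1 event).
#' @return Object of class `ablarec_cox`: `coefficients` (data.frame
#'   with `name`, `beta`, `hr`, `ci_low`, `ci_high`, `p`), `loglik`,
#'   `null_loglik`, `n`, `n_event`, and the underlying `fit`.
#' @export
cox_fit <- function(X, time, event) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1) stop("need at least one event")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  dat <- data.frame(time = time, event = event, X, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations", conditionMessage(w)))
        stop("Cox fit did not converge (monotone likelihood?): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(
      name = colnames(X),
      beta = unname(co[, "coef"]),
      hr = unname(exp(co[, "coef"])),
      ci_low = unname(exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
      ci_high = unname(exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
      p = unname(co[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE),
    loglik = fit$loglik[2],
    null_loglik = fit$loglik[1],
    n = nrow(X), n_event = sum(event),
    fit = fit), class = "ablarec_cox")
}

#' @export
print.ablarec_cox <- function(x, ...) {
  cat(sprintf("<ablarec_cox> %d patients, %d events, loglik %.3f\n",
              x$n, x$n_event, x$loglik))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' LASSO-penalized Cox regression path
#'
#' Cyclic coordinate descent on the penalized Breslow partial likelihood
#' (via `glmnet`): features are z-scored internally, soft-thresholding
#' produces exact zeros, and the path is computed with warm starts along
#' a decreasing grid of 100 log-spaced penalties from `lambda_max` (the
#' smallest penalty shrinking every coefficient to zero) down to
#' `0.01 * lambda_max`.  Coefficients are reported on the original
#' feature scale.
#'
#' @param X feature matrix (n x p, named columns, p >= 2).
#' @param time,event survival outcome; at least one event.
#' @param lambdas optional decreasing penalty grid; default as above.
#' @return Object of class `cox_lasso_path`: `lambdas`, `beta`
#'   (p x n_lambda matrix), `lambda_max`, and the `glmnet` fit.
#' @export
lasso_cox_path <- function(X, time, event, lambdas = NULL) {
  X <- as.matrix(X)
  if (sum(event) < 1) stop("all-censored data: no events to fit")
  y <- survival::Surv(time, event)
  # small-sample path tails can be dropped by glmnet; the retained
  # solutions are valid, so that specific warning is muffled
  fit <- muffle_path_warning(
    glmnet::glmnet(X, y, family = "cox", alpha = 1,
                   lambda = lambdas, nlambda = 100,
                   lambda.min.ratio = 0.01, standardize = TRUE))
  structure(list(lambdas = fit$lambda,
                 beta = as.matrix(fit$beta),
                 lambda_max = max(fit$lambda),
                 fit = fit), class = "cox_lasso_path")
}

#' Choose the LASSO penalty by cross-validated partial likelihood
#'
#' For each penalty on the grid the Verweij-van Houwelingen
#' cross-validated log partial likelihood is computed (the full-data
#' partial likelihood at the held-out-refit coefficients minus the
#' held-in partial likelihood, via `cv.glmnet` with `grouped = TRUE`);
#' the selected penalty maximizes it.  Folds default to leave-one-out,
#' making the choice fully deterministic.
#'
#' @param X,time,event as in [lasso_cox_path()].
#' @param nfolds number of CV folds; default `nrow(X)` (leave-one-out).
#' @param lambdas optional penalty grid.
#' @return list: `lambda` (the maximizer), `lambdas`, `cv_loglik`
#'   (per-penalty CV log partial likelihood, up to a constant), and the
#'   `cv.glmnet` object.
#' @export
cv_select_lambda <- function(X, time, event, nfolds = nrow(X), lambdas = NULL) {
  X <- as.matrix(X)
  if (sum(event) < 1) stop("all-censored data: no events to cross-validate")
  y <- survival::Surv(time, event)
  foldid <- rep_len(seq_len(nfolds), nrow(X))
  cv <- muffle_path_warning(
    glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                      lambda = lambdas, nlambda = 100,
                      lambda.min.ratio = 0.01, standardize = TRUE,
                      foldid = foldid, grouped = TRUE,
                      type.measure = "deviance"))
  list(lambda = cv$lambda.min, lambdas = cv$lambda,
       cv_loglik = -cv$cvm / 2, cv = cv)
}

#' Build a radiomics signature from a penalized Cox model
#'
#' The signature is the coefficient-weighted sum of the selected
#' features (the Cox linear predictor at the chosen penalty, on the
#' original feature scale); the risk cutoff is the median signature
#' score of the training patients.  If the chosen penalty selects no
#' feature, the largest penalty retaining at least one feature is used
#' instead (flagged in the result).
#'
#' @param path a [lasso_cox_path()].
#' @param lambda the chosen penalty (e.g. from [cv_select_lambda()]).
#' @param X_train training feature matrix used to place the median
#'   cutoff.
#' @param phase optional phase label carried along.
#' @return Object of class `radiomics_signature`: `phase`, `features`,
#'   `coefficients`, `lambda`, `median_cutoff`, `fallback`.
#' @export
build_signature <- function(path, lambda, X_train, phase = NA_character_) {
  stopifnot(inherits(path, "cox_lasso_path"))
  b <- as.numeric(glmnet::coef.glmnet(path$fit, s = lambda))
  names(b) <- rownames(path$beta)
  fallback <- FALSE
  if (all(b == 0)) {
    nnz <- colSums(path$beta != 0)
    if (all(nnz == 0)) stop("no penalty on the path selects any feature")
    lambda <- max(path$lambdas[nnz > 0])
    b <- path$beta[, which(path$lambdas == lambda)[1]]
    fallback <- TRUE
  }
  sel <- names(b)[b != 0]
  coefs <- b[sel]
  scores <- as.numeric(as.matrix(X_train[, sel, drop = FALSE]) %*% coefs)
  structure(list(phase = phase, features = sel, coefficients = coefs,
                 lambda = lambda, median_cutoff = stats::median(scores),
                 fallback = fallback),
            class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat(sprintf("<radiomics_signature> phase %s: %d features, cutoff %.4f\n",
              x$phase, length(x$features), x$median_cutoff))
  invisible(x)
}

#' Score patients with a radiomics signature
#'
#' @param signature a [build_signature()] result.
#' @param X feature matrix containing the signature's feature columns.
#' @return Numeric vector of signature scores (one per row of `X`).
#' @export
score_signature <- function(signature, X) {
  as.numeric(as.matrix(X[, signature$features, drop = FALSE]) %*%
               signature$coefficients)
}

#' Median-split risk stratification
#'
#' Scores at or above the cutoff are labelled `"high"` risk, below it
#' `"low"`.  With an odd number of distinct training scores and the
#' cutoff at their median, the high group is one patient larger (the
#' median patient itself is high risk).
#'
#' @param scores numeric signature scores (finite).
#' @param cutoff the risk cutoff (typically the training median).
#' @return Factor with levels `low`, `high`.
#' @export
median_stratify <- function(scores, cutoff) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' @param time,event survival outcome.
#' @return list of class `km_curve`: `time` (event times), `surv`,
#'   `n_risk`, `n_event`, `var` (Greenwood variance of the estimate).
#' @export
km_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "plain")
  v <- sf$std.err^2 * sf$surv^2
  v[!is.finite(v)] <- 0       # estimate at 0 with no remaining variance
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, var = v),
            class = "km_curve")
}

#' Survival probability of a KM curve at a horizon
#'
#' @param km a [km_estimate()] result.
#' @param t horizon (same units as the input times).
#' @return list: `surv`, `var` (Greenwood) at the last event time <= t.
#' @export
km_at <- function(km, t) {
  idx <- which(km$time <= t)
  if (!length(idx)) return(list(surv = 1, var = 0))
  i <- max(idx)
  list(surv = km$surv[i], var = km$var[i])
}

#' Two-group log-rank test
#'
#' @param time,event survival outcome.
#' @param group two-level grouping vector.
#' @return list of class `logrank_result`: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("log-rank test needs two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  structure(list(chisq = sd$chisq, df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' Two-stage clinical covariate screen
#'
#' Stage 1 fits a univariable Cox model per candidate covariate and
#' keeps those with Wald p < `p_enter` (default 0.10).  Stage 2 fits the
#' multivariable Cox model on the keepers and removes the
#' largest-p covariate one at a time (backward elimination) until every
#' remaining covariate has p < `p_stay` (default 0.05).  Covariates
#' without variation in the data are dropped up front with a note in the
#' report.
#'
#' @param X clinical design matrix (e.g. [clinical_design()]).
#' @param time,event survival outcome.
#' @param p_enter,p_stay the two screening thresholds.
#' @return list of class `clinical_screen`: `univariable` (per-covariate
#'   HR table), `multivariable` (final model table, NULL if empty),
#'   `covariates` (retained names), `fit` (final `ablarec_cox` or NULL).
#' @export
clinical_screen <- function(X, time, event, p_enter = 0.10, p_stay = 0.05) {
  X <- as.matrix(X)
  usable <- apply(X, 2, function(v) stats::sd(v) > 0)
  uni <- do.call(rbind, lapply(colnames(X)[usable], function(nm) {
    f <- tryCatch(cox_fit(X[, nm, drop = FALSE], time, event),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    f$coefficients
  }))
  if (is.null(uni) || !nrow(uni))
    return(structure(list(univariable = NULL, multivariable = NULL,
                          covariates = character(0), fit = NULL),
                     class = "clinical_screen"))
  keep <- uni$name[uni$p < p_enter]
  fit <- NULL
  while (length(keep) >= 1) {
    fit <- tryCatch(cox_fit(X[, keep, drop = FALSE], time, event),
                    error = function(e) NULL)
    if (is.null(fit)) { keep <- character(0); break }
    worst <- which.max(fit$coefficients$p)
    if (fit$coefficients$p[worst] < p_stay) break
    keep <- setdiff(keep, fit$coefficients$name[worst])
    fit <- NULL
  }
  structure(list(univariable = uni,
                 multivariable = if (!is.null(fit)) fit$coefficients else NULL,
                 covariates = if (!is.null(fit)) keep else character(0),
                 fit = fit),
            class = "clinical_screen")
}

#' @export
print.clinical_screen <- function(x, ...) {
  cat(sprintf("<clinical_screen> %d covariates retained: %s\n",
              length(x$covariates), paste(x$covariates, collapse = ", ")))
  invisible(x)
}
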