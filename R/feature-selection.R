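#' Test-retest intra-class correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the ANOVA mean squares of the subjects x 2-raters table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 measurement columns and n subjects.  Symmetric in the two
#' columns and invariant to a common affine rescaling of both.
#'
#' Degenerate rule: if the table has zero total variance (both columns
#' identical and constant) the agreement is perfect by construction and
#' 1 is returned.
#'
#' @param test,retest numeric vectors of per-subject feature values
#'   (length >= 3 each, paired).
#' @return ICC in `(-Inf, 1]`.
#' @export
icc <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest must be paired")
  n <- length(test)
  if (n < 3L) stop("ICC needs at least 3 subjects")
  if (any(!is.finite(test)) || any(!is.finite(retest)))
    stop("non-finite feature values")
  x <- cbind(test, retest)
  k <- 2L
  grand <- mean(x)
  if (all(x == x[1])) return(1)          # zero total variance
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0) return(1)              # only reachable when agreement is exact
  (msr - mse) / denom
}

#' Reproducibility filter: retain features with ICC >= threshold
#'
#' Computes the test-retest ICC of every feature column and retains those
#' at or above the threshold (default 0.75, the conventional cut for
#' good reproducibility).
#'
#' @param test,retest matched feature matrices (same column names;
#'   rows = retest subjects).
#' @param threshold retention threshold on the ICC.
#' @return list with `icc_table` (data.frame: `feature_name`, `icc`,
#'   `retained` — the histogram data of a reproducibility figure) and
#'   `retained` (character vector of retained feature names).
#' @export
filter_by_icc <- function(test, retest, threshold = 0.75) {
  if (!identical(colnames(test), colnames(retest)))
    stop("test and retest matrices must have identical columns")
  if (nrow(test) != nrow(retest))
    stop("test and retest matrices must have the same subjects")
  vals <- vapply(seq_len(ncol(test)),
                 function(j) icc(test[, j], retest[, j]), numeric(1))
  tab <- data.frame(feature_name = colnames(test), icc = vals,
                    retained = vals >= threshold, stringsAsFactors = FALSE)
  list(icc_table = tab, retained = tab$feature_name[tab$retained])
}

#' Gaussian (correlation-based) mutual information
#'
#' `-0.5 * log(1 - rho^2)` with `rho` the Pearson correlation (the
#' point-biserial correlation when one input is binary), clipped to
#' `|rho| <= 1 - 1e-12` so the value stays finite.  Zero by convention
#' when either input is constant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Mutual information in nats, >= 0.
#' @export
mutual_info_gaussian <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  rho <- stats::cor(x, y)
  rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  -0.5 * log(1 - rho^2)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection with the difference (MID) criterion: the
#' first pick maximizes relevance `MI(f; target)`; each subsequent pick
#' maximizes `relevance(f) - mean over selected s of MI(f; s)`, with all
#' mutual informations from [mutual_info_gaussian()].  Ties are broken
#' lexicographically by feature name, so the ranking is deterministic and
#' invariant to input column order.
#'
#' @param features numeric matrix (patients x features, named columns).
#' @param target per-patient outcome vector (e.g. a binary
#'   early-recurrence label), length = nrow(features).
#' @param k number of features to rank (default 20).
#' @return list of class `mrmr_ranking`: `features` (ordered names),
#'   `scores` (per-step criterion values).
#' @export
mrmr_select <- function(features, target, k = 20L) {
  if (is.null(colnames(features))) stop("features must have column names")
  if (nrow(features) != length(target))
    stop("target length must match feature rows")
  if (length(target) < 3L) stop("target must be defined for >= 3 patients")
  p <- ncol(features)
  if (k > p) {
    warning(sprintf("k = %d exceeds the %d available features; selecting all", k, p))
    k <- p
  }
  target <- as.numeric(target)
  nms <- colnames(features)
  relevance <- vapply(seq_len(p),
                      function(j) mutual_info_gaussian(features[, j], target),
                      numeric(1))
  ord <- order(nms)     # lexicographic tie-break: scan candidates in name order
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    cand <- setdiff(ord, selected)
    crit <- relevance[cand] -
      if (length(selected)) red_sum[cand] / length(selected) else 0
    pick <- cand[which.max(crit)]       # first max in name order
    scores <- c(scores, max(crit))
    selected <- c(selected, pick)
    if (step < k) {
      others <- setdiff(seq_len(p), selected)
      red_sum[others] <- red_sum[others] + vapply(
        others, function(j) mutual_info_gaussian(features[, j], features[, pick]),
        numeric(1))
    }
  }
  structure(list(features = nms[selected], scores = scores),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat(sprintf("<mrmr_ranking> %d features; top: %s\n", length(x$features),
              paste(utils::head(x$features, 3), collapse = ", ")))
  invisible(x)
}

#' Binary early-recurrence target for relevance ranking
#'
#' Dichotomizes recurrence-free survival at a horizon (default 24
#' months): 1 if recurrence occurred by the horizon, 0 if followed
#' event-free past it.  Patients censored event-free before the horizon
#' carry no label and are returned as `NA` (callers drop them from
#' relevance estimation).
#'
#' @param time RFS time in months.
#' @param event 0/1 recurrence indicator.
#' @param horizon months (default 24).
#' @return Integer vector with values 0, 1 or `NA`.
#' @export
early_recurrence_label <- function(time, event, horizon = 24) {
  out <- ifelse(event == 1 & time <= horizon, 1L,
                ifelse(time > horizon, 0L, NA_integer_))
  as.integer(out)
}
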