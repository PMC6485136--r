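#' Configuration for a full pipeline run
#'
#' Collects every fixed constant of the analysis in one place: the
#' simulation settings, the train/validation split, the number of
#' test-retest patients, the ICC retention threshold (0.75), the mRMR
#' candidate count (20), the penalty-selection folds (leave-one-out by
#' default), the clinical screening thresholds (0.10 univariable, 0.05
#' multivariable), the bootstrap resample count (1000), the evaluation
#' horizons (12/24/36 months), and the master seed every stochastic
#' stage derives its own seed from.
#'
#' @param sim a [sim_config()]; its `seed` is re-derived from
#'   `master_seed` so one seed governs the whole run.
#' @param n_train,n_val split sizes; default the 129:55 proportion of
#'   `sim$n_patients`.
#' @param n_retest patients re-segmented for the reproducibility filter.
#' @param icc_threshold,mrmr_k,p_enter,p_stay,bootstrap_B,horizons,n_bins
#'   pipeline constants (see above).
#' @param cv_nfolds folds for penalty selection; `NULL` = leave-one-out.
#' @param master_seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_train = NULL, n_val = NULL,
                            n_retest = 20L,
                            icc_threshold = 0.75,
                            mrmr_k = 20L,
                            cv_nfolds = NULL,
                            p_enter = 0.10, p_stay = 0.05,
                            bootstrap_B = 1000L,
                            horizons = c(12, 24, 36),
                            n_bins = 32L,
                            master_seed = 1L) {
  n <- sim$n_patients
  if (is.null(n_train)) n_train <- round(n * 129 / 184)
  if (is.null(n_val)) n_val <- n - n_train
  if (icc_threshold <= 0 || icc_threshold > 1) stop("icc_threshold in (0, 1]")
  if (mrmr_k < 1) stop("mrmr_k must be >= 1")
  if (bootstrap_B < 2) stop("bootstrap_B must be >= 2")
  structure(list(sim = sim, n_train = n_train, n_val = n_val,
                 n_retest = as.integer(n_retest),
                 icc_threshold = icc_threshold, mrmr_k = as.integer(mrmr_k),
                 cv_nfolds = cv_nfolds, p_enter = p_enter, p_stay = p_stay,
                 bootstrap_B = as.integer(bootstrap_B), horizons = horizons,
                 n_bins = as.integer(n_bins),
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A 60-patient cohort on 32-voxel grids at 2 mm spacing with 10 retest
#' patients and 200 bootstrap resamples: the full pipeline in minutes on
#' one CPU.
#'
#' @param master_seed integer master seed.
#' @param n_patients cohort size (default 60).
#' @return A [pipeline_config()].
#' @export
demo_config <- function(master_seed = 1L, n_patients = 60L) {
  pipeline_config(
    sim = sim_config(n_patients = n_patients, volume_dim = 32L, spacing = 2),
    n_retest = 10L, bootstrap_B = 200L, master_seed = master_seed)
}

phases <- c("arterial", "portal_venous", "parenchymal")

#' Run the full radiomics-nomogram analysis
#'
#' Executes, in order: cohort simulation, random train/validation split,
#' per-phase feature extraction (647 features on the original image and
#' 8 wavelet bands), test-retest re-segmentation and ICC filtering, mRMR
#' ranking to 20 candidates, LASSO-Cox signature building with
#' cross-validated penalty per phase plus a three-signature fusion
#' model, the two-stage clinical covariate screen, the four combined
#' (clinical + radiomics) models, discrimination evaluation of all nine
#' models on both datasets with bootstrap confidence intervals,
#' median-split KM summaries, the likelihood-ratio comparison of the
#' combined portal-venous model against the clinical model, and the
#' nomogram with Hosmer-Lemeshow and calibration tables.
#'
#' Every stochastic stage derives its seed deterministically from
#' `config$master_seed`, so a repeated run is identical.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress to stderr.
#' @return A nested report list (class `ablarec_report`); see the
#'   vignette for the schema.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  ms <- config$master_seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  sim <- config$sim
  sim$seed <- derive_seed(ms, "cohort")
  say("[simulate] n=%d patients, seed %d", sim$n_patients, sim$seed)
  cohort <- stage("simulate", generate_cohort(sim))

  clin_all <- clinical_table(cohort)
  if (anyNA(clin_all)) stop("missing clinical values; the pipeline does not impute")

  sp <- stage("split", split_cohort(cohort, config$n_train, config$n_val,
                                    seed = derive_seed(ms, "split")))
  train <- sp$train; val <- sp$validation
  rec_tr <- clinical_table(train); rec_va <- clinical_table(val)
  out_tr <- list(time = rec_tr$rfs_time, event = rec_tr$event)
  out_va <- list(time = rec_va$rfs_time, event = rec_va$event)
  say("[split] %d train / %d validation", length(train), length(val))

  # -- extract -------------------------------------------------------------
  feats <- stage("extract", {
    lapply(stats::setNames(phases, phases), function(ph) {
      say("[extract] phase %s", ph)
      extract_feature_matrix(cohort, ph, config$n_bins)
    })
  })
  ids_tr <- rec_tr$patient_id; ids_va <- rec_va$patient_id

  # -- retest + ICC filter --------------------------------------------------
  set.seed(derive_seed(ms, "retest_pick"))
  retest_ids <- sort(sample(clin_all$patient_id,
                            min(config$n_retest, length(cohort))))
  retest_idx <- match(retest_ids, clin_all$patient_id)
  icc_results <- stage("icc_filter", {
    lapply(stats::setNames(phases, phases), function(ph) {
      say("[retest] phase %s, %d patients", ph, length(retest_idx))
      re_feats <- t(vapply(seq_along(retest_idx), function(k) {
        i <- retest_idx[k]
        pr <- make_retest_pair(cohort[[i]]$volumes[[ph]], cohort[[i]]$mask, sim,
                               seed = derive_seed(ms, paste0("retest_", ph, "_", k)))
        extract_feature_vector(pr$volume, pr$mask, config$n_bins)
      }, numeric(647)))
      filter_by_icc(feats[[ph]][retest_idx, , drop = FALSE], re_feats,
                    threshold = config$icc_threshold)
    })
  })

  # -- mRMR ----------------------------------------------------------------
  er <- early_recurrence_label(out_tr$time, out_tr$event)
  rankings <- stage("mrmr", {
    lapply(stats::setNames(phases, phases), function(ph) {
      X <- feats[[ph]][ids_tr, icc_results[[ph]]$retained, drop = FALSE]
      X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
      ok <- !is.na(er)
      r <- mrmr_select(X[ok, , drop = FALSE], er[ok], k = config$mrmr_k)
      say("[mrmr] phase %s: %d retained -> %d candidates", ph, ncol(X),
          length(r$features))
      r
    })
  })

  # -- signatures ----------------------------------------------------------
  signatures <- list(); sig_tr <- list(); sig_va <- list(); km_tables <- list()
  for (ph in phases) {
    res <- stage(paste0("signature_", ph), {
      Xtr <- feats[[ph]][ids_tr, rankings[[ph]]$features, drop = FALSE]
      Xva <- feats[[ph]][ids_va, rankings[[ph]]$features, drop = FALSE]
      nf <- config$cv_nfolds %||% nrow(Xtr)
      cv <- cv_select_lambda(Xtr, out_tr$time, out_tr$event, nfolds = nf)
      path <- lasso_cox_path(Xtr, out_tr$time, out_tr$event)
      sig <- build_signature(path, cv$lambda, Xtr, phase = ph)
      list(sig = sig, str = score_signature(sig, Xtr),
           sva = score_signature(sig, Xva), cv = cv)
    })
    signatures[[ph]] <- res$sig
    sig_tr[[ph]] <- res$str; sig_va[[ph]] <- res$sva
    grp_tr <- median_stratify(res$str, res$sig$median_cutoff)
    grp_va <- median_stratify(res$sva, res$sig$median_cutoff)
    km_tables[[ph]] <- list(
      train = group_rfs_summary(out_tr$time, out_tr$event, grp_tr, config$horizons),
      validation = group_rfs_summary(out_va$time, out_va$event, grp_va,
                                     config$horizons))
    say("[signature] %s: %d features, lambda %.4f, cutoff %.4f", ph,
        length(res$sig$features), res$sig$lambda, res$sig$median_cutoff)
  }

  Str <- do.call(cbind, sig_tr); colnames(Str) <- paste0("sig_", phases)
  Sva <- do.call(cbind, sig_va); colnames(Sva) <- paste0("sig_", phases)
  sig_ok <- apply(Str, 2, stats::sd) > 0
  fusion_fit <- stage("fusion",
    cox_fit(Str[, sig_ok, drop = FALSE], out_tr$time, out_tr$event))
  fusion_beta <- stats::setNames(fusion_fit$coefficients$beta,
                                 fusion_fit$coefficients$name)

  # -- clinical screen -----------------------------------------------------
  Ctr <- clinical_design(rec_tr); Cva <- clinical_design(rec_va)
  screen <- stage("clinical_screen",
    clinical_screen(Ctr, out_tr$time, out_tr$event,
                    p_enter = config$p_enter, p_stay = config$p_stay))
  say("[clinical] retained: %s",
      if (length(screen$covariates)) paste(screen$covariates, collapse = ", ")
      else "(none)")
  clin_risk <- function(Xc) {
    if (!length(screen$covariates)) return(rep(0, nrow(Xc)))
    beta <- stats::setNames(screen$fit$coefficients$beta,
                            screen$fit$coefficients$name)
    as.numeric(Xc[, names(beta), drop = FALSE] %*% beta)
  }

  # -- combined models -----------------------------------------------------
  combined_fits <- list()
  risk_models <- list(
    clinical = list(train = clin_risk(Ctr), validation = clin_risk(Cva)))
  for (ph in phases) {
    risk_models[[paste0("radiomics_", ph)]] <-
      list(train = sig_tr[[ph]], validation = sig_va[[ph]])
  }
  risk_models$radiomics_fusion <- list(
    train = as.numeric(Str[, sig_ok, drop = FALSE] %*% fusion_beta),
    validation = as.numeric(Sva[, sig_ok, drop = FALSE] %*% fusion_beta))

  combined_design <- function(Xc, S, cols) {
    cbind(Xc[, screen$covariates, drop = FALSE], S[, cols, drop = FALSE])
  }
  for (ph in phases) {
    nm <- paste0("combined_", ph)
    combined_fits[[nm]] <- stage(nm, cox_fit(
      combined_design(Ctr, Str, paste0("sig_", ph)),
      out_tr$time, out_tr$event))
    beta <- stats::setNames(combined_fits[[nm]]$coefficients$beta,
                            combined_fits[[nm]]$coefficients$name)
    risk_models[[nm]] <- list(
      train = as.numeric(combined_design(Ctr, Str, paste0("sig_", ph))[, names(beta), drop = FALSE] %*% beta),
      validation = as.numeric(combined_design(Cva, Sva, paste0("sig_", ph))[, names(beta), drop = FALSE] %*% beta))
  }
  nm <- "combined_all"
  combined_fits[[nm]] <- stage(nm, cox_fit(
    combined_design(Ctr, Str, colnames(Str)[sig_ok]),
    out_tr$time, out_tr$event))
  beta <- stats::setNames(combined_fits[[nm]]$coefficients$beta,
                          combined_fits[[nm]]$coefficients$name)
  risk_models[[nm]] <- list(
    train = as.numeric(combined_design(Ctr, Str, colnames(Str)[sig_ok])[, names(beta), drop = FALSE] %*% beta),
    validation = as.numeric(combined_design(Cva, Sva, colnames(Str)[sig_ok])[, names(beta), drop = FALSE] %*% beta))

  # -- evaluation ----------------------------------------------------------
  say("[evaluate] 9 models x 2 datasets, B = %d", config$bootstrap_B)
  performance <- stage("evaluate",
    evaluate_all(risk_models, out_tr, out_va,
                 B = config$bootstrap_B, seed = derive_seed(ms, "bootstrap")))

  # ANOVA-style nested comparison: clinical vs clinical + portal signature
  comparison <- stage("lrt", {
    if (length(screen$covariates)) {
      lrt_compare(screen$fit, combined_fits$combined_portal_venous)
    } else NULL
  })

  # -- nomogram + calibration ----------------------------------------------
  nomo_fit <- combined_fits$combined_portal_venous
  nomo_X <- combined_design(Ctr, Str, "sig_portal_venous")
  nomogram <- stage("nomogram", build_nomogram(nomo_fit, nomo_X,
                                               horizons = config$horizons))
  nomo_Xva <- combined_design(Cva, Sva, "sig_portal_venous")
  calib <- list(); hl <- list()
  for (h in config$horizons) {
    if (h > nomogram$max_time) next
    pr_tr <- predict_rfs(nomogram, nomo_X, t = h)
    calib[[paste0("train_", h)]] <- tryCatch(
      calibration_table(pr_tr, out_tr$time, out_tr$event, t = h),
      error = function(e) NULL)
    hl[[paste0("train_", h)]] <- tryCatch(
      hl_survival(pr_tr, out_tr$time, out_tr$event,
                  n_groups = min(10L, floor(length(pr_tr) / 5)), t = h),
      error = function(e) NULL)
    if (h <= max(out_va$time)) {
      pr_va <- predict_rfs(nomogram, nomo_Xva, t = h)
      calib[[paste0("validation_", h)]] <- tryCatch(
        calibration_table(pr_va, out_va$time, out_va$event, t = h),
        error = function(e) NULL)
    }
  }

  structure(list(
    config = config,
    cohort_size = length(cohort),
    split = list(n_train = length(train), n_val = length(val),
                 train_ids = ids_tr, validation_ids = ids_va),
    icc = lapply(icc_results, function(r)
      list(n_retained = length(r$retained), icc_table = r$icc_table)),
    mrmr = lapply(rankings, `[[`, "features"),
    signatures = signatures,
    km = km_tables,
    clinical = screen,
    fusion = fusion_fit,
    combined = combined_fits,
    performance = performance,
    comparison = comparison,
    nomogram = nomogram,
    calibration = calib,
    hosmer_lemeshow = hl,
    risk_models = risk_models,
    outcomes = list(train = out_tr, validation = out_va)
  ), class = "ablarec_report")
}

#' @export
print.ablarec_report <- function(x, ...) {
  cat(sprintf("<ablarec_report> %d patients (%d/%d split)\n", x$cohort_size,
              x$split$n_train, x$split$n_val))
  cat("  ICC-retained features:",
      paste(sprintf("%s=%d", names(x$icc),
                    vapply(x$icc, `[[`, 0L, "n_retained")), collapse = ", "), "\n")
  cat("  C-index (train/validation):\n")
  perf <- x$performance
  for (m in unique(perf$model)) {
    tr <- perf[perf$model == m & perf$dataset == "train", ]
    va <- perf[perf$model == m & perf$dataset == "validation", ]
    cat(sprintf("    %-28s %.3f (%.3f-%.3f) / %.3f (%.3f-%.3f)\n", m,
                tr$c_index, tr$ci_low, tr$ci_high,
                va$c_index, va$ci_low, va$ci_high))
  }
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes/masks + clinical CSV)
#'
#' One `<id>_<phase>.nii.gz` per phase per patient, one
#' `<id>_mask.nii.gz`, and `clinical.csv` with one row per patient.
#'
#' @param cohort an `ablarec_cohort` with images.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    id <- p$record$patient_id
    if (is.null(p$volumes)) stop("cohort was generated without images")
    for (ph in names(p$volumes))
      write_volume(p$volumes[[ph]], file.path(dir, sprintf("%s_%s.nii.gz", id, ph)))
    write_mask(p$mask, file.path(dir, sprintf("%s_mask.nii.gz", id)))
  }
  utils::write.csv(clinical_table(cohort), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}
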