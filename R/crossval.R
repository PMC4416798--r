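# Leave-one-session-out cross-validation driver: per fold, two-pass ICA
# on the training sessions, dipole/eye component rejection, SLR-count
# component selection, artifactual-epoch rejection, PCA + sparse
# logistic classification, and the pre-onset variant. The per-fold
# spatial models are kept for the pseudo-online path and the QC
# analyses.

#' Simulate and preprocess all sessions of a subject
#'
#' Each session is simulated at the acquisition rate, band-passed to
#' 1-45 Hz with the automatically-ordered FIR design, resampled to the
#' analysis rate, and additionally filtered to 8-40 Hz for epoch
#' extraction.
#'
#' @param config Configuration list.
#' @param seed Cohort seed.
#' @param subject Subject index.
#' @return List with `rec145` and `rec840`: lists of 10 recordings at
#'   the analysis rate (1-45 Hz, and additionally 8-40 Hz filtered).
#'   Epoch sets are extracted from `rec840` on demand by the fold
#'   drivers, which keeps the memory footprint bounded.
#' @export
prepare_subject <- function(config, seed = 1, subject = 1) {
  conditions <- session_conditions()
  spec_wide <- design_fir(config$preprocess$band, config$fs)
  spec_feat <- design_fir(config$preprocess$feature_band,
                          config$fs_analysis)
  rec145 <- vector("list", length(conditions))
  rec840 <- vector("list", length(conditions))
  q <- config$fs / config$fs_analysis
  for (i in seq_along(conditions)) {
    raw <- simulate_session(config, conditions[i], seed, subject, i)
    # fused band-pass + decimation (the 1-45 Hz band-pass provides the
    # anti-aliasing margin for the downsampling)
    r <- raw
    r$data <- .bandpass_decimate(raw$data, spec_wide$coefficients, q)
    r$fs <- config$fs_analysis
    if (nrow(r$events) > 0) {
      sc <- r$events$onset_sample / q
      r$events$onset_sample <- as.integer(sign(sc) * floor(abs(sc) + 0.5))
    }
    rm(raw)
    r$profile <- NULL                  # events carry what the folds need
    rec145[[i]] <- r
    r8 <- r
    r8$data <- .filtfilt_zero(r$data, spec_feat$coefficients)
    rec840[[i]] <- r8
    gc(FALSE)
  }
  list(rec145 = rec145, rec840 = rec840, conditions = conditions,
       subject = subject, seed = seed)
}

# batch epoch sets of the given sessions, extracted on demand
.batch_epochs <- function(prep, idx, config) {
  lapply(idx, function(i)
    suppressMessages(extract_batch(prep$rec840[[i]], config = config)))
}

# concatenate epoch sets (same channel count and epoch length)
.bind_epochs <- function(eps) {
  eps <- eps[!vapply(eps, is.null, TRUE)]
  datas <- lapply(eps, function(e) e$data)
  n <- sum(vapply(datas, function(d) dim(d)[1], 0))
  d1 <- dim(datas[[1]])
  arr <- array(0, c(n, d1[2], d1[3]))
  off <- 0
  for (d in datas) {
    arr[(off + 1):(off + dim(d)[1]), , ] <- d
    off <- off + dim(d)[1]
  }
  out <- eps[[1]]
  out$data <- arr
  for (f in c("label", "subclass", "session", "trial", "center",
              "condition")) {
    out[[f]] <- unlist(lapply(eps, function(e) e[[f]]), use.names = FALSE)
  }
  out
}

# fit the fold's spatial model and component masks
.fold_spatial <- function(prep, test_session, config, seed) {
  train_idx <- setdiff(seq_along(prep$rec145), test_session)
  model <- fit_ica_two_pass(prep$rec145[train_idx], seed = seed,
                            config = config)
  mont <- .cfg_montage(config)
  hm <- .cfg_model(config)
  fits <- lapply(seq_len(model$n_comp), function(k)
    fit_single_dipole(model$scalp_maps[, k], mont, hm,
                      n_restarts = config$dipole$n_restarts,
                      seed = seed + k))
  dip <- reject_components_by_dipole(fits, config$dipole$rv_max,
                                     config$dipole$radial_max,
                                     config$dipole$z_min)
  # eye criterion on up to 2 min of training activations
  Xact <- do.call(cbind, lapply(prep$rec145[train_idx[1:min(2, length(train_idx))]],
                                function(r) r$data))
  Xact <- Xact[, seq_len(min(ncol(Xact), 120 * config$fs_analysis)),
               drop = FALSE]
  eye <- detect_eye_components(model$scalp_maps, model$unmixing %*% Xact,
                               mont, config$fs_analysis,
                               config$eye$frontal_factor,
                               config$eye$lowfreq_frac,
                               config$eye$kurtosis_min)
  candidates <- which(dip$keep & !eye)
  if (length(candidates) < 2) {
    rv <- vapply(fits, function(f) f$residual_variance, 0)
    candidates <- order(rv)[1:2]
  }
  list(model = model, fits = fits, dipole_keep = dip$keep,
       dipole_reasons = dip$reasons, eye = eye, candidates = candidates,
       train_sessions = train_idx, test_session = test_session)
}

# run one batch fold end to end; returns predictions and fold artifacts
.fold_batch <- function(prep, fold, config, seed) {
  sp <- .fold_spatial(prep, fold, config, seed)
  tfc <- tf_config(fs = config$fs_analysis,
                   n_windows = config$tf$n_windows_batch,
                   n_freqs = config$tf$n_freqs, f_lo = config$tf$f_lo,
                   f_hi = config$tf$f_hi,
                   window_len = config$tf$window_len,
                   cycles = config$tf$cycles,
                   power_floor = config$tf$power_floor)
  train_ep <- .bind_epochs(.batch_epochs(prep, sp$train_sessions, config))
  test_ep <- .batch_epochs(prep, fold, config)[[1]]
  tr_c <- apply_unmixing(train_ep, sp$model, sp$candidates)
  rm(train_ep)
  te_c <- apply_unmixing(test_ep, sp$model, sp$candidates)
  rm(test_ep)
  gc(FALSE)
  tr_tf <- epochs_tf(tr_c, tfc)
  rm(tr_c)
  te_tf <- epochs_tf(te_c, tfc)
  rm(te_c)
  gc(FALSE)
  selection <- select_components_by_slr(tr_tf, sp$candidates,
                                        seed = seed,
                                        nfolds = config$slr$nfolds)
  ret <- match(selection$retained_ids, sp$candidates)
  tr_tf_r <- .subset_tf(tr_tf, ret)
  te_tf_r <- .subset_tf(te_tf, ret)
  baseline <- tf_baseline(tr_tf_r)
  keep_tr <- reject_artifactual_epochs(tr_tf_r, baseline,
                                       config$reject_epoch$band,
                                       config$reject_epoch$hi_db,
                                       config$reject_epoch$lo_db)
  keep_te <- reject_artifactual_epochs(te_tf_r, baseline,
                                       config$reject_epoch$band,
                                       config$reject_epoch$hi_db,
                                       config$reject_epoch$lo_db)
  tr_tf_r <- .subset_tf_epochs(tr_tf_r, keep_tr)
  te_tf_r <- .subset_tf_epochs(te_tf_r, keep_te)
  fv_tr <- build_feature_vectors(tr_tf_r)
  fv_te <- build_feature_vectors(te_tf_r)
  pca <- fit_pca(fv_tr$X, config$pca_var)
  slr <- fit_slr(project_pca(fv_tr$X, pca), fv_tr$y, seed = seed,
                 nfolds = config$slr$nfolds)
  prob <- predict_slr(slr, project_pca(fv_te$X, pca))
  # pre-onset variant: windows wholly before the onset, same spatial
  # model, classifier retrained
  pre_rng <- c(-Inf, -(config$tf$window_len - 1) / 2 / config$fs_analysis)
  fv_tr_pre <- build_feature_vectors(tr_tf_r, pre_rng)
  fv_te_pre <- build_feature_vectors(te_tf_r, pre_rng)
  pca_pre <- fit_pca(fv_tr_pre$X, config$pca_var)
  slr_pre <- fit_slr(project_pca(fv_tr_pre$X, pca_pre), fv_tr_pre$y,
                     seed = seed, nfolds = config$slr$nfolds)
  prob_pre <- predict_slr(slr_pre, project_pca(fv_te_pre$X, pca_pre))
  trials <- data.frame(fold = fold, session = fv_te$session,
                       condition = fv_te$condition,
                       truth = fv_te$y, subclass = fv_te$subclass,
                       prob = prob, pred = classify_proba(prob),
                       prob_pre = prob_pre,
                       pred_pre = classify_proba(prob_pre),
                       stringsAsFactors = FALSE)
  list(trials = trials, spatial = sp, selection = selection,
       baseline = baseline, pca = pca, slr = slr,
       n_rejected_epochs = sum(!keep_tr) + sum(!keep_te),
       retained_ids = selection$retained_ids)
}

.subset_tf <- function(tf, comp_idx) {
  tf$power <- tf$power[, comp_idx, , , drop = FALSE]
  tf
}

.subset_tf_epochs <- function(tf, keep) {
  tf$power <- tf$power[keep, , , , drop = FALSE]
  for (f in c("label", "subclass", "session", "trial", "center",
              "condition"))
    tf[[f]] <- tf[[f]][keep]
  tf
}

#' Leave-one-session-out cross-validation of one subject
#'
#' @param prep A [prepare_subject()] result.
#' @param config Configuration list.
#' @param seed Integer seed (per-fold seeds are derived from it).
#' @return List with `trials` (pooled test predictions across folds)
#'   and `folds` (per-fold artifacts: spatial model, dipole fits,
#'   selection report, classifier).
#' @export
crossvalidate <- function(prep, config = default_config(), seed = 1) {
  n_sessions <- length(prep$rec145)
  if (n_sessions < 10)
    warning("fewer than 10 sessions; fold count adjusted to ", n_sessions)
  folds <- lapply(seq_len(n_sessions), function(s) {
    fb <- .fold_batch(prep, s, config, .derive_seed(seed, prep$subject, 100 + s))
    message(sprintf("subject %d fold %d: %d candidates, %d retained, test accuracy %.2f",
                    prep$subject, s, length(fb$spatial$candidates),
                    length(fb$retained_ids),
                    mean(fb$trials$truth == fb$trials$pred)))
    gc(FALSE)
    fb
  })
  trials <- do.call(rbind, lapply(folds, function(f) f$trials))
  trials$subject <- prep$subject
  list(trials = trials, folds = folds, subject = prep$subject)
}

#' Run the batch experiment on a synthetic cohort
#'
#' Simulates every subject, runs the leave-one-session-out
#' cross-validation, and assembles the summary tables: per-subject
#' class-wise accuracy, full/cued/uncued kappas, subclass kappas and
#' the pre-onset comparison.
#'
#' @param config Configuration list.
#' @param seed Cohort seed.
#' @param subjects Subject indices (default `1:config$cohort$n_subjects`).
#' @param keep_prep Keep the preprocessed sessions in the result (needed
#'   by [run_pseudo_online()] and the QC analyses; default TRUE).
#' @param keep_rec145 Also keep the wide-band (1-45 Hz) recordings in
#'   each subject's prep (only needed for the channel-correlation QC;
#'   default FALSE to bound memory).
#' @return A `batch_result`.
#' @export
run_batch <- function(config = default_config(), seed = 1,
                      subjects = NULL, keep_prep = TRUE,
                      keep_rec145 = FALSE) {
  if (is.null(subjects)) subjects <- seq_len(config$cohort$n_subjects)
  res <- list()
  for (s in subjects) {
    prep <- prepare_subject(config, seed, s)
    cv <- crossvalidate(prep, config, seed)
    if (!keep_rec145) prep$rec145 <- NULL
    res[[as.character(s)]] <- list(
      cv = cv, prep = if (keep_prep) prep else NULL)
    rm(prep); gc(FALSE)
  }
  trials <- do.call(rbind, lapply(res, function(r) r$cv$trials))
  summary <- .batch_summary(trials)
  structure(list(subjects = res, trials = trials, summary = summary,
                 config = config, seed = seed),
            class = "batch_result")
}

.batch_summary <- function(trials) {
  subjects <- sort(unique(trials$subject))
  acc <- lapply(subjects, function(s) {
    d <- trials[trials$subject == s, ]
    cm <- confusion_matrix(d$truth, d$pred)
    a <- classwise_accuracy(cm)
    k <- kappa_score(cm)
    kp <- kappa_score(confusion_matrix(d$truth, d$pred_pre))
    data.frame(subject = s, accuracy = a$mean, accuracy_sd = a$sd,
               kappa = k$k, kappa_l = k$k_l, significant = k$significant,
               kappa_pre = kp$k, kappa_pre_l = kp$k_l)
  })
  acc <- do.call(rbind, acc)
  cond <- split_condition_kappa(trials)
  subcls <- list()
  for (sc in c("0->1", "1->2", "2->1", "1->0"))
    subcls[[sc]] <- subclass_kappa(trials, sc)
  list(per_subject = acc, condition = cond, subclass = subcls)
}
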