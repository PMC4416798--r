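# Pseudo-online decoding: jittered 2 s training windows, sliding test
# windows, all-or-nothing trial scores and ROC/AUC for averaging orders
# m = 1, 2, 3, plus the decoder output time-courses. Each fold reuses
# the spatial model of the corresponding batch fold.

#' Run the pseudo-online experiment
#'
#' For every subject and fold of a finished batch run: the training
#' sessions' jittered 2 s epochs and the test session's sliding epochs
#' are unmixed with the fold's spatial model, decomposed on the
#' 14-window TF grid, component-selected, and classified with a freshly
#' trained PCA + SLR model. Each test trial contributes 9 time-ordered
#' probabilities; the all-or-nothing score (maximum of the moving
#' average of order m) yields one ROC/AUC per averaging order, and the
#' per-bin output quartiles give the decoder time-course.
#'
#' @param batch A [run_batch()] result with `keep_prep = TRUE`.
#' @param config Configuration list (defaults to the batch config).
#' @param seed Integer seed.
#' @return An `online_result`: `epochs` (per-epoch probabilities),
#'   `scores` (per trial x m), `roc` (per subject and m), `timecourse`.
#' @export
run_pseudo_online <- function(batch, config = NULL, seed = 1) {
  if (is.null(config)) config <- batch$config
  tfc <- tf_config(fs = config$fs_analysis,
                   n_windows = config$tf$n_windows_sliding,
                   n_freqs = config$tf$n_freqs, f_lo = config$tf$f_lo,
                   f_hi = config$tf$f_hi,
                   window_len = config$tf$window_len,
                   cycles = config$tf$cycles,
                   power_floor = config$tf$power_floor)
  all_ep <- NULL
  all_scores <- NULL
  roc <- list()
  for (s_chr in names(batch$subjects)) {
    sub <- batch$subjects[[s_chr]]
    if (is.null(sub$prep))
      stop("run_batch must be called with keep_prep = TRUE before the pseudo-online analysis")
    prep <- sub$prep
    s <- prep$subject
    for (fold in seq_along(sub$cv$folds)) {
      fb <- sub$cv$folds[[fold]]
      sp <- fb$spatial
      fseed <- .derive_seed(seed, s, 200 + fold)
      tr_ep <- .bind_epochs(lapply(sp$train_sessions, function(i)
        suppressMessages(extract_sliding(prep$rec840[[i]], mode = "train",
                                         config = config))))
      te_ep <- suppressMessages(extract_sliding(prep$rec840[[fold]],
                                                mode = "test",
                                                config = config))
      tr_c <- apply_unmixing(tr_ep, sp$model, sp$candidates)
      rm(tr_ep)
      te_c <- apply_unmixing(te_ep, sp$model, sp$candidates)
      rm(te_ep)
      tr_tf <- epochs_tf(tr_c, tfc)
      rm(tr_c)
      te_tf <- epochs_tf(te_c, tfc)
      rm(te_c)
      gc(FALSE)
      # the batch fold's component selection is reused along with its
      # spatial model ("the independent components were not recomputed")
      ret <- match(fb$retained_ids, sp$candidates)
      tr_tf <- .subset_tf(tr_tf, ret)
      te_tf <- .subset_tf(te_tf, ret)
      baseline <- tf_baseline(tr_tf)
      keep_tr <- reject_artifactual_epochs(tr_tf, baseline,
                                           config$reject_epoch$band,
                                           config$reject_epoch$hi_db,
                                           config$reject_epoch$lo_db)
      tr_tf <- .subset_tf_epochs(tr_tf, keep_tr)
      fv_tr <- build_feature_vectors(tr_tf)
      fv_te <- build_feature_vectors(te_tf)
      pca <- fit_pca(fv_tr$X, config$pca_var)
      slr <- fit_slr(project_pca(fv_tr$X, pca), fv_tr$y, seed = fseed,
                     nfolds = config$slr$nfolds)
      prob <- predict_slr(slr, project_pca(fv_te$X, pca))
      all_ep <- rbind(all_ep, data.frame(
        subject = s, fold = fold, trial = fv_te$trial,
        label = fv_te$y, center = fv_te$center, prob = prob,
        stringsAsFactors = FALSE))
    }
    # all-or-nothing scores per trial and averaging order
    d <- all_ep[all_ep$subject == s, ]
    key <- paste(d$fold, d$trial)
    for (k in unique(key)) {
      dd <- d[key == k, ]
      dd <- dd[order(dd$center), ]
      for (m in 1:3) {
        all_scores <- rbind(all_scores, data.frame(
          subject = s, fold = dd$fold[1], trial = dd$trial[1],
          label = dd$label[1], m = m,
          score = allornothing_score(dd$prob, m),
          stringsAsFactors = FALSE))
      }
    }
    roc[[s_chr]] <- lapply(1:3, function(m) {
      ds <- all_scores[all_scores$subject == s & all_scores$m == m, ]
      roc_auc(ds$score, ds$label)
    })
  }
  tc <- lapply(split(all_ep, all_ep$subject), function(d)
    output_timecourse(d$prob, d$center, d$label))
  structure(list(epochs = all_ep, scores = all_scores, roc = roc,
                 timecourse = tc),
            class = "online_result")
}
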