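# Performance assessment: pooled confusion matrices, class-wise
# accuracy, Cohen's kappa with the corrected adjusted-Wald lower bound,
# condition and subclass splits, all-or-nothing trial scores, ROC/AUC
# and decoder output time-courses.

#' Build a 2x2 confusion matrix
#'
#' Rows are the true class, columns the predicted class, in the order
#' (constant, change).
#'
#' @param truth,pred Label vectors (`"change"` / `"constant"`).
#' @return 2x2 integer matrix.
#' @export
confusion_matrix <- function(truth, pred) {
  lv <- c("constant", "change")
  table(factor(truth, lv), factor(pred, lv))
}

#' Class-wise normalised accuracy
#'
#' Rows of the summed confusion matrix are normalised to 1; the mean and
#' SD of the two diagonal entries give the cross-validated accuracy.
#'
#' @param cm 2x2 confusion matrix (rows = truth).
#' @return List with `mean` and `sd`, in percent.
#' @export
classwise_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("every true class needs at least one trial")
  diag_norm <- diag(cm / rs)
  list(mean = 100 * mean(diag_norm), sd = 100 * stats::sd(diag_norm))
}

#' Cohen's kappa with the corrected adjusted-Wald lower bound
#'
#' `k = (p - p0) / (1 - p0)` with `p` the observed agreement and `p0`
#' the chance agreement from the marginals. The adjusted estimate uses
#' `p_hat = (C + 2) / (N + 4)` and the lower confidence bound is
#' `k_l = k_hat - z * sqrt(p_hat (1 - p_hat) / ((N + 4) (1 - p0)^2))`
#' (the square root covering the (N + 4) term). The kappa is significant
#' when `k_l > 0`.
#'
#' @param cm 2x2 confusion matrix (rows = truth).
#' @param alpha Significance level (default 0.05; `z` is the two-sided
#'   normal quantile, 1.96 at 0.05).
#' @return A `kappa_result` with `k`, `p`, `p0`, `k_hat`, `p_hat`,
#'   `k_l`, `z`, `N`, `C`, `significant`.
#' @export
kappa_score <- function(cm, alpha = 0.05) {
  cm <- as.matrix(cm)
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  C <- sum(diag(cm))
  p <- C / N
  p0 <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (p0 >= 1) stop("chance agreement is 1; kappa undefined")
  z <- stats::qnorm(1 - alpha / 2)
  k <- (p - p0) / (1 - p0)
  p_hat <- (C + 2) / (N + 4)
  k_hat <- (p_hat - p0) / (1 - p0)
  k_l <- k_hat - z * sqrt(p_hat * (1 - p_hat) / ((N + 4) * (1 - p0)^2))
  structure(list(k = k, p = p, p0 = p0, k_hat = k_hat, p_hat = p_hat,
                 k_l = k_l, z = z, N = N, C = C,
                 significant = k_l > 0),
            class = "kappa_result")
}

#' Pool fold confusion matrices by condition and compare across subjects
#'
#' Sums each subject's cued test-fold confusion matrices separately
#' from the uncued ones, computes the condition kappas, and compares
#' them across subjects with a two-sided paired t-test.
#'
#' @param fold_tables data.frame with columns `subject`, `condition`,
#'   `truth`, `pred` (one row per test trial).
#' @return List with per-subject `kappa_cued` / `kappa_uncued`
#'   (`kappa_result` lists) and `t_test` (p-value; 1 when the paired
#'   differences have zero variance).
#' @export
split_condition_kappa <- function(fold_tables) {
  subjects <- sort(unique(fold_tables$subject))
  kc <- list(); ku <- list()
  for (s in subjects) {
    d <- fold_tables[fold_tables$subject == s, ]
    for (cond in c("cued", "uncued")) {
      dd <- d[d$condition == cond, ]
      if (nrow(dd) == 0) next
      res <- kappa_score(confusion_matrix(dd$truth, dd$pred))
      if (cond == "cued") kc[[as.character(s)]] <- res
      else ku[[as.character(s)]] <- res
    }
  }
  common <- intersect(names(kc), names(ku))
  p_val <- NA_real_
  if (length(common) >= 2) {
    dk <- vapply(common, function(s) kc[[s]]$k - ku[[s]]$k, 0)
    p_val <- if (stats::sd(dk) == 0) 1
             else stats::t.test(dk)$p.value
  } else if (length(common) >= 1) {
    p_val <- 1
  }
  list(kappa_cued = kc, kappa_uncued = ku, t_test = p_val)
}

#' Kappa restricted to one change-speed subclass
#'
#' Restricts the pooled predictions to change trials of the given
#' transition and constant trials at the preceding speed (e.g. "1->2"
#' vs "1"), and computes the kappa of the restricted confusion counts.
#'
#' @param fold_tables data.frame with `truth`, `pred`, `subclass`.
#' @param subclass One of `"0->1"`, `"1->2"`, `"2->1"`, `"1->0"`.
#' @return A `kappa_result`, or NULL (with a warning) when the subclass
#'   is empty.
#' @export
subclass_kappa <- function(fold_tables, subclass) {
  from_speed <- sub("->.*", "", subclass)
  sel <- (fold_tables$truth == "change" & fold_tables$subclass == subclass) |
    (fold_tables$truth == "constant" & fold_tables$subclass == from_speed)
  d <- fold_tables[sel, ]
  if (nrow(d) == 0 || length(unique(d$truth)) < 2) {
    warning("subclass ", subclass, " has no paired trials")
    return(NULL)
  }
  kappa_score(confusion_matrix(d$truth, d$pred))
}

#' All-or-nothing trial scores from sliding-window probabilities
#'
#' A trial's score is the maximum of the moving average (window `m`) of
#' its 9 time-ordered epoch probabilities; `m = 1` is the plain maximum.
#'
#' @param probs Numeric vector of per-epoch probabilities, in time
#'   order.
#' @param m Averaging order (1, 2 or 3).
#' @return The trial score.
#' @export
allornothing_score <- function(probs, m = 1) {
  n <- length(probs)
  if (m > n) stop("averaging order exceeds the number of epochs")
  if (m == 1) return(max(probs))
  ma <- vapply(seq_len(n - m + 1), function(i) mean(probs[i:(i + m - 1)]),
               0)
  max(ma)
}

#' ROC curve and AUC by threshold sweep
#'
#' @param scores Per-trial scores.
#' @param labels Per-trial labels (`"change"` = positive).
#' @return A `roc_result`: `fpr`, `tpr` (monotone non-decreasing),
#'   `auc` (trapezoid rule).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "change"
  if (!any(pos) || all(pos)) stop("both classes are required for a ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_result")
}

#' Decoder output time-course summaries
#'
#' Median and quartiles of the decoder output probability per sliding
#' time bin and class.
#'
#' @param probs Per-epoch probabilities.
#' @param centers Epoch centres (s relative to onset).
#' @param labels Epoch class labels.
#' @return data.frame with `class`, `center_s`, `median`, `q25`, `q75`,
#'   `n`.
#' @export
output_timecourse <- function(probs, centers, labels) {
  out <- NULL
  for (cl in unique(labels)) {
    for (c0 in sort(unique(centers[labels == cl]))) {
      p <- probs[labels == cl & centers == c0]
      q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      out <- rbind(out, data.frame(class = cl, center_s = c0,
                                   median = q[2], q25 = q[1], q75 = q[3],
                                   n = length(p)))
    }
  }
  out
}
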