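# Component selection by sparse-logistic-regression feature counts with
# the scree-test acceleration factor, artifactual-epoch rejection in the
# 20-40 Hz band, and feature-vector assembly.

#' Select neural components by sparse-logistic-regression feature counts
#'
#' One L1-regularised logistic model is fitted on the flattened
#' time-frequency features of all candidate components; the nonzero
#' weights are counted per component; the counts are sorted in
#' descending order and the scree-test acceleration factor
#' `a_i = c_{i+1} - 2 c_i + c_{i-1}` is evaluated on the sorted counts.
#' Components ranked strictly before the elbow (the rank maximising the
#' acceleration factor) are retained, with a minimum of one. With fewer
#' than three candidates, or when all counts are equal, all components
#' are retained.
#'
#' @param tf A `tf_tensor` of training epochs restricted to the
#'   candidate components.
#' @param component_ids Integer ids the tensor's component axis refers
#'   to.
#' @param seed Integer seed for the internal cross-validation of the
#'   regularisation path.
#' @param nfolds Internal CV folds (default 5).
#' @return A `selection_report`: `counts` (per component, input order),
#'   `sorted_counts`, `acceleration`, `elbow_rank`, `retained_ids`.
#' @export
select_components_by_slr <- function(tf, component_ids = NULL, seed = 1,
                                     nfolds = 5) {
  d <- dim(tf$power)
  n_comp <- d[2]
  if (is.null(component_ids)) component_ids <- seq_len(n_comp)
  if (n_comp < 2) stop("need at least two candidate components")
  X <- matrix(tf$power, d[1], n_comp * d[3] * d[4])
  y <- as.integer(tf$label == "change")
  fit <- .slr_glmnet(X, y, seed = seed, nfolds = nfolds)
  w <- fit$weights
  comp_of_feature <- rep_len(seq_len(n_comp), length(w))
  counts <- vapply(seq_len(n_comp), function(k)
    sum(w[comp_of_feature == k] != 0), integer(1))
  if (all(counts == 0)) stop("sparse model selected no features at all")
  sc <- scree_retain(counts)
  retained <- component_ids[sc$order[seq_len(sc$n_keep)]]
  structure(list(counts = counts, order = sc$order,
                 sorted_counts = sc$sorted,
                 acceleration = sc$acceleration,
                 elbow_rank = sc$elbow_rank,
                 retained_ids = sort(retained),
                 component_ids = component_ids),
            class = "selection_report")
}

#' Scree-test acceleration-factor elbow rule
#'
#' Sorts the per-component feature counts in descending order (ties
#' broken by ascending component index), computes the acceleration
#' factor `a_i = c_{i+1} - 2 c_i + c_{i-1}` at the interior ranks, and
#' retains the ranks strictly before the elbow (the rank with maximal
#' acceleration), with a minimum of one. All components are kept when
#' there are fewer than three or all counts are equal. The rule is
#' invariant to rescaling all counts by a positive constant.
#'
#' @param counts Per-component nonzero-weight counts.
#' @return List with `order` (sorting permutation), `sorted`,
#'   `acceleration`, `elbow_rank` and `n_keep`.
#' @export
scree_retain <- function(counts) {
  n <- length(counts)
  ord <- order(counts, -seq_along(counts), decreasing = TRUE,
               method = "radix")
  sorted <- counts[ord]
  if (n < 3 || length(unique(sorted)) == 1) {
    return(list(order = ord, sorted = sorted, acceleration = numeric(0),
                elbow_rank = NA_integer_, n_keep = n))
  }
  i <- 2:(n - 1)
  accel <- sorted[i + 1] - 2 * sorted[i] + sorted[i - 1]
  elbow <- i[which.max(accel)]
  list(order = ord, sorted = sorted, acceleration = accel,
       elbow_rank = elbow, n_keep = max(1L, elbow - 1L))
}

#' Reject epochs with abnormal high-band power perturbations
#'
#' An epoch is rejected when, for at least one retained component, its
#' power in any 20-40 Hz bin of any time window deviates from the
#' training baseline by more than +25 dB or less than -100 dB.
#'
#' @param tf A `tf_tensor` restricted to the retained components.
#' @param baseline components x freqs matrix of baseline dB power (mean
#'   log spectrum of the training constant-speed epochs); see
#'   [tf_baseline()].
#' @param band Frequency band checked (default 20-40 Hz).
#' @param hi_db,lo_db Rejection bounds in dB (defaults +25 / -100).
#' @return Logical keep-mask, one entry per epoch.
#' @export
reject_artifactual_epochs <- function(tf, baseline, band = c(20, 40),
                                      hi_db = 25, lo_db = -100) {
  d <- dim(tf$power)
  fsel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  keep <- rep(TRUE, d[1])
  for (k in seq_len(d[2])) {
    # epochs x freqs x windows deviation from baseline
    dev <- sweep(tf$power[, k, fsel, , drop = FALSE], 3,
                 baseline[k, fsel], "-")
    bad <- apply(dev, 1, function(v) any(v > hi_db | v < lo_db))
    keep <- keep & !bad
  }
  keep
}

#' Baseline mean log spectrum per component and frequency
#'
#' @param tf A `tf_tensor` of training epochs.
#' @param class Epoch class the baseline is computed from (default the
#'   constant-speed class, matching the ERSP convention).
#' @return components x freqs matrix (dB).
#' @export
tf_baseline <- function(tf, class = "constant") {
  sel <- tf$label == class
  if (!any(sel)) stop("no epochs of class ", class)
  apply(tf$power[sel, , , , drop = FALSE], c(2, 3), mean)
}

#' Flatten a TF tensor into per-trial feature vectors
#'
#' Per retained component the frequency x time grid is flattened and the
#' blocks are concatenated in fixed component order. With
#' `window_range`, only windows whose centres fall inside the range are
#' used (the pre-onset variant uses windows wholly before the onset).
#'
#' @param tf A `tf_tensor` restricted to the retained components.
#' @param window_range Optional time range (s) restricting the windows.
#' @return List with `X` (epochs x features), `y` (labels), plus the
#'   epoch metadata columns.
#' @export
build_feature_vectors <- function(tf, window_range = NULL) {
  d <- dim(tf$power)
  wsel <- if (is.null(window_range)) seq_len(d[4])
          else which(tf$times >= window_range[1] & tf$times <= window_range[2])
  if (length(wsel) == 0) stop("window range excludes all TF windows")
  pw <- tf$power[, , , wsel, drop = FALSE]
  # feature order: component-major, then frequency, then time
  X <- matrix(aperm(pw, c(1, 3, 4, 2)), d[1],
              length(wsel) * d[3] * d[2])
  list(X = X, y = tf$label, subclass = tf$subclass, session = tf$session,
       trial = tf$trial, center = tf$center, condition = tf$condition,
       n_features_per_component = d[3] * length(wsel))
}
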