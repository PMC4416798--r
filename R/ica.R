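# Two-pass ICA with probability-based segment rejection. The spatial
# model (unmixing/mixing/scalp maps) learned on the training sessions of
# a fold is shared by the batch and pseudo-online paths.

#' Probability-based rejection of signal segments
#'
#' The signal is cut into contiguous segments; every channel's empirical
#' density is estimated by a histogram over the whole signal, each
#' segment is scored by its joint log-probability under these densities,
#' and segments whose score deviates from the mean score by more than
#' `z` standard deviations are marked for removal.
#'
#' @param X Channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param seg_len_s Segment length in seconds (default 0.5).
#' @param z Rejection threshold in SDs of the segment score (default 5).
#' @param n_bins Histogram bins per channel (default 50).
#' @return Logical keep-mask, one entry per segment; segment boundaries
#'   as attribute `"starts"` (0-based sample offsets).
#' @export
reject_segments <- function(X, fs, seg_len_s = 0.5, z = 5, n_bins = 50) {
  X <- as.matrix(X)
  seg <- round(seg_len_s * fs)
  n_seg <- floor(ncol(X) / seg)
  if (n_seg < 20) stop("need at least 20 segments for stable statistics")
  scores <- numeric(n_seg)
  used <- n_seg * seg
  for (ch in seq_len(nrow(X))) {
    x <- X[ch, ]
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    h <- .bincode(x, br, include.lowest = TRUE)
    dens <- tabulate(h, n_bins) / length(x)
    lp <- log(pmax(dens[h[seq_len(used)]], 1e-12))
    scores <- scores + colSums(matrix(lp, seg, n_seg))
  }
  mu <- mean(scores); sd_s <- stats::sd(scores)
  keep <- if (sd_s == 0) rep(TRUE, n_seg) else abs(scores - mu) <= z * sd_s
  attr(keep, "starts") <- (seq_len(n_seg) - 1L) * seg
  attr(keep, "seg_len") <- seg
  keep
}

# drop rejected segments from a channels x samples matrix
.apply_segment_mask <- function(X, keep) {
  seg <- attr(keep, "seg_len")
  starts <- attr(keep, "starts")
  idx <- unlist(lapply(which(keep), function(s)
    (starts[s] + 1):(starts[s] + seg)))
  X[, idx, drop = FALSE]
}

# FastICA with symmetric orthogonalisation and logcosh contrast on
# whitened data; deterministic given seed. Returns unmixing (comp x ch)
# and mixing (ch x comp) in the original channel space.
.fastica <- function(X, n_comp = NULL, seed = 1, maxit = 300, tol = 1e-7) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (is.null(n_comp)) n_comp <- rank
  n_comp <- min(n_comp, rank)
  d <- eg$values[seq_len(n_comp)]
  E <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  Wh <- diag(1 / sqrt(d), n_comp) %*% t(E)       # whitening (comp x ch)
  Z <- Wh %*% Xc
  W <- .rng_local(seed, matrix(stats::rnorm(n_comp^2), n_comp))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / ncol(Z) - diag(gprime, n_comp) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmix <- W %*% Wh                               # comp x ch
  mix <- MASS::ginv(unmix)                        # ch x comp
  list(unmixing = unmix, mixing = mix, n_comp = n_comp, rank = rank,
       iterations = it, converged = delta < tol)
}

#' Two-pass ICA on the training sessions of a fold
#'
#' Pass 1: probability-based segment rejection on the concatenated
#' 1-45 Hz training signal, then ICA. Pass 2: a second segment rejection
#' on the component activations' probability scores, band-pass of the
#' surviving segments to 8-40 Hz, and a final ICA whose unmixing matrix
#' is returned. Dimensionality is reduced by PCA to at most
#' `ica$max_components` (and to the numerical rank when lower), recorded
#' in the provenance.
#'
#' @param recordings List of `eeg_recording`s at the analysis rate
#'   (1-45 Hz filtered), the held-out test session excluded.
#' @param seed Integer seed.
#' @param config Configuration list (`ica`, `preprocess` entries).
#' @return A `spatial_model`: `unmixing`, `mixing`, `scalp_maps`,
#'   `n_comp`, `provenance`.
#' @export
fit_ica_two_pass <- function(recordings, seed = 1,
                             config = default_config()) {
  ic <- config$ica
  fs <- recordings[[1]]$fs
  X <- do.call(cbind, lapply(recordings, function(r) r$data))
  # pass 1: clean raw segments
  keep1 <- reject_segments(X, fs, ic$seg_len_s, ic$z)
  X1 <- .apply_segment_mask(X, keep1)
  X1s <- .stride_subsample(X1, ic$max_samples)
  maxit1 <- if (is.null(ic$maxit_pass1)) ic$maxit else ic$maxit_pass1
  ica1 <- .fastica(X1s, n_comp = ic$max_components, seed = seed,
                   maxit = maxit1, tol = ic$tol)
  # pass 2: reject segments by the probability of component activations
  A1 <- ica1$unmixing %*% X1
  keep2 <- reject_segments(A1, fs, ic$seg_len_s, ic$z)
  X2 <- .apply_segment_mask(X1, keep2)
  # the second ICA sees the feature band: filter evenly spaced
  # contiguous chunks totalling max_samples (only those feed the fit)
  spec <- design_fir(config$preprocess$feature_band, fs)
  X2s <- .chunk_subsample(X2, ic$max_samples, 8 * spec$n_taps)
  X2s <- if (ncol(X2s) > spec$n_taps + 1)
    .filtfilt_zero(X2s, spec$coefficients) else X2s
  ica2 <- .fastica(X2s, n_comp = ic$max_components, seed = seed + 1,
                   maxit = ic$maxit, tol = ic$tol)
  structure(list(unmixing = ica2$unmixing, mixing = ica2$mixing,
                 scalp_maps = ica2$mixing, n_comp = ica2$n_comp,
                 provenance = list(
                   sessions = vapply(recordings, function(r)
                     as.integer(r$session_id), 0L),
                   seed = seed, rank = ica2$rank,
                   segs_pass1 = sum(!keep1), segs_pass2 = sum(!keep2),
                   iterations = c(ica1$iterations, ica2$iterations))),
            class = "spatial_model")
}

# evenly strided column subsample used to bound the ICA fit cost
.stride_subsample <- function(X, max_samples) {
  if (ncol(X) <= max_samples) return(X)
  X[, round(seq(1, ncol(X), length.out = max_samples)), drop = FALSE]
}

# evenly spaced contiguous chunks totalling about max_samples; keeps
# enough context per chunk for subsequent zero-phase filtering
.chunk_subsample <- function(X, max_samples, chunk_len) {
  n <- ncol(X)
  if (n <= max_samples) return(X)
  k <- max(1L, floor(max_samples / chunk_len))
  starts <- round(seq(1, n - chunk_len + 1, length.out = k))
  idx <- unlist(lapply(starts, function(s) s:(s + chunk_len - 1)))
  X[, unique(idx), drop = FALSE]
}

#' Apply an unmixing matrix to an epoch set
#'
#' @param ep An `epoch_set` in channel space.
#' @param model A `spatial_model`.
#' @param components Optional component subset (default: all).
#' @return The epoch set in component space (labels preserved).
#' @export
apply_unmixing <- function(ep, model, components = NULL) {
  W <- model$unmixing
  if (!is.null(components)) W <- W[components, , drop = FALSE]
  d <- dim(ep$data)
  if (d[2] != ncol(W)) stop("channel count does not match the unmixing matrix")
  out <- array(0, c(d[1], nrow(W), d[3]))
  for (j in seq_len(d[1])) out[j, , ] <- W %*% ep$data[j, , ]
  ep$data <- out
  ep
}

#' Write a spatial model to a directory (matrices + JSON metadata)
#' @param model A `spatial_model`.
#' @param dir Output directory.
#' @export
write_spatial_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model$unmixing, file.path(dir, "unmixing.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(model$mixing, file.path(dir, "mixing.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(model$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
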