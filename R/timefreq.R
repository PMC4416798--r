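# Morlet wavelet time-frequency decomposition on a 20-frequency grid,
# event-related spectral perturbation with the pipeline's baselines, and
# the band-power ERD percentage.

#' Time-frequency configuration
#'
#' 20 log-spaced frequencies between 8 and 40 Hz; fixed 107-sample
#' analysis windows whose centres are evenly spaced from 54/fs after the
#' epoch start to 54/fs before its end (50 windows on an 8 s epoch,
#' spanning -3789 to +3789 ms around the onset; 14 windows on a 2 s
#' sliding epoch, -0.79 to +0.79 s around its centre); wavelet cycle
#' counts interpolated linearly from 3 at the lowest to 7.5 at the
#' highest bin.
#'
#' @param fs Sampling rate (Hz).
#' @param n_windows Number of analysis windows (50 batch / 14 sliding).
#' @param n_freqs,f_lo,f_hi Frequency grid (defaults 20 bins, 8-40 Hz).
#' @param window_len Window length in samples (default 107).
#' @param cycles Length-2: cycles at the lowest and highest frequency.
#' @param power_floor Linear-power floor applied before the dB transform.
#' @return A `tf_config` object with `freqs`, `cycles`, `window_len`,
#'   `n_windows`, `fs`, `power_floor` and the complex `bank`
#'   (window_len x n_freqs) of unit-energy Morlet wavelets.
#' @export
tf_config <- function(fs = 256, n_windows = 50, n_freqs = 20, f_lo = 8,
                      f_hi = 40, window_len = 107, cycles = c(3, 7.5),
                      power_floor = 1e-20) {
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_freqs))
  cyc <- seq(cycles[1], cycles[2], length.out = n_freqs)
  half <- (window_len - 1) / 2
  t <- (-half:half) / fs
  bank <- matrix(0i, window_len, n_freqs)
  for (k in seq_len(n_freqs)) {
    sigma <- cyc[k] / (2 * pi * freqs[k])
    w <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * freqs[k] * t)
    bank[, k] <- w / sqrt(sum(Mod(w)^2))
  }
  structure(list(freqs = freqs, cycles = cyc, window_len = window_len,
                 n_windows = n_windows, fs = fs,
                 power_floor = power_floor, bank = bank,
                 bank_re = Re(bank), bank_im = Im(bank)),
            class = "tf_config")
}

# 0-based window-centre sample offsets for an epoch of n samples
.tf_centers <- function(config, n) {
  margin <- 54
  if (n < config$window_len) stop("epoch shorter than the analysis window")
  round(seq(margin, n - margin, length.out = config$n_windows))
}

#' Window-centre times of an epoch's TF grid
#' @param config A [tf_config()].
#' @param n Epoch length in samples.
#' @param start_s Epoch start time relative to the onset (s).
#' @return Numeric vector of window-centre times (s).
#' @export
tf_times <- function(config, n, start_s) {
  start_s + .tf_centers(config, n) / config$fs
}

#' Morlet log-power matrix of one epoch of one component
#'
#' @param x Numeric vector (one component, one epoch).
#' @param config A [tf_config()].
#' @return n_freqs x n_windows matrix of dB power (10 log10 of squared
#'   wavelet magnitude, floored at `power_floor`).
#' @export
wavelet_tf <- function(x, config) {
  centers <- .tf_centers(config, length(x))
  half <- (config$window_len - 1) / 2
  seg <- vapply(centers, function(c0) {
    idx <- (c0 - half):(c0 + half) + 1
    idx <- pmin(pmax(idx, 1), length(x))
    x[idx]
  }, numeric(config$window_len))
  co <- crossprod(seg, Conj(config$bank))     # n_windows x n_freqs
  p <- pmax(Mod(co)^2, config$power_floor)
  t(10 * log10(p))
}

#' Time-frequency tensor of an epoch set
#'
#' Computes the Morlet log-power of every epoch and component. The inner
#' products are evaluated as one matrix product per window position.
#'
#' @param ep An `epoch_set` in component space.
#' @param config A [tf_config()] at the epoch sampling rate.
#' @return A `tf_tensor`: `power` array (epochs x components x freqs x
#'   windows, dB), `times` (window centres relative to onset for batch
#'   epochs, or to the epoch centre for sliding epochs), plus the epoch
#'   metadata (`label`, `subclass`, `session`, `trial`, `center`,
#'   `condition`) and the `config`.
#' @export
epochs_tf <- function(ep, config) {
  d <- dim(ep$data)
  n_ep <- d[1]; n_comp <- d[2]; n <- d[3]
  centers <- .tf_centers(config, n)
  half <- (config$window_len - 1) / 2
  nf <- length(config$freqs)
  pw <- array(0, c(n_ep, n_comp, nf, config$n_windows))
  flat <- matrix(ep$data, n_ep * n_comp, n)   # (epoch,comp) x samples
  for (w in seq_along(centers)) {
    idx <- (centers[w] - half):(centers[w] + half) + 1
    seg <- flat[, idx, drop = FALSE]
    # real and imaginary inner products as real matrix products
    p <- (seg %*% config$bank_re)^2 + (seg %*% config$bank_im)^2
    p <- pmax(p, config$power_floor)
    pw[, , , w] <- array(10 * log10(p), c(n_ep, n_comp, nf))
  }
  start_s <- if (!is.null(ep$window$change)) ep$window$change[1] else -ep$window$half
  structure(list(power = pw, freqs = config$freqs,
                 times = start_s + centers / config$fs,
                 label = ep$label, subclass = ep$subclass,
                 session = ep$session, trial = ep$trial,
                 center = ep$center, condition = ep$condition,
                 config = config),
            class = "tf_tensor")
}

#' Event-related spectral perturbation
#'
#' Mean over trials of the log power minus a baseline mean log spectrum
#' per component and frequency. `baseline = "constant"` uses the mean
#' log spectrum over the whole epoch length of the constant-speed class;
#' `baseline = "preonset"` uses a time range of the same trials
#' (`baseline_range`, seconds relative to onset; the early-epoch variant
#' uses -3.789 to -1.007 s).
#'
#' @param tf A `tf_tensor` of batch epochs.
#' @param class Class to average (`"change"` or `"constant"`).
#' @param baseline `"constant"` or `"preonset"`.
#' @param baseline_range Time range for `"preonset"` (s).
#' @return components x freqs x windows array of dB deviations.
#' @export
ersp <- function(tf, class = "change", baseline = c("constant", "preonset"),
                 baseline_range = c(-3.789, -1.007)) {
  baseline <- match.arg(baseline)
  sel <- tf$label == class
  if (!any(sel)) stop("no epochs of class ", class)
  m <- apply(tf$power[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  if (baseline == "constant") {
    base_sel <- tf$label == "constant"
    if (!any(base_sel)) stop("constant-speed baseline requires constant epochs")
    base <- apply(tf$power[base_sel, , , , drop = FALSE], c(2, 3), mean)
  } else {
    # change epochs run -4..4 s around the onset
    tsel <- tf$times >= baseline_range[1] & tf$times <= baseline_range[2]
    if (!any(tsel)) stop("baseline range outside the TF grid")
    base <- apply(tf$power[sel, , , tsel, drop = FALSE], c(2, 3), mean)
  }
  sweep(m, c(1, 2), base)
}

#' Band-power event-related desynchronization percentage
#'
#' `ERD(%) = (A - R) / R * 100`, where `A` is the mean linear power in
#' the region of interest and `R` the mean linear power in the reference
#' period (both averaged over the band's frequency bins after undoing
#' the dB transform).
#'
#' @param tf A `tf_tensor`.
#' @param class Class of trials to use.
#' @param band Frequency band (Hz), e.g. `c(8, 15)` for mu.
#' @param roi Time range of interest (s).
#' @param reference Reference time range (s); the convention is the
#'   first 1 s of the epoch.
#' @return List with `A`, `R`, `erd_percent`.
#' @export
erd_percent <- function(tf, class = "change", band = c(8, 15),
                        roi = c(0.5, 1.5), reference = NULL) {
  if (is.null(reference)) reference <- tf$times[1] + c(0, 1)
  fsel <- tf$freqs >= band[1] & tf$freqs <= band[2]
  rsel <- tf$times >= roi[1] & tf$times <= roi[2]
  bsel <- tf$times >= reference[1] & tf$times <= reference[2]
  if (!any(fsel) || !any(rsel) || !any(bsel))
    stop("band or time range outside the TF grid")
  sel <- tf$label == class
  lin <- 10^(tf$power[sel, , fsel, , drop = FALSE] / 10)
  A <- mean(lin[, , , rsel, drop = FALSE])
  R <- mean(lin[, , , bsel, drop = FALSE])
  if (R == 0) stop("reference power is zero")
  list(A = A, R = R, erd_percent = (A - R) / R * 100)
}
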