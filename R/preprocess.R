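# FIR band-pass design with automatic order selection, zero-phase
# application and polyphase-free integer-factor resampling.

#' Design a Hamming-window FIR band-pass with automatic order
#'
#' The transition bandwidth of each passband edge is
#' `min(max(0.25 * edge, 2 Hz), distance of the edge to the nearer of 0
#' or Nyquist)`; the overall transition bandwidth is the minimum over the
#' two edges. The estimated order is `ceil(3.3 * fs / tb)` rounded up to
#' the next even integer, and the filter length is order + 1 taps. The
#' -6 dB cutoffs sit half a transition bandwidth outside the passband
#' edges, where the windowed-sinc design places its half-amplitude
#' points. For a 1-45 Hz passband at 2048 Hz this yields 6761 taps with
#' cutoffs 0.5 and 45.5 Hz; for 8-40 Hz at 256 Hz, 425 taps with cutoffs
#' 7 and 41 Hz.
#'
#' @param passband Length-2 numeric, passband edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec`: `passband_edges`, `transition_bandwidth`,
#'   `n_taps`, `cutoff_minus6dB`, `coefficients`, `design_fs`.
#' @export
design_fir <- function(passband, fs) {
  lo <- passband[1]; hi <- passband[2]
  nyq <- fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("passband must satisfy 0 < low < high < fs/2")
  tb_edge <- function(edge) min(max(0.25 * edge, 2), min(edge, nyq - edge))
  tb <- min(tb_edge(lo), tb_edge(hi))
  m <- ceiling(3.3 * fs / tb)
  if (m %% 2 == 1) m <- m + 1
  n_taps <- m + 1
  cutoffs <- c(lo - tb / 2, hi + tb / 2)
  # windowed-sinc band-pass with -6 dB points at the cutoffs
  k <- seq_len(n_taps) - 1 - m / 2
  sinc <- function(fc) {
    h <- 2 * fc / fs * rep(1, n_taps)
    nz <- k != 0
    h[nz] <- sin(2 * pi * fc / fs * k[nz]) / (pi * k[nz])
    h
  }
  h <- (sinc(cutoffs[2]) - sinc(cutoffs[1])) *
    (0.54 - 0.46 * cos(2 * pi * (0:m) / m))
  structure(list(passband_edges = c(lo, hi), transition_bandwidth = tb,
                 n_taps = n_taps, cutoff_minus6dB = cutoffs,
                 coefficients = h, design_fs = fs),
            class = "filter_spec")
}

#' Frequency response of a filter design
#' @param spec A [design_fir()] result.
#' @param freqs Frequencies in Hz.
#' @return Complex response at `freqs`.
#' @export
filter_response <- function(spec, freqs) {
  k <- seq_along(spec$coefficients) - 1
  vapply(freqs, function(f) {
    sum(spec$coefficients * exp(-2i * pi * f / spec$design_fs * k))
  }, complex(1))
}

# zero-phase filter a channels x samples matrix: single-pass FFT
# convolution with the linear-phase group delay removed, reflection
# padding at both edges; channels are processed in chunks through mvfft
.filtfilt_zero <- function(X, h) {
  nt <- length(h)
  D <- (nt - 1) / 2
  n <- ncol(X)
  if (n <= nt) stop("signal shorter than the filter")
  pad <- min(D, n - 1)
  ne <- n + 2 * pad
  L <- stats::nextn(ne + nt - 1, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(L - nt)))
  out <- matrix(0, nrow(X), n)
  chunk <- max(1L, min(nrow(X), floor(2^23 / L)))
  rows <- (pad + D + 1):(pad + D + n)
  for (c0 in seq(1, nrow(X), by = chunk)) {
    chs <- c0:min(c0 + chunk - 1, nrow(X))
    B <- matrix(0, L, length(chs))
    for (j in seq_along(chs)) {
      x <- X[chs[j], ]
      B[seq_len(ne), j] <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    }
    Y <- stats::mvfft(stats::mvfft(B) * H, inverse = TRUE)
    for (j in seq_along(chs)) out[chs[j], ] <- Re(Y[rows, j]) / L
  }
  out
}

# fused band-pass + integer decimation: identical (to numerical
# accuracy) to .filtfilt_zero followed by taking every q-th sample,
# implemented by truncating the filtered spectrum to the decimated band
# before the inverse transform. Valid because the band-pass leaves no
# energy above the decimated Nyquist.
.bandpass_decimate <- function(X, h, q) {
  nt <- length(h)
  D <- (nt - 1) / 2
  n <- ncol(X)
  if (n <= nt) stop("signal shorter than the filter")
  if (n %% q != 0) stop("signal length must be a multiple of q")
  pad <- min(D, n - 1)
  # align so the first retained output sample is a multiple of q
  pad <- pad + (q - (pad + D) %% q) %% q
  if (pad > n - 1) stop("signal too short for aligned decimation")
  ne <- n + 2 * pad
  L <- stats::nextn(ne + nt - 1, c(2, 3, 5))
  while (L %% (2 * q) != 0) L <- stats::nextn(L + 1, c(2, 3, 5))
  m <- L / q
  half <- m / 2
  H <- stats::fft(c(h, numeric(L - nt)))
  n_out <- n / q
  j0 <- (pad + D) / q                     # 0-based first decimated sample
  out <- matrix(0, nrow(X), n_out)
  chunk <- max(1L, min(nrow(X), floor(2^23 / L)))
  for (c0 in seq(1, nrow(X), by = chunk)) {
    chs <- c0:min(c0 + chunk - 1, nrow(X))
    B <- matrix(0, L, length(chs))
    for (j in seq_along(chs)) {
      x <- X[chs[j], ]
      B[seq_len(ne), j] <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    }
    Y <- stats::mvfft(B) * H
    Z <- rbind(Y[1:half, , drop = FALSE],
               Y[(L - m + half + 1):L, , drop = FALSE])
    Yd <- stats::mvfft(Z, inverse = TRUE)
    for (j in seq_along(chs))
      out[chs[j], ] <- Re(Yd[(j0 + 1):(j0 + n_out), j]) / L
  }
  out
}

#' Apply a zero-phase FIR filter to a recording
#'
#' Single-pass convolution with the group delay of the linear-phase
#' kernel compensated; the edges are padded by reflection so output
#' length equals input length.
#'
#' @param rec An `eeg_recording` (or plain matrix with attribute-free
#'   channels x samples layout when `fs` is given).
#' @param spec A [design_fir()] result designed at the recording rate.
#' @return Filtered recording.
#' @export
apply_zero_phase <- function(rec, spec) {
  if (is.matrix(rec)) {
    return(.filtfilt_zero(rec, spec$coefficients))
  }
  if (abs(rec$fs - spec$design_fs) > 1e-9)
    stop("filter was designed at a different sampling rate")
  rec$data <- .filtfilt_zero(rec$data, spec$coefficients)
  rec
}

#' Resample a recording to a lower rate
#'
#' Integer-factor decimation with a zero-phase anti-aliasing low-pass
#' (windowed sinc at 80% of the target Nyquist). Event sample indices
#' are rescaled, rounding half away from zero.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate in Hz (must divide `rec$fs`).
#' @param anti_alias Apply the anti-aliasing low-pass (default TRUE).
#'   Can be disabled when the signal is already band-limited well below
#'   the target Nyquist, e.g. after the 1-45 Hz band-pass.
#' @return Resampled recording.
#' @export
resample_recording <- function(rec, target_fs = 256, anti_alias = TRUE) {
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the recording rate")
  q <- round(q)
  if (anti_alias) {
    # anti-aliasing low-pass: half-amplitude point at 80% target Nyquist
    fc <- 0.8 * target_fs / 2
    tb <- 0.4 * target_fs / 2
    m <- ceiling(3.3 * rec$fs / tb)
    if (m %% 2 == 1) m <- m + 1
    k <- (0:m) - m / 2
    h <- 2 * fc / rec$fs * rep(1, m + 1)
    nz <- k != 0
    h[nz] <- sin(2 * pi * fc / rec$fs * k[nz]) / (pi * k[nz])
    h <- h * (0.54 - 0.46 * cos(2 * pi * (0:m) / m))
    rec$data <- .filtfilt_zero(rec$data, h)
  }
  idx <- seq(1, ncol(rec$data), by = q)
  rec$data <- rec$data[, idx, drop = FALSE]
  rec$fs <- target_fs
  if (nrow(rec$events) > 0) {
    s <- rec$events$onset_sample / q
    rec$events$onset_sample <- as.integer(sign(s) * floor(abs(s) + 0.5))
  }
  rec
}
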