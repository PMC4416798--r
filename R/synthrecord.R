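# Synthetic EEG generation: dipolar sources with mu/beta event-related
# desynchronization, 1/f background, blink, EMG-burst and step-locked
# artifact sources, forward-projected through the 4-shell model.

#' Source specification for the synthetic generator
#'
#' @param kind One of `"cortical"`, `"background"`, `"blink"`, `"emg"`,
#'   `"step"`.
#' @param loc Dipole location (mm, head frame). Cortical sources must lie
#'   inside the brain shell.
#' @param amp Source amplitude (nA m, applied to a unit-variance carrier).
#' @param band Carrier band in Hz (cortical/background/emg).
#' @param erd_db Event-related power drop in dB inside `erd_window`
#'   (cortical sources; >= 0).
#' @param erd_window Seconds relative to each speed-change onset.
#' @param moment_dir Moment direction (defaults to radial).
#' @param params Extra kind-specific parameters.
#' @return A `source_spec` object.
#' @export
source_spec <- function(kind, loc, amp, band = NULL, erd_db = 0,
                        erd_window = c(0, 2), moment_dir = NULL,
                        params = list()) {
  if (erd_db < 0) stop("erd_db must be non-negative")
  if (is.null(moment_dir)) moment_dir <- loc / sqrt(sum(loc^2))
  structure(list(kind = kind, loc = as.numeric(loc), amp = amp,
                 band = band, erd_db = erd_db, erd_window = erd_window,
                 moment_dir = moment_dir / sqrt(sum(moment_dir^2)),
                 params = params),
            class = "source_spec")
}

#' Build the default source set of a subject
#'
#' Cortical mu and beta sources in the posterior parietal cortex with the
#' configured event-related desynchronization, an optional weaker motor
#' source, 1/f background sources, blink, two EMG-burst sources at the
#' neck and a step-locked artifact source.
#'
#' @param config Configuration list.
#' @param subject Subject index (controls the motor-source subset and the
#'   background source layout).
#' @return List of [source_spec()] objects.
#' @export
build_sources <- function(config, subject = 1) {
  sc <- config$sources
  src <- list(
    with(sc$parietal_mu,
         source_spec("cortical", loc, amp, band, erd_db, erd_window)),
    with(sc$parietal_beta,
         source_spec("cortical", loc, amp, band, erd_db, erd_window))
  )
  if (subject %in% config$cohort$motor_subjects) {
    src <- c(src, list(with(sc$motor_mu,
                            source_spec("cortical", loc, amp, band, erd_db,
                                        erd_window))))
  }
  # fixed per-subject background layout
  bg_locs <- .rng_local(1000L + subject, {
    lapply(seq_len(sc$n_background), function(i) {
      z <- stats::rnorm(3)
      z / sqrt(sum(z^2)) * stats::runif(1, 25, 55)
    })
  })
  for (loc in bg_locs) {
    src <- c(src, list(source_spec("background", loc, sc$background_amp,
                                   band = c(1, 45),
                                   params = list(alpha = 1))))
  }
  src <- c(src,
           list(source_spec("blink", sc$blink$loc, sc$blink$amp,
                            moment_dir = c(0.3, 0, 1),
                            params = sc$blink[c("rate_hz", "width_s")])),
           lapply(sc$emg$locs, function(l)
             source_spec("emg", l, sc$emg$amp, band = sc$emg$band,
                         params = sc$emg[c("burst_rate_hz", "burst_s",
                                           "tonic_frac")])),
           list(source_spec("step", sc$step$loc, sc$step$amp,
                            params = sc$step[c("n_harmonics", "rate_1kmh",
                                               "rate_2kmh")])))
  src
}

# band-limited noise via FFT shaping; unit variance; assumes RNG is set
.band_noise <- function(n, fs, lo, hi, alpha = 0, edge = min(1, lo / 2)) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  H <- rep(0, n)
  H[f >= lo & f <= hi] <- 1
  # raised-cosine transition edges
  lo_t <- f >= lo - edge & f < lo
  hi_t <- f > hi & f <= hi + edge
  H[lo_t] <- 0.5 * (1 + cos(pi * (lo - f[lo_t]) / edge))
  H[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - hi) / edge))
  if (alpha > 0) H <- H * pmax(f, 0.5)^(-alpha / 2)
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

# multiplicative amplitude envelope implementing the ERD: drops to
# 10^(-erd_db/20) inside [onset + w1, onset + w2], raised-cosine edges
.erd_envelope <- function(t, onsets, erd_db, window, edge = 0.25) {
  env <- rep(1, length(t))
  if (erd_db <= 0 || length(onsets) == 0) return(env)
  g <- 10^(-erd_db / 20)
  for (o in onsets) {
    a <- o + window[1]; b <- o + window[2]
    core <- t >= a + edge & t <= b - edge
    env[core] <- g
    up <- t >= a & t < a + edge
    env[up] <- 1 + (g - 1) * 0.5 * (1 - cos(pi * (t[up] - a) / edge))
    dn <- t > b - edge & t <= b
    env[dn] <- g + (1 - g) * 0.5 * (1 - cos(pi * (t[dn] - (b - edge)) / edge))
  }
  env
}

# smooth 0/1 gate of walking periods (belt speed > eps); moving average
# via cumulative sums
.walk_gate <- function(v, fs, eps = 0.01) {
  g <- as.numeric(v > eps)
  k <- max(3L, round(0.25 * fs))
  n <- length(g)
  cs <- cumsum(c(rep(g[1], k), g, rep(g[n], k)))
  (cs[(k + 1):(k + n) + k] - cs[seq_len(n)]) / (2 * k)
}

# per-source waveform (unit scale before amp); RNG must be set by caller
.source_waveform <- function(spec, t, fs, onsets, belt) {
  n <- length(t)
  switch(spec$kind,
    cortical = {
      # bursty rhythm: band-limited carrier under a slow lognormal
      # amplitude envelope (waxing/waning, as real mu/beta); the
      # burstiness is also what makes the source separable by ICA
      carrier <- .band_noise(n, fs, spec$band[1], spec$band[2])
      env <- exp(0.6 * .band_noise(n, fs, 0.3, 2))
      w <- carrier * env
      w <- w / stats::sd(w)
      w * .erd_envelope(t, onsets, spec$erd_db, spec$erd_window)
    },
    background = {
      alpha <- if (is.null(spec$params$alpha)) 1 else spec$params$alpha
      w <- .band_noise(n, fs, spec$band[1], spec$band[2], alpha = alpha) *
        exp(0.7 * .band_noise(n, fs, 0.2, 1.5))
      w / stats::sd(w)
    },
    blink = {
      rate <- spec$params$rate_hz; width <- spec$params$width_s
      w <- numeric(n)
      n_blinks <- stats::rpois(1, rate * (t[n] - t[1]))
      if (n_blinks > 0) {
        times <- sort(stats::runif(n_blinks, t[1], t[n] - width))
        amps <- stats::rnorm(n_blinks, 1, 0.15)
        hw <- round(width * fs)
        pulse <- 0.5 * (1 - cos(2 * pi * seq_len(hw) / (hw + 1)))
        for (j in seq_len(n_blinks)) {
          i0 <- round((times[j] - t[1]) * fs) + 1L
          idx <- i0:(i0 + hw - 1L)
          ok <- idx >= 1 & idx <= n
          w[idx[ok]] <- w[idx[ok]] + amps[j] * pulse[ok]
        }
      }
      w
    },
    emg = {
      carrier <- .band_noise(n, fs, spec$band[1],
                             min(spec$band[2], 0.45 * fs))
      env <- rep(spec$params$tonic_frac, n)
      dur <- t[n] - t[1]
      n_bursts <- stats::rpois(1, spec$params$burst_rate_hz * dur)
      if (n_bursts > 0) {
        times <- stats::runif(n_bursts, t[1], t[n] - spec$params$burst_s)
        hw <- round(spec$params$burst_s * fs)
        pulse <- 0.5 * (1 - cos(2 * pi * seq_len(hw) / (hw + 1)))
        for (j in seq_len(n_bursts)) {
          i0 <- round((times[j] - t[1]) * fs) + 1L
          idx <- i0:(i0 + hw - 1L)
          ok <- idx >= 1 & idx <= n
          env[idx[ok]] <- env[idx[ok]] + pulse[ok]
        }
      }
      carrier * env * .walk_gate(belt, fs)
    },
    step = {
      v_kmh <- belt * 3.6
      rate <- ifelse(v_kmh > 0.05, 0.55 + 0.2 * pmax(v_kmh, 0.5), 0)
      phase <- 2 * pi * cumsum(rate) / fs
      w <- numeric(n)
      nh <- spec$params$n_harmonics
      phis <- stats::runif(nh, 0, 2 * pi)
      for (h in seq_len(nh)) w <- w + sin(h * phase + phis[h]) / h
      w * .walk_gate(belt, fs)
    },
    stop("unknown source kind: ", spec$kind))
}

#' Simulate a multichannel EEG recording of one session
#'
#' Sums the forward-projected waveforms of all sources and adds white
#' sensor noise. Cortical sources carry band-limited oscillations whose
#' power drops by the configured ERD depth after every speed-change
#' onset; EMG and step-locked sources are gated by treadmill activity.
#'
#' @param plan A [make_session_plan()] result.
#' @param sources List of [source_spec()] objects (see
#'   [build_sources()]).
#' @param montage A [montage()].
#' @param model A [head_model()].
#' @param fs Sampling rate in Hz (default 2048).
#' @param seed Integer seed for all waveform randomness.
#' @param noise_sd Sensor-noise SD in microvolts.
#' @param config Configuration list (encoder settings for the profile).
#' @param session_id Session identifier attached to the recording.
#' @return An `eeg_recording` with events and speed profile attached.
#' @export
simulate_recording <- function(plan, sources, montage, model, fs = 2048,
                               seed = 1, noise_sd = 1,
                               config = default_config(),
                               session_id = NA_integer_) {
  if (montage$radius > model$shell_radii[4] * (1 + 1e-9) ||
      montage$radius < model$shell_radii[4] * (1 - 1e-9))
    stop("montage scalp radius does not match the head model")
  profile <- render_speed_profile(plan, config)
  events <- detect_onsets_encoder(profile, config$encoder$threshold_ms)
  n <- round(plan$total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  belt <- .belt_speed_at(profile, t)
  n_ch <- length(montage$labels)
  gains <- matrix(0, n_ch, length(sources))
  S <- matrix(0, length(sources), n)
  # each source draws from its own derived seed, so a source generates
  # the same waveform regardless of which other sources are present
  for (j in seq_along(sources)) {
    spec <- sources[[j]]
    if (spec$amp == 0) next
    if (spec$kind == "cortical" &&
        sqrt(sum(spec$loc^2)) >= model$shell_radii[1])
      stop("cortical source must lie inside the brain shell")
    G <- .forward_gain(spec$loc, montage, model, strict = FALSE)
    g <- as.numeric(G %*% spec$moment_dir)
    gains[, j] <- (g - mean(g)) * spec$amp
    S[j, ] <- .rng_local(.derive_seed(seed, j, 7),
                         .source_waveform(spec, t, fs, events$onset_s, belt))
  }
  X <- gains %*% S
  rm(S)
  if (noise_sd > 0)
    X <- X + .rng_local(.derive_seed(seed, 0, 8),
                        stats::rnorm(length(X), 0, noise_sd))
  recording(X, fs, montage$labels, events, plan$condition, session_id,
            profile)
}

#' Simulate a full subject (10 sessions, 7 cued / 3 uncued)
#'
#' Sessions are generated in the interleaved order
#' cued-cued-uncued repeated with two or three cued sessions between
#' uncued ones. Deterministic given `seed`.
#'
#' @param config Configuration list.
#' @param seed Integer subject seed.
#' @param subject Subject index.
#' @return List of 10 `eeg_recording` objects.
#' @export
simulate_subject <- function(config, seed = 1, subject = 1) {
  conditions <- session_conditions()
  lapply(seq_along(conditions), function(i)
    simulate_session(config, conditions[i], seed, subject, i))
}

#' Session condition sequence of a subject
#' @return Character vector of 10 conditions (7 cued, 3 uncued,
#'   uncued sessions after two or three cued ones).
#' @export
session_conditions <- function() {
  c("cued", "cued", "uncued", "cued", "cued", "cued", "uncued",
    "cued", "cued", "uncued")
}

#' Simulate a single session of a subject
#'
#' @param config Configuration list.
#' @param condition `"cued"` or `"uncued"`.
#' @param seed Subject seed.
#' @param subject Subject index.
#' @param session_id Session number (1-10); determines the session's
#'   private seed.
#' @return An `eeg_recording`.
#' @export
simulate_session <- function(config, condition, seed = 1, subject = 1,
                             session_id = 1) {
  sess_seed <- .derive_seed(seed, subject, session_id)
  plan <- make_session_plan(condition, seed = sess_seed, config = config)
  sources <- build_sources(config, subject)
  simulate_recording(plan, sources, .cfg_montage(config),
                     .cfg_model(config), fs = config$fs, seed = sess_seed,
                     noise_sd = config$noise_sd, config = config,
                     session_id = session_id)
}

# deterministic 31-bit sub-seed
.derive_seed <- function(seed, a, b) {
  s <- (as.double(seed) * 2654435761 + a * 40503 + b * 9973) %% 2147483647
  as.integer(s)
}
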