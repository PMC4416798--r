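#' Session plan: block speeds and durations
#'
#' A cued session is the deterministic design: 19 blocks of 20 s whose
#' speeds follow 0-1-2-1-2-1 repeated three times, followed by a rest
#' block, 380 s in total. An uncued session keeps the same speed order
#' but draws each block's steady-walk duration from the statistics of
#' self-paced walking (Gaussian, mean 17.4 s / SD 5.35 after an
#' acceleration, mean 12.8 s / SD 6.51 after a deceleration, floored at
#' `steady_floor_s`), adds the ramp time, and truncates the session at
#' 380 s.
#'
#' @param condition `"cued"` or `"uncued"`.
#' @param seed Integer seed (used for uncued block durations).
#' @param config Configuration list (see [default_config()]); only the
#'   `session` entry is used.
#' @return A `session_plan`: list with `condition`, `block_speeds`
#'   (km/h), `block_durations` (s, including the entry ramp),
#'   `accel_ramp`, `decel_ramp`, `total_duration`.
#' @export
make_session_plan <- function(condition = c("cued", "uncued"), seed = 1,
                              config = default_config()) {
  condition <- match.arg(condition)
  sc <- config$session
  speeds <- c(rep(sc$speeds_kmh, sc$reps), 0)   # final rest block
  n_blocks <- length(speeds)
  if (condition == "cued") {
    durations <- rep(sc$block_s, n_blocks)
  } else {
    durations <- .rng_local(seed, {
      d <- numeric(n_blocks)
      d[1] <- sc$block_s                         # initial standing block
      for (k in 2:n_blocks) {
        accel <- speeds[k] > speeds[k - 1]
        ramp <- if (accel) sc$accel_s else sc$decel_s
        stat <- if (accel) sc$uncued_steady_accel else sc$uncued_steady_decel
        steady <- max(stats::rnorm(1, stat[["mean"]], stat[["sd"]]),
                      sc$steady_floor_s)
        d[k] <- ramp + steady
      }
      d
    })
    # truncate at the nominal session length
    cum <- cumsum(durations)
    keep <- which(cum < sc$total_s)
    n_keep <- max(keep) + 1L
    n_keep <- min(n_keep, n_blocks)
    durations <- durations[seq_len(n_keep)]
    speeds <- speeds[seq_len(n_keep)]
    durations[n_keep] <- sc$total_s - sum(durations[-n_keep])
  }
  structure(list(condition = condition,
                 block_speeds = speeds,
                 block_durations = durations,
                 accel_ramp = sc$accel_s,
                 decel_ramp = sc$decel_s,
                 total_duration = sum(durations)),
            class = "session_plan")
}

#' Render the treadmill speed profile of a session plan
#'
#' Produces the belt-speed trace and the subject-minus-belt relative
#' speed trace that the linear encoder monitors. At each planned block
#' boundary the subject initiates the speed change: the relative speed
#' ramps linearly at `rel_slope` m/s^2 until the encoder threshold would
#' be crossed and the belt then adapts with the 4 s (acceleration) or
#' 8 s (deceleration) ramp, after which the relative speed returns to
#' zero.
#'
#' @param plan A [make_session_plan()] result.
#' @param config Configuration list (`encoder` and `session` entries).
#' @param seed Optional seed for encoder measurement noise
#'   (`encoder$rel_noise_sd`); the default configuration is noiseless.
#' @return A `speed_profile`: list with `t` (s), `belt` (m/s), `rel`
#'   (m/s), `fs`, `transitions` (data.frame: initiation time, ramp start,
#'   from/to km/h, ramp duration), `plan`.
#' @export
render_speed_profile <- function(plan, config = default_config(),
                                 seed = NULL) {
  enc <- config$encoder
  fs <- enc$profile_fs
  kmh <- 1 / 3.6
  total <- plan$total_duration
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  bounds <- cumsum(plan$block_durations)
  starts <- c(0, bounds[-length(bounds)])
  belt <- numeric(length(t))
  rel <- numeric(length(t))
  trans <- NULL
  cur <- plan$block_speeds[1] * kmh
  belt[] <- cur
  for (k in 2:length(plan$block_speeds)) {
    from <- plan$block_speeds[k - 1]
    to <- plan$block_speeds[k]
    if (to == from) next
    accel <- to > from
    ramp <- if (accel) plan$accel_ramp else plan$decel_ramp
    t_init <- starts[k]
    # relative-speed excursion: linear rise to the encoder threshold
    cross <- enc$threshold_ms / enc$rel_slope
    t_onset <- t_init + cross
    sgn <- if (accel) 1 else -1
    # rel speed: rises until the belt ramp has begun, then decays
    rise <- t >= t_init & t < t_onset + 0.5
    decay <- t >= t_onset + 0.5 & t < t_onset + 1.5
    peak <- enc$rel_slope * (cross + 0.5)
    rel[rise] <- rel[rise] + sgn * enc$rel_slope * (t[rise] - t_init)
    rel[decay] <- rel[decay] + sgn * peak * (1 - (t[decay] - t_onset - 0.5))
    in_ramp <- t >= t_onset & t < t_onset + ramp
    belt[in_ramp] <- belt[in_ramp] +
      (to - from) * kmh * (t[in_ramp] - t_onset) / ramp
    belt[t >= t_onset + ramp] <- to * kmh
    trans <- rbind(trans, data.frame(t_init = t_init, t_onset = t_onset,
                                     from_kmh = from, to_kmh = to,
                                     ramp_s = ramp))
  }
  if (!is.null(seed) && enc$rel_noise_sd > 0) {
    rel <- rel + .rng_local(seed, stats::rnorm(length(rel), 0,
                                               enc$rel_noise_sd))
  }
  structure(list(t = t, belt = belt, rel = rel, fs = fs,
                 transitions = trans, plan = plan),
            class = "speed_profile")
}

#' Detect speed-change onsets from the encoder trace
#'
#' Emits one event per speed transition at the first crossing of the
#' +/- threshold by the subject-minus-belt relative speed. The detector
#' re-arms once the relative speed has returned below half the
#' threshold.
#'
#' @param profile A [render_speed_profile()] result.
#' @param threshold Detection threshold in m/s (default 0.12).
#' @return data.frame with `onset_s`, `from_kmh`, `to_kmh`.
#' @export
detect_onsets_encoder <- function(profile, threshold = 0.12) {
  rel <- profile$rel
  armed <- TRUE
  onsets <- numeric(0)
  for (i in seq_along(rel)) {
    a <- abs(rel[i])
    if (armed && a >= threshold) {
      onsets <- c(onsets, profile$t[i])
      armed <- FALSE
    } else if (!armed && a < threshold / 2) {
      armed <- TRUE
    }
  }
  if (length(onsets) == 0)
    return(data.frame(onset_s = numeric(0), from_kmh = numeric(0),
                      to_kmh = numeric(0)))
  # label each onset with the transition it belongs to
  tr <- profile$transitions
  idx <- vapply(onsets, function(o) {
    which.min(abs(tr$t_onset - o))
  }, integer(1))
  data.frame(onset_s = onsets, from_kmh = tr$from_kmh[idx],
             to_kmh = tr$to_kmh[idx])
}

# belt speed (m/s) of a plan evaluated at arbitrary times, using the
# transition table of a rendered profile
.belt_speed_at <- function(profile, t) {
  kmh <- 1 / 3.6
  v <- rep(profile$plan$block_speeds[1] * kmh, length(t))
  tr <- profile$transitions
  if (is.null(tr)) return(v)
  for (k in seq_len(nrow(tr))) {
    t0 <- tr$t_onset[k]; ramp <- tr$ramp_s[k]
    from <- tr$from_kmh[k] * kmh; to <- tr$to_kmh[k] * kmh
    in_ramp <- t >= t0 & t < t0 + ramp
    v[in_ramp] <- from + (to - from) * (t[in_ramp] - t0) / ramp
    v[t >= t0 + ramp] <- to
  }
  v
}
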