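#' Default pipeline configuration
#'
#' All tunable constants of the generator and the analysis pipeline in one
#' nested list: band edges and sampling rates, segment-rejection settings,
#' dipole-rejection thresholds, time-frequency grid, epoch-rejection
#' bounds, PCA variance fraction, clustering parameters and the synthetic
#' cohort description. The analysis constants carry the study defaults
#' (1-45 Hz band, 256 Hz analysis rate, 0.5 s segments at 5 SD, 8-40 Hz
#' feature band, 10% residual variance, 70% radial distance, z >= 0 mm,
#' +25/-100 dB epoch bounds, 90% PCA variance, k = 4 clusters at 5 SD,
#' 40% fold-membership rule, 58% cortex sphere, 0.12 m/s onset threshold).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    fs = 2048,
    fs_analysis = 256,
    head = list(shell_radii = c(71, 72, 79, 85),
                shell_conductivities = c(0.33, 1.0, 0.0042, 0.33),
                series_terms = 60),
    session = list(n_sessions = 10, n_cued = 7,
                   block_s = 20, speeds_kmh = c(0, 1, 2, 1, 2, 1), reps = 3,
                   total_s = 380, accel_s = 4, decel_s = 8,
                   uncued_steady_accel = c(mean = 17.4, sd = 5.35),
                   uncued_steady_decel = c(mean = 12.8, sd = 6.51),
                   steady_floor_s = 6),
    encoder = list(threshold_ms = 0.12, rel_slope = 0.24, profile_fs = 64,
                   rel_noise_sd = 0),
    sources = list(
      parietal_mu = list(loc = c(-12, -40, 40), band = c(8, 15),
                         amp = 30, erd_db = 3, erd_window = c(0, 2)),
      parietal_beta = list(loc = c(-12, -40, 40), band = c(16, 31),
                           amp = 15, erd_db = 1.5, erd_window = c(0, 2)),
      motor_mu = list(loc = c(15, -35, 38), band = c(8, 15),
                      amp = 15, erd_db = 1, erd_window = c(0, 2)),
      n_background = 6, background_amp = 35,
      blink = list(loc = c(72, 0, -25), amp = 150, rate_hz = 0.20,
                   width_s = 0.35),
      emg = list(locs = list(c(-60, 27, -49), c(-60, -27, -49)),
                 amp = 30, band = c(20, 100), burst_rate_hz = 0.4,
                 burst_s = 0.5, tonic_frac = 0.15),
      step = list(loc = c(-50, 0, -40), amp = 30, n_harmonics = 5,
                  rate_1kmh = 0.75, rate_2kmh = 0.95)
    ),
    noise_sd = 0.4,
    preprocess = list(band = c(1, 45), feature_band = c(8, 40)),
    ica = list(seg_len_s = 0.5, z = 5, max_components = 20,
               max_samples = 18000, maxit_pass1 = 40, maxit = 100,
               tol = 1e-5),
    dipole = list(n_restarts = 3, rv_max = 0.10, radial_max = 0.70,
                  z_min = 0),
    eye = list(frontal_factor = 2, lowfreq_frac = 0.55, kurtosis_min = 8),
    epochs = list(change_window = c(-4, 4), constant_window = c(-12, -4),
                  min_preceding_s = 12),
    sliding = list(train_change_centers = seq(0, 1.5, 0.5),
                   train_constant_centers = seq(-10, -7, 1),
                   test_change_centers = seq(-1, 3, 0.5),
                   test_constant_centers = seq(-9, -5, 0.5),
                   window_s = 2),
    tf = list(n_freqs = 20, f_lo = 8, f_hi = 40, window_len = 107,
              n_windows_batch = 50, n_windows_sliding = 14,
              cycles = c(3, 7.5), power_floor = 1e-20),
    reject_epoch = list(band = c(20, 40), hi_db = 25, lo_db = -100),
    pca_var = 0.90,
    slr = list(nfolds = 5),
    cluster = list(k = 4, outlier_sd = 5, min_fold_frac = 0.40,
                   min_subjects = 2, cortex_fraction = 0.58),
    cohort = list(n_subjects = 2, motor_subjects = c(1, 2))
  )
}

#' Write a configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops names on simple numeric pairs; restore the ones we rely on
  for (nm in c("uncued_steady_accel", "uncued_steady_decel")) {
    v <- unlist(cfg$session[[nm]])
    cfg$session[[nm]] <- c(mean = unname(v[1]), sd = unname(v[2]))
  }
  cfg
}

# montage / head model instances for a config
.cfg_montage <- function(config) montage_biosemi64(config$head$shell_radii[4])
.cfg_model <- function(config)
  head_model(config$head$shell_radii, config$head$shell_conductivities,
             config$head$series_terms)
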