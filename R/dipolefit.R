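#' Fit a single equivalent current dipole to a scalp map
#'
#' Multi-start nonlinear search over dipole location; at every candidate
#' location the moment is solved linearly by least squares against the
#' average-referenced scalp map. The residual variance is the fraction of
#' map variance left unexplained by the fitted dipole. Following
#' BESA-style fitters, the search is allowed to leave the brain shell
#' (the series is evaluated as a formal extension up to just below the
#' scalp radius), which is what makes the "distance > 70% of the sphere
#' radius" rejection heuristic and the far-field QC pool meaningful.
#'
#' @param scalp_map Numeric vector (one value per montage channel).
#' @param montage A [montage()].
#' @param model A [head_model()].
#' @param n_restarts Number of seeded restarts (default 8), started from
#'   points on the 60%-radius sphere.
#' @param seed Integer seed for the restart directions.
#' @return A `dipole_fit` object: `dipole`, `residual_variance`,
#'   `radial_fraction`, `converged`.
#' @export
fit_single_dipole <- function(scalp_map, montage, model, n_restarts = 8,
                              seed = 1) {
  scalp_map <- as.numeric(scalp_map)
  if (length(scalp_map) != nrow(montage$positions))
    stop("scalp map length must match the montage")
  map <- scalp_map - mean(scalp_map)
  ss_map <- sum(map^2)
  if (ss_map == 0) stop("scalp map must not be constant")
  R <- model$shell_radii[4]

  rv_at <- function(loc) {
    b2 <- sum(loc^2)
    if (b2 >= (0.985 * R)^2) return(1 + sqrt(b2) / R)  # soft barrier
    G <- .forward_gain(loc, montage, model, strict = FALSE)
    G <- G - rep(colMeans(G), each = nrow(G))   # average reference
    gtg <- crossprod(G)
    m <- tryCatch(solve(gtg, crossprod(G, map)),
                  error = function(e) NULL)
    if (is.null(m)) return(1)
    sum((map - as.numeric(G %*% m))^2) / ss_map
  }

  # seeded restart points on the 60%-radius sphere
  rs <- .rng_local(seed, {
    z <- matrix(stats::rnorm(3 * n_restarts), n_restarts, 3)
    0.6 * R * z / sqrt(rowSums(z^2))
  })

  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    opt <- stats::optim(rs[i, ], rv_at, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 400))
    conv <- opt$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || opt$value < best$value)
      best <- list(value = opt$value, par = opt$par, converged = conv)
  }

  if (!any_conv) {
    return(structure(list(dipole = dipole(best$par, c(0, 0, 0)),
                          residual_variance = 1,
                          radial_fraction = sqrt(sum(best$par^2)) / R,
                          converged = FALSE), class = "dipole_fit"))
  }
  loc <- best$par
  G <- .forward_gain(loc, montage, model, strict = FALSE)
  G <- G - rep(colMeans(G), each = nrow(G))
  m <- qr.solve(G, map)
  rv <- min(max(sum((map - as.numeric(G %*% m))^2) / ss_map, 0), 1)
  structure(list(dipole = dipole(loc, m),
                 residual_variance = rv,
                 radial_fraction = sqrt(sum(loc^2)) / R,
                 converged = best$converged),
            class = "dipole_fit")
}

#' Dipole-based rejection of independent components
#'
#' A component is rejected when its equivalent dipole explains the scalp
#' map poorly (residual variance above 10%), lies close to the skull
#' (more than 70% of the sphere radius from the centre), or below the
#' axial plane through the sphere centre (z < 0 mm; cerebellum/neck).
#' All thresholds are strict inequalities: a fit exactly at a threshold
#' is retained.
#'
#' @param fits List of `dipole_fit` objects, one per component.
#' @param rv_max Residual-variance threshold (default 0.10).
#' @param radial_max Radial-fraction threshold (default 0.70).
#' @param z_min Minimum dipole z coordinate in mm (default 0).
#' @return List with logical `keep` mask and character `reasons`
#'   (empty string for retained components).
#' @export
reject_components_by_dipole <- function(fits, rv_max = 0.10,
                                        radial_max = 0.70, z_min = 0) {
  reasons <- vapply(fits, function(f) {
    r <- character(0)
    if (f$residual_variance > rv_max) r <- c(r, "residual_variance")
    if (f$radial_fraction > radial_max) r <- c(r, "radial_fraction")
    if (f$dipole$location[3] < z_min) r <- c(r, "z_below_0")
    paste(r, collapse = ",")
  }, character(1))
  list(keep = reasons == "", reasons = reasons)
}

#' Detect eye-movement components
#'
#' Simplified blink/eye detector combining a spatial and a temporal
#' criterion: a component is flagged when its scalp map is frontally
#' dominated (mean absolute weight over the frontal electrodes exceeds
#' the mean absolute weight elsewhere by `frontal_factor`) and its
#' activation is either dominated by low-frequency power (< 4 Hz) or has
#' high temporal kurtosis (stereotyped transients).
#'
#' @param scalp_maps Channels x components matrix of scalp maps.
#' @param activations Components x samples matrix of activations.
#' @param montage A [montage()].
#' @param fs Sampling rate of the activations in Hz.
#' @param frontal_factor Spatial dominance factor (default 2).
#' @param lowfreq_frac Minimum fraction of power below 4 Hz (default 0.55).
#' @param kurtosis_min Minimum excess-free kurtosis (default 8).
#' @return Logical vector, one flag per component.
#' @export
detect_eye_components <- function(scalp_maps, activations, montage, fs,
                                  frontal_factor = 2, lowfreq_frac = 0.55,
                                  kurtosis_min = 8) {
  frontal <- c("Fp1", "Fpz", "Fp2", "AF7", "AF8")
  idx <- match(frontal, montage$labels)
  if (anyNA(idx))
    stop("montage lacks the frontal labels needed for eye detection")
  scalp_maps <- as.matrix(scalp_maps)
  activations <- as.matrix(activations)
  n_comp <- ncol(scalp_maps)
  stopifnot(nrow(activations) == n_comp)
  flags <- logical(n_comp)
  for (k in seq_len(n_comp)) {
    w <- abs(scalp_maps[, k])
    spatial <- mean(w[idx]) > frontal_factor * mean(w[-idx])
    a <- activations[k, ]
    v <- stats::var(a)
    if (v == 0 || !is.finite(v)) {
      warning(sprintf("component %d has zero-variance activation", k))
      next
    }
    if (!spatial) next
    sp <- abs(stats::fft(a - mean(a)))^2
    n <- length(a)
    freqs <- (seq_len(n) - 1) * fs / n
    half <- freqs <= fs / 2
    lf <- sum(sp[half & freqs < 4]) / sum(sp[half])
    ku <- mean((a - mean(a))^4) / v^2
    flags[k] <- (lf > lowfreq_frac) || (ku > kurtosis_min)
  }
  flags
}

# evaluate expr under a local, restorable RNG state with the given seed
.rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
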