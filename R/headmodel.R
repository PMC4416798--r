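#' 4-shell spherical head model
#'
#' Concentric 4-shell (brain, CSF, skull, scalp) spherical volume conductor
#' with BESA-style default geometry. The Legendre series coefficients of
#' the forward solution depend only on the shell geometry and are
#' precomputed at construction.
#'
#' @param shell_radii Radii of the four shells in mm, strictly increasing
#'   (brain, CSF, skull, scalp). Defaults 71/72/79/85 mm.
#' @param shell_conductivities Conductivities in S/m (same order).
#'   Defaults 0.33/1.0/0.0042/0.33.
#' @param series_terms Truncation of the Legendre expansion (>= 20,
#'   default 60). Terms are summed with an early stop when a term's
#'   relative contribution falls below `series_tol`.
#' @param series_tol Early-stop tolerance on the relative contribution of
#'   the last term (default 1e-12).
#' @return A `head_model` object.
#' @export
head_model <- function(shell_radii = c(71, 72, 79, 85),
                       shell_conductivities = c(0.33, 1.0, 0.0042, 0.33),
                       series_terms = 60,
                       series_tol = 1e-12) {
  if (length(shell_radii) != 4 || length(shell_conductivities) != 4)
    stop("exactly four shells are required")
  if (any(diff(shell_radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(shell_conductivities <= 0)) stop("conductivities must be positive")
  if (series_terms < 20) stop("series_terms must be at least 20")
  m <- structure(list(shell_radii = shell_radii,
                      shell_conductivities = shell_conductivities,
                      series_terms = as.integer(series_terms),
                      series_tol = series_tol),
                 class = "head_model")
  m$coef <- .shell_series_coef(m)
  m
}

# Per-degree transfer coefficients K_n of the layered sphere.
#
# In each shell the degree-n radial solution is A*rho^n + B*rho^-(n+1)
# (rho = r / scalp radius). The dipole source contributes rho^-(n+1) in
# shell 1 with unit coefficient; continuity of potential and radial
# current at the three interfaces plus zero radial current at the scalp
# give a 7x7 linear system per degree whose solution evaluated at the
# scalp surface is K_n.
.shell_series_coef <- function(model) {
  rho <- model$shell_radii / model$shell_radii[4]
  sig <- model$shell_conductivities
  N <- model$series_terms
  K <- numeric(N)
  for (n in seq_len(N)) {
    # unknowns: A1, A2, B2, A3, B3, A4, B4
    A <- matrix(0, 7, 7)
    b <- numeric(7)
    pw <- function(r) r^n
    pwm <- function(r) r^(-(n + 1))
    dpw <- function(r) n * r^(n - 1)
    dpwm <- function(r) -(n + 1) * r^(-(n + 2))
    for (j in 1:3) {
      r <- rho[j]
      # potential continuity: A_j r^n + B_j r^-(n+1) = A_{j+1} r^n + B_{j+1} r^-(n+1)
      rowp <- 2 * j - 1
      rowc <- 2 * j
      cols_j <- if (j == 1) c(1L, NA) else c(2L * j - 2L, 2L * j - 1L)
      cols_j1 <- c(2L * j, 2L * j + 1L)
      A[rowp, cols_j[1]] <- pw(r)
      if (!is.na(cols_j[2])) A[rowp, cols_j[2]] <- pwm(r)
      A[rowp, cols_j1[1]] <- -pw(r)
      A[rowp, cols_j1[2]] <- -pwm(r)
      # current continuity
      A[rowc, cols_j[1]] <- sig[j] * dpw(r)
      if (!is.na(cols_j[2])) A[rowc, cols_j[2]] <- sig[j] * dpwm(r)
      A[rowc, cols_j1[1]] <- -sig[j + 1] * dpw(r)
      A[rowc, cols_j1[2]] <- -sig[j + 1] * dpwm(r)
      if (j == 1) {
        # source term (coefficient 1 on rho^-(n+1) in shell 1)
        b[rowp] <- -pwm(r)
        b[rowc] <- -sig[1] * dpwm(r)
      }
    }
    # outer boundary: radial current vanishes at the scalp (rho = 1)
    A[7, 6] <- dpw(1)
    A[7, 7] <- dpwm(1)
    sol <- solve(A, b)
    K[n] <- sol[6] + sol[7]           # potential at the scalp surface
  }
  K
}

# Legendre polynomials P_n(x) and derivatives P'_n(x) for n = 1..N,
# vectorized over x; returns list of two (length(x) x N) matrices.
.legendre_pn <- function(x, N) {
  P <- matrix(0, length(x), N)
  dP <- matrix(0, length(x), N)
  Pm1 <- rep(1, length(x))   # P_0
  P[, 1] <- x
  dP[, 1] <- 1
  dPm1 <- rep(0, length(x))
  if (N > 1) {
    for (n in 1:(N - 1)) {
      # recurrence: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
      Pn1 <- ((2 * n + 1) * x * P[, n] - n * Pm1) / (n + 1)
      dPn1 <- ((2 * n + 1) * (P[, n] + x * dP[, n]) - n * dPm1) / (n + 1)
      Pm1 <- P[, n]; dPm1 <- dP[, n]
      P[, n + 1] <- Pn1
      dP[, n + 1] <- dPn1
    }
  }
  list(P = P, dP = dP)
}

#' Scalp potentials of a current dipole in the 4-shell spherical model
#'
#' Evaluates the analytic Legendre series of the concentric 4-shell
#' conductor at the montage electrodes and re-references to the channel
#' average. The result is linear in the dipole moment.
#'
#' @param dipole A [dipole()] (location mm, moment nA m).
#' @param montage A [montage()].
#' @param model A [head_model()].
#' @return Numeric vector of 64 average-referenced potentials in microvolts.
#' @export
forward_potentials <- function(dipole, montage, model) {
  if (sqrt(sum(dipole$location^2)) >= model$shell_radii[1])
    stop("dipole must lie strictly inside the brain shell")
  G <- .forward_gain(dipole$location, montage, model, strict = TRUE)
  v <- as.numeric(G %*% dipole$moment)
  v - mean(v)
}

# Gain matrix (n_electrodes x 3, microvolts per nA m, unreferenced) of a
# dipole location. Evaluates the series without the brain-shell domain
# check: the dipole fitter follows the BESA-style convention of letting
# the search wander beyond the innermost shell, where the same series is
# evaluated as a formal extension. With strict = TRUE a series whose last
# term still contributes more than `series_tol` raises a convergence
# error; with strict = FALSE the truncated sum is returned.
.forward_gain <- function(location, montage, model, strict = FALSE) {
  R <- model$shell_radii[4]
  b <- sqrt(sum(location^2))
  if (b >= 0.995 * R) stop("dipole location must lie inside the scalp sphere")
  E <- montage$positions / R          # unit electrode directions
  sigma1 <- model$shell_conductivities[1]
  # SI conversion: mm -> m, nA m -> A m; output in microvolts
  unit_scale <- 1e-9 / (sigma1 * (R * 1e-3)^2) * 1e6 / (4 * pi)
  f <- b / R
  u <- if (b < 1e-12) c(0, 0, 1) else location / b
  x <- as.numeric(E %*% u)
  N <- model$series_terms
  ns <- seq_len(N)
  cn <- model$coef * f^(ns - 1)
  # adaptive truncation: drop degrees whose scalar weight is negligible
  w <- abs(cn) * ns
  keepN <- which(w > max(w) * 1e-12)
  N <- max(2L, if (length(keepN)) max(keepN) else N)
  ns <- seq_len(N)
  cn <- cn[ns]
  leg <- .legendre_pn(x, N)
  # v = sum_n c_n [ (n P_n - x P'_n) (u . q) + P'_n (E q) ]
  a_tan <- as.numeric(leg$dP %*% cn)
  a_rad <- as.numeric(leg$P %*% (cn * ns)) - x * a_tan
  G <- a_rad %*% rbind(u) + a_tan * E
  # convergence: contribution of the last term relative to the total
  last <- max(abs(cn[N] * (N * leg$P[, N] - x * leg$dP[, N])),
              abs(cn[N] * leg$dP[, N]))
  last_rel <- last / max(max(abs(G)), .Machine$double.xmin)
  # a truncated series whose last term still moves the result by more than
  # 1e-4 relative is treated as non-convergent for the public forward op
  if (strict && last_rel > 1e-4)
    stop("Legendre series did not converge for this dipole location")
  G * unit_scale
}

#' Construct a current dipole
#'
#' @param location 3-vector, mm, head frame (+x anterior, +y left,
#'   +z superior).
#' @param moment 3-vector, nA m.
#' @return A `dipole` object.
#' @export
dipole <- function(location, moment) {
  stopifnot(length(location) == 3, length(moment) == 3)
  structure(list(location = as.numeric(location),
                 moment = as.numeric(moment)), class = "dipole")
}
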