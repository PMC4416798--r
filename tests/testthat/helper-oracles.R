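# Independent oracles and small fixtures shared across tests.

# Closed-form potential of a dipole in a homogeneous conducting sphere,
# evaluated on the surface. Derived by summing the Legendre series with
# generating-function identities; independent of the package's
# truncated multilayer series.
homog_sphere_oracle <- function(loc, mom, montage, sigma, R) {
  E <- montage$positions / R
  b <- sqrt(sum(loc^2))
  f <- b / R
  u <- if (b < 1e-12) c(0, 0, 1) else loc / b
  x <- as.numeric(E %*% u)
  qr <- sum(mom * u)
  tq <- as.numeric(E %*% mom) - qr * x
  S <- sqrt(1 - 2 * f * x + f^2)
  radial <- if (f < 1e-12) 3 * x else 2 * (x - f) / S^3 + (1 / S - 1) / f
  tang <- 2 / S^3 + (S + 1) / (S * (1 - f * x + S))
  v <- (qr * radial + tq * tang) / (4 * pi * sigma * (R * 1e-3)^2) * 1e-9 * 1e6
  v - mean(v)
}

# Amari permutation-invariance index of P = W %*% A (perfect separation
# gives 0; < 0.1 counts as recovered)
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * n * (n - 1))
}

# Mann-Whitney AUC oracle: fraction of positive/negative pairs ordered
# correctly, ties counted half
mann_whitney_auc <- function(scores, labels) {
  sp <- scores[labels == "change"]
  sn <- scores[labels != "change"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a short session plan (seconds) for cheap simulations
mini_plan <- function(speeds = c(0, 1, 0, 1), durations = rep(20, length(speeds))) {
  structure(list(condition = "cued", block_speeds = speeds,
                 block_durations = durations, accel_ramp = 4,
                 decel_ramp = 8, total_duration = sum(durations)),
            class = "session_plan")
}

# single unit-amplitude cortical source without ERD
flat_source <- function(loc = c(-12, -40, 40), band = c(8, 15), amp = 1,
                        erd_db = 0) {
  source_spec("cortical", loc, amp, band, erd_db)
}

# supergaussian band-limited sources mixed into 64 channels
make_mixture <- function(n_src = 8, n = 30000, fs = 256, seed = 41) {
  set.seed(seed)
  S <- matrix(0, n_src, n)
  for (j in seq_len(n_src)) {
    carrier <- gaitEEG:::.band_noise(n, fs, 8 + 2 * j, 16 + 2 * j)
    env <- abs(gaitEEG:::.band_noise(n, fs, 0.1, 1.2))
    S[j, ] <- carrier * env
  }
  A <- matrix(rnorm(64 * n_src), 64)
  list(S = S, A = A, X = A %*% S)
}

test_montage <- montage_biosemi64()
test_model <- head_model()
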