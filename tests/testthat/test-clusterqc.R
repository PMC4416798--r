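# Cross-subject component clustering, dorsal centroid projection and
# the artifact QC analyses.

# synthetic member pool: two tight dipole/map groups
make_members <- function(n_per = 20, seed = 91, outlier = FALSE) {
  set.seed(seed)
  centers <- list(c(-28, -36, 40), c(35, 10, 45))
  subject <- integer(0); fold <- integer(0); xyz <- NULL; maps <- NULL
  for (g in 1:2) {
    for (i in seq_len(n_per)) {
      loc <- centers[[g]] + rnorm(3, 0, 1.5)
      map <- forward_potentials(dipole(loc, loc / 10), test_montage,
                                test_model)
      subject <- c(subject, (i - 1) %% 4 + 1)
      fold <- c(fold, (i - 1) %/% 4 + 1)
      xyz <- rbind(xyz, loc); maps <- rbind(maps, map)
    }
  }
  if (outlier) {
    # ~10 within-cluster SDs away from group 1, but nearer to it than to
    # group 2, so k-means keeps it in the cluster
    loc <- c(-28, -36, 40) + c(18, 14, -16)
    xyz <- rbind(xyz, loc)
    maps <- rbind(maps, forward_potentials(dipole(loc * 0.9, c(5, 5, 5)),
                                           test_montage, test_model))
    subject <- c(subject, 1); fold <- c(fold, 9)
  }
  list(subject = subject, fold = fold,
       component = seq_along(subject), xyz = xyz, maps = maps)
}

test_that("well-separated groups are clustered perfectly with high silhouette", {
  mem <- make_members()
  cs <- cluster_components(mem, k = 2, seed = 1, n_folds = 5)
  expect_equal(length(cs$clusters), 2)
  truth <- rep(1:2, each = length(mem$subject) / 2)
  tab <- table(truth, cs$assignment)
  expect_equal(unname(sort(apply(tab, 1, max))), c(20, 20))
  # silhouette on the feature space
  d <- as.matrix(dist(cs$features))
  sil <- vapply(seq_len(40), function(i) {
    own <- cs$assignment == cs$assignment[i]
    a <- mean(d[i, own & seq_len(40) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.8)
  # determinism
  cs2 <- cluster_components(mem, k = 2, seed = 1, n_folds = 5)
  expect_identical(cs$assignment, cs2$assignment)
})

test_that("distant members are flagged as outliers and excluded", {
  mem <- make_members(outlier = TRUE)
  cs <- cluster_components(mem, k = 2, outlier_sd = 5, seed = 2,
                           n_folds = 5)
  expect_true(cs$outlier[41] || cs$assignment[41] == 0)
})

test_that("subjects contributing under 40% of folds are dropped from a cluster", {
  mem <- make_members()
  # subject 5 contributes 3 members (3 distinct folds) to group 1
  for (f in 1:3) {
    loc <- c(-28, -36, 40) + rnorm(3, 0, 2)
    mem$xyz <- rbind(mem$xyz, loc)
    mem$maps <- rbind(mem$maps,
                      forward_potentials(dipole(loc, loc / 10),
                                         test_montage, test_model))
    mem$subject <- c(mem$subject, 5)
    mem$fold <- c(mem$fold, f)
  }
  mem$component <- seq_along(mem$subject)
  cs <- cluster_components(mem, k = 2, seed = 3, n_folds = 10,
                           min_fold_frac = 0.4)
  expect_true(all(cs$assignment[mem$subject == 5] == 0))
})

test_that("dorsal projection lands on the cortex sphere", {
  p <- project_centroid_dorsal(c(0, 0, 10), 0.58, 85)
  expect_equal(p, c(0, 0, 49.3), tolerance = 1e-9)
  expect_equal(sqrt(sum(p^2)), 0.58 * 85, tolerance = 1e-9)
  on_sphere <- c(20, 10, sqrt(49.3^2 - 500))
  expect_equal(project_centroid_dorsal(on_sphere), on_sphere)
  set.seed(92)
  for (i in 1:10) {
    xy <- rnorm(2, 0, 15)
    pp <- project_centroid_dorsal(c(xy, runif(1, -10, 30)))
    expect_equal(sqrt(sum(pp^2)), 49.3, tolerance = 1e-9)
  }
  expect_warning(out <- project_centroid_dorsal(c(60, 0, 0)), "outside")
  expect_equal(out, c(60, 0, 0))
})

test_that("channel correlation QC produces symmetric unit-diagonal matrices", {
  cfg <- default_config()
  cfg$fs <- 256
  rec <- simulate_session(cfg, "cued", seed = 8, subject = 1,
                          session_id = 1)
  # duplicate one channel into another to force r^2 = 1
  rec$data[2, ] <- rec$data[1, ]
  qc <- channel_correlation_qc(list(rec), cfg)
  for (cond in names(qc$r2)) {
    M <- qc$r2[[cond]]
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_equal(diag(M), rep(1, 64), tolerance = 1e-12)
    expect_equal(M[1, 2], 1, tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1 + 1e-12))
  }
  expect_length(qc$mad, 3)
  expect_true(all(qc$mad >= 0))
})

test_that("retained-rejected pairing maximises the ERSP correlation", {
  set.seed(93)
  e1 <- matrix(rnorm(100), 10)
  ret <- list(compA = e1, compB = matrix(rnorm(100), 10))
  mkfit <- function(loc, rv) {
    structure(list(dipole = dipole(loc, c(1, 0, 0)),
                   residual_variance = rv,
                   radial_fraction = sqrt(sum(loc^2)) / 85,
                   converged = TRUE), class = "dipole_fit")
  }
  rej <- list(identical = e1, negated = -e1)
  fits <- list(mkfit(c(-80, 0, -10), 0.05), mkfit(c(-80, 5, -12), 0.05))
  best <- retained_rejected_pairing(ret, rej, fits)
  expect_equal(unname(best$pair), c("identical", "compA"))
  expect_equal(best$correlation, 1)
  # negation pairs at -1, so it can never win
  r_neg <- cor(as.numeric(-e1), as.numeric(e1))
  expect_equal(r_neg, -1)
  # ineligible pools: shallow, noisy or anterior dipoles
  fits_bad <- list(mkfit(c(-40, 0, 10), 0.05),  # radial fraction too small
                   mkfit(c(80, 0, -10), 0.05))  # anterior
  none <- retained_rejected_pairing(ret, rej, fits_bad)
  expect_null(none$pair)
  expect_equal(none$n_eligible, 0L)
})
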