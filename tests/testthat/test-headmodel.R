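# Forward model, montage geometry, dipole fitting and component
# rejection heuristics.

test_that("montage has 64 unique labelled positions with mirror symmetry", {
  m <- test_montage
  expect_length(unique(m$labels), 64)
  r <- sqrt(rowSums(m$positions^2))
  expect_true(all(abs(r - 85) < 1e-9 * 85))
  for (pair in list(c("C3", "C4"), c("F3", "F4"), c("P7", "P8"),
                    c("Fp1", "Fp2"), c("PO3", "PO4"))) {
    a <- m$positions[pair[1], ]
    b <- m$positions[pair[2], ]
    expect_equal(a[c(1, 3)], b[c(1, 3)], tolerance = 1e-9)
    expect_equal(a[2], -b[2], tolerance = 1e-9)
  }
  # anterior electrodes have positive x
  expect_true(m$positions["Fpz", 1] > 0)
  expect_true(m$positions["Oz", 1] < 0)
  expect_true(m$positions["Cz", 3] > 84)
})

test_that("montage round-trips through the TSV interface", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_montage(test_montage, path)
  m2 <- read_montage(path)
  expect_equal(m2$labels, test_montage$labels)
  expect_equal(unname(m2$positions), unname(test_montage$positions),
               tolerance = 1e-6)
})

test_that("forward solution is linear, superposing and average-referenced", {
  d1 <- dipole(c(10, 20, 30), c(5, -3, 2))
  d2 <- dipole(c(-15, 5, 40), c(0, 4, 1))
  v1 <- forward_potentials(d1, test_montage, test_model)
  v2 <- forward_potentials(d2, test_montage, test_model)
  v1d <- forward_potentials(dipole(d1$location, 2 * d1$moment),
                            test_montage, test_model)
  expect_equal(v1d, 2 * v1, tolerance = 1e-12)
  v12 <- forward_potentials(dipole(d1$location, d1$moment), test_montage,
                            test_model) +
    forward_potentials(d2, test_montage, test_model)
  expect_equal(v12, v1 + v2, tolerance = 1e-9)
  expect_lt(abs(sum(v1)), 1e-9 * sqrt(sum(v1^2)))
})

test_that("central radial dipole gives a rotationally symmetric topography", {
  v <- forward_potentials(dipole(c(0, 0, 0), c(0, 0, 10)), test_montage,
                          test_model)
  z <- test_montage$positions[, 3]
  for (zz in unique(round(z, 6))) {
    sel <- abs(z - zz) < 1e-6
    if (sum(sel) > 1) {
      expect_lt(diff(range(v[sel])), 1e-9 * max(abs(v)))
    }
  }
})

test_that("equal conductivities reduce to the homogeneous-sphere closed form", {
  hm <- head_model(shell_conductivities = rep(0.33, 4))
  set.seed(11)
  for (i in 1:12) {
    loc <- rnorm(3)
    loc <- loc / sqrt(sum(loc^2)) * runif(1, 0, 55)
    mom <- rnorm(3) * 10
    v <- forward_potentials(dipole(loc, mom), test_montage, hm)
    o <- homog_sphere_oracle(loc, mom, test_montage, 0.33, 85)
    expect_lt(max(abs(v - o)) / max(abs(o)), 1e-6)
  }
})

test_that("forward solver rejects invalid dipoles", {
  expect_error(forward_potentials(dipole(c(0, 0, 72), c(1, 0, 0)),
                                  test_montage, test_model),
               "brain shell")
  # truncating the series makes superficial dipoles non-convergent
  hm_short <- head_model(series_terms = 20)
  expect_error(forward_potentials(dipole(c(0, 0, 60), c(1, 0, 0)),
                                  test_montage, hm_short),
               "converge")
})

test_that("single-dipole fits recover noise-free forward maps", {
  set.seed(21)
  for (i in 1:5) {
    loc <- rnorm(3)
    loc <- loc / sqrt(sum(loc^2)) * runif(1, 15, 60)
    mom <- rnorm(3) * 20
    map <- forward_potentials(dipole(loc, mom), test_montage, test_model)
    fit <- fit_single_dipole(map, test_montage, test_model, seed = i)
    expect_lt(sqrt(sum((fit$dipole$location - loc)^2)), 2)
    expect_lt(fit$residual_variance, 1e-4)
    expect_true(fit$converged)
  }
})

test_that("degenerate and composite maps behave as specified", {
  expect_error(fit_single_dipole(rep(0, 64), test_montage, test_model),
               "constant")
  m1 <- forward_potentials(dipole(c(0, 35, 40), c(10, 0, 5)),
                           test_montage, test_model)
  m2 <- forward_potentials(dipole(c(0, -35, 40), c(-10, 0, 5)),
                           test_montage, test_model)
  f1 <- fit_single_dipole(m1, test_montage, test_model, seed = 1)
  f2 <- fit_single_dipole(m2, test_montage, test_model, seed = 1)
  f12 <- fit_single_dipole(m1 + m2, test_montage, test_model, seed = 1)
  expect_gt(f12$residual_variance,
            max(f1$residual_variance, f2$residual_variance))
})

test_that("dipole-based rejection applies strict thresholds", {
  mk <- function(rv, rf, z) {
    structure(list(dipole = dipole(c(0, 0, z) + c(rf * 85, 0, 0) * 0,
                                   c(1, 0, 0)),
                   residual_variance = rv, radial_fraction = rf,
                   converged = TRUE), class = "dipole_fit")
  }
  f_keep <- mk(0.05, 0.5, 30)
  f_z <- mk(0.05, 0.5, -1)
  f_rv <- mk(0.2, 0.5, 30)
  f_edge <- mk(0.10, 0.70, 0)
  res <- reject_components_by_dipole(list(f_keep, f_z, f_rv, f_edge))
  expect_equal(res$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(res$reasons[2], "z_below_0")
  expect_match(res$reasons[3], "residual_variance")
  expect_equal(res$reasons[4], "")
})

test_that("eye detector flags blink components but not parietal rhythms", {
  fs <- 256
  n <- 90 * fs
  blink_map <- as.numeric(gaitEEG:::.forward_gain(c(70, 0, -20),
                                                  test_montage, test_model)
                          %*% c(0.3, 0, 1))
  blink_map <- blink_map - mean(blink_map)
  par_map <- forward_potentials(dipole(c(-12, -40, 40), c(-2, -9, 11)),
                                test_montage, test_model)
  set.seed(5)
  blink_act <- numeric(n)
  for (t0 in sort(sample(seq_len(n - fs), 25)))
    blink_act[t0:(t0 + 75)] <- blink_act[t0:(t0 + 75)] +
      sin(pi * (0:75) / 75)^2
  par_act <- sin(2 * pi * 10 * seq_len(n) / fs) + rnorm(n, 0, 0.1)
  flags <- detect_eye_components(cbind(blink_map, par_map),
                                 rbind(blink_act, par_act),
                                 test_montage, fs)
  expect_true(flags[1])
  expect_false(flags[2])
  expect_warning(
    flags0 <- detect_eye_components(cbind(blink_map), rbind(rep(1, n)),
                                    test_montage, fs),
    "zero-variance")
  expect_false(flags0[1])
  bad_m <- montage(replace(test_montage$labels,
                           match(c("Fp1", "Fpz", "Fp2"),
                                 test_montage$labels),
                           c("X1", "X2", "X3")),
                   test_montage$positions)
  expect_error(detect_eye_components(cbind(par_map), rbind(par_act),
                                     bad_m, fs),
               "frontal")
})
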