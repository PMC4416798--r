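# Morlet wavelet decomposition, ERSP and ERD statistics.

test_that("the batch TF grid has 50 windows spanning -3789 to 3789 ms", {
  cfgtf <- tf_config(fs = 256, n_windows = 50)
  x <- rnorm(2048)
  tf <- wavelet_tf(x, cfgtf)
  expect_equal(dim(tf), c(20, 50))
  times <- tf_times(cfgtf, 2048, start_s = -4)
  expect_equal(times[1], -3.7891, tolerance = 1e-3)
  expect_equal(times[50], 3.7891, tolerance = 1e-3)
  expect_equal(times, -rev(times), tolerance = 1e-9)
  # sliding grid: 14 windows, -0.79..0.79 s around the epoch centre
  cfgsl <- tf_config(fs = 256, n_windows = 14)
  tsl <- tf_times(cfgsl, 512, start_s = -1)
  expect_equal(range(tsl), c(-0.7891, 0.7891), tolerance = 1e-3)
  expect_error(wavelet_tf(rnorm(50), cfgtf), "shorter")
})

test_that("frequencies are log-spaced and cycles ramp from 3 to 7.5", {
  cfgtf <- tf_config()
  expect_length(cfgtf$freqs, 20)
  expect_equal(range(cfgtf$freqs), c(8, 40))
  expect_equal(diff(log(cfgtf$freqs)), rep(log(40 / 8) / 19, 19),
               tolerance = 1e-12)
  expect_equal(range(cfgtf$cycles), c(3, 7.5))
  expect_true(all(diff(cfgtf$cycles) > 0))
})

test_that("doubling the amplitude raises every cell by 6.02 dB", {
  cfgtf <- tf_config(fs = 256, n_windows = 50)
  set.seed(51)
  x <- gaitEEG:::.band_noise(2048, 256, 8, 35)
  expect_equal(wavelet_tf(2 * x, cfgtf) - wavelet_tf(x, cfgtf),
               matrix(20 * log10(2), 20, 50), tolerance = 1e-9)
})

test_that("a pure sine peaks at the nearest frequency bin", {
  cfgtf <- tf_config(fs = 256, n_windows = 50)
  x <- sin(2 * pi * 12 * seq_len(2048) / 256)
  tf <- wavelet_tf(x, cfgtf)
  target <- which.min(abs(cfgtf$freqs - 12))
  for (w in 5:45) expect_equal(which.max(tf[, w]), target)
})

test_that("shifting by one window step shifts the TF columns by one", {
  # epoch length chosen so the window step is exactly 40 samples
  n <- 49 * 40 + 108
  cfgtf <- tf_config(fs = 256, n_windows = 50)
  set.seed(52)
  x <- gaitEEG:::.band_noise(n + 40, 256, 8, 35)
  tf1 <- wavelet_tf(x[1:n], cfgtf)
  tf2 <- wavelet_tf(x[41:(n + 40)], cfgtf)
  expect_equal(tf1[, 2:50], tf2[, 1:49], tolerance = 1e-6)
})

test_that("adding in-band power never lowers the target bin", {
  cfgtf <- tf_config(fs = 256, n_windows = 50)
  set.seed(53)
  x <- gaitEEG:::.band_noise(2048, 256, 20, 35)   # no content near 10 Hz
  bin10 <- which.min(abs(cfgtf$freqs - 10))
  tf1 <- wavelet_tf(x, cfgtf)
  tf2 <- wavelet_tf(x + 0.5 * sin(2 * pi * 10 * seq_len(2048) / 256),
                    cfgtf)
  expect_true(all(tf2[bin10, ] >= tf1[bin10, ] - 1e-9))
})

# build a small synthetic tf_tensor directly
make_tf_tensor <- function(power, label, times = NULL,
                           freqs = exp(seq(log(8), log(40), length.out = dim(power)[3]))) {
  if (is.null(times)) times <- seq(-3.789, 3.789, length.out = dim(power)[4])
  structure(list(power = power, freqs = freqs, times = times,
                 label = label, subclass = rep("1->2", dim(power)[1]),
                 session = rep(1, dim(power)[1]),
                 trial = seq_len(dim(power)[1]),
                 center = rep(0, dim(power)[1]),
                 condition = rep("cued", dim(power)[1])),
            class = "tf_tensor")
}

test_that("ERSP baselining behaves as specified on constructed tensors", {
  pw <- array(5, c(6, 2, 20, 50))
  lab <- rep(c("change", "constant"), each = 3)
  tf <- make_tf_tensor(pw, lab)
  # all-equal power: ERSP identically zero
  expect_equal(max(abs(ersp(tf, "change"))), 0)
  # self-normalisation: the baseline class averages to 0 dB
  pw2 <- pw + array(rnorm(length(pw), 0, 2), dim(pw))
  tf2 <- make_tf_tensor(pw2, lab)
  e <- ersp(tf2, "constant", baseline = "constant")
  expect_equal(apply(e, c(1, 2), mean), matrix(0, 2, 20),
               tolerance = 1e-9)
  # pre-onset baseline subtracts the early-window mean
  e2 <- ersp(tf2, "change", baseline = "preonset",
             baseline_range = c(-3.789, -1.007))
  tsel <- tf2$times <= -1.007
  expect_equal(apply(e2[, , tsel], c(1, 2), mean), matrix(0, 2, 20),
               tolerance = 1e-9)
  expect_error(ersp(make_tf_tensor(pw, rep("change", 6)), "change"),
               "constant")
})

test_that("ERD percentage follows its defining formula", {
  pw <- array(0, c(4, 1, 20, 50))
  lab <- rep("change", 4)
  tf <- make_tf_tensor(pw, lab)
  # A = R -> 0%
  expect_equal(erd_percent(tf, "change", c(8, 15), c(0.5, 1.5))$erd_percent,
               0)
  # A = R/2 -> -50%
  pw2 <- pw
  roi <- tf$times >= 0.5 & tf$times <= 1.5
  pw2[, , , roi] <- 10 * log10(0.5)
  tf2 <- make_tf_tensor(pw2, lab)
  expect_equal(erd_percent(tf2, "change", c(8, 15), c(0.5, 1.5),
                           reference = c(-3.8, -2.8))$erd_percent, -50,
               tolerance = 1e-9)
  # a -3 dB drop corresponds to -49.88%
  pw3 <- pw
  pw3[, , , roi] <- -3
  tf3 <- make_tf_tensor(pw3, lab)
  expect_equal(erd_percent(tf3, "change", c(8, 15), c(0.5, 1.5),
                           reference = c(-3.8, -2.8))$erd_percent,
               (10^(-0.3) - 1) * 100, tolerance = 1e-6)
  pw4 <- pw3
  pw4[, , , ] <- -Inf
  expect_error(erd_percent(make_tf_tensor(pw4, lab), "change",
                           c(8, 15), c(0.5, 1.5)), "zero")
})
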