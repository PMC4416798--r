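# Session plans, speed profiles, onset detection and the synthetic
# recording generator.

test_that("cued session plan reproduces the printed block design", {
  p <- make_session_plan("cued")
  expect_length(p$block_speeds, 19)
  expect_equal(p$total_duration, 380)
  expect_equal(p$block_speeds[1:6], c(0, 1, 2, 1, 2, 1))
  expect_equal(sum(diff(p$block_speeds) != 0), 18)
  pr <- render_speed_profile(p)
  ev <- detect_onsets_encoder(pr)
  expect_equal(nrow(ev), 18)
  expect_equal(sum(ev$to_kmh > ev$from_kmh), 9)
  # subclass composition of the design
  tab <- table(paste(ev$from_kmh, ev$to_kmh, sep = "->"))
  expect_equal(as.integer(tab[c("0->1", "1->2", "2->1", "1->0")]),
               c(3, 6, 6, 3))
})

test_that("uncued plans are seeded, truncated at 380 s and floored", {
  p1 <- make_session_plan("uncued", seed = 7)
  p2 <- make_session_plan("uncued", seed = 7)
  p3 <- make_session_plan("uncued", seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_equal(p1$total_duration, 380)
  expect_equal(p1$block_speeds[1:6], c(0, 1, 2, 1, 2, 1))
  ramps <- ifelse(diff(p1$block_speeds) > 0, 4, 8)
  steady <- p1$block_durations[-1] - ramps
  expect_true(all(steady[-length(steady)] >= 6))
})

test_that("speed ramps span 4 s up and 8 s down with zero plateau slope", {
  p <- mini_plan(c(0, 1, 2, 1))
  pr <- render_speed_profile(p)
  tr <- pr$transitions
  expect_equal(tr$ramp_s, c(4, 4, 8))
  kmh <- 1 / 3.6
  for (k in seq_len(nrow(tr))) {
    i0 <- which.min(abs(pr$t - tr$t_onset[k]))
    i1 <- which.min(abs(pr$t - (tr$t_onset[k] + tr$ramp_s[k])))
    expect_equal(pr$belt[i1] - pr$belt[i0],
                 (tr$to_kmh[k] - tr$from_kmh[k]) * kmh, tolerance = 0.02)
  }
  # plateau derivative is zero
  plateau <- pr$t > tr$t_onset[1] + 4.5 & pr$t < tr$t_init[2] - 0.5
  expect_true(all(diff(pr$belt[plateau]) == 0))
})

test_that("encoder onset detection crosses the threshold analytically", {
  # noiseless linear ramp of slope s starting at t0
  fs <- 64
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s <- 0.08
  t0 <- 10
  rel <- pmax(0, t - t0) * s
  prof <- structure(list(t = t, belt = rep(0, length(t)), rel = rel,
                         fs = fs,
                         transitions = data.frame(t_init = t0,
                                                  t_onset = t0 + 0.12 / s,
                                                  from_kmh = 0, to_kmh = 1,
                                                  ramp_s = 4),
                         plan = mini_plan(c(0, 1))),
                    class = "speed_profile")
  ev <- detect_onsets_encoder(prof, threshold = 0.12)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, t0 + 0.12 / s, tolerance = 1 / fs)
  # constant profile -> no events
  prof$rel <- rep(0, length(t))
  expect_equal(nrow(detect_onsets_encoder(prof)), 0)
})

test_that("zero-amplitude sources and zero noise give a silent recording", {
  src <- list(flat_source(amp = 0))
  rec <- simulate_recording(mini_plan(c(0, 1)), src, test_montage,
                            test_model, fs = 256, seed = 1, noise_sd = 0)
  expect_true(all(rec$data == 0))
})

test_that("a single cortical source yields a rank-1 recording", {
  rec <- simulate_recording(mini_plan(c(0, 1)), list(flat_source()),
                            test_montage, test_model, fs = 256, seed = 2,
                            noise_sd = 0)
  ref <- rec$data[which.max(rowSums(rec$data^2)), ]
  cors <- apply(rec$data, 1, function(ch)
    if (sd(ch) == 0) 1 else abs(cor(ch, ref)))
  expect_true(all(cors > 1 - 1e-10))
})

test_that("per-channel variance decomposes over independent sources", {
  srcs <- list(flat_source(c(-12, -40, 40), band = c(8, 15)),
               flat_source(c(15, -35, 38), band = c(16, 31)),
               source_spec("background", c(20, 10, 30), amp = 1,
                           band = c(1, 45), params = list(alpha = 1)))
  plan <- mini_plan(c(1, 1), durations = c(40, 40))
  noise_sd <- 0.02
  rec_all <- simulate_recording(plan, srcs, test_montage, test_model,
                                fs = 256, seed = 9, noise_sd = noise_sd)
  var_sum <- noise_sd^2
  for (j in seq_along(srcs)) {
    only_j <- lapply(seq_along(srcs), function(i) {
      s <- srcs[[i]]
      if (i != j) s$amp <- 0
      s
    })
    rj <- simulate_recording(plan, only_j, test_montage, test_model,
                             fs = 256, seed = 9, noise_sd = 0)
    var_sum <- var_sum + apply(rj$data, 1, stats::var)
  }
  var_all <- apply(rec_all$data, 1, stats::var)
  expect_lt(max(abs(var_all - var_sum) / var_sum), 0.02)
})

test_that("the implanted ERD drops mu power by the configured depth", {
  cfg <- default_config()
  src <- cfg$sources$parietal_mu
  plan <- mini_plan(rep(c(0, 1), 4))
  rec <- simulate_recording(plan,
                            list(source_spec("cortical", src$loc, src$amp,
                                             src$band, src$erd_db,
                                             src$erd_window)),
                            test_montage, test_model, fs = 512, seed = 4,
                            noise_sd = 0)
  ch <- which.max(rowSums(rec$data^2))
  spec <- design_fir(c(8, 15), 512)
  x <- apply_zero_phase(rec$data[ch, , drop = FALSE], spec)[1, ]
  on <- rec$events$onset_s
  p_in <- p_out <- numeric(0)
  for (o in on) {
    idx_in <- round((o + 0.35) * 512):round((o + 1.65) * 512)
    idx_out <- round((o - 3) * 512):round((o - 1) * 512)
    p_in <- c(p_in, mean(x[idx_in]^2))
    p_out <- c(p_out, mean(x[idx_out]^2))
  }
  drop_db <- 10 * log10(mean(p_in) / mean(p_out))
  expect_equal(drop_db, -src$erd_db, tolerance = 1)
})

test_that("subject simulation interleaves 7 cued and 3 uncued sessions", {
  conds <- session_conditions()
  expect_length(conds, 10)
  expect_equal(sum(conds == "cued"), 7)
  gaps <- diff(which(conds == "uncued"))
  expect_true(all(gaps %in% c(3, 4)))
  cfg <- default_config()
  cfg$fs <- 256
  recs <- simulate_subject(cfg, seed = 3)
  expect_length(recs, 10)
  expect_equal(vapply(recs, function(r) r$condition, ""), conds)
  # same subject seed -> identical cued plans; different seeds -> same
  # cued plan, different noise realisation
  r2 <- simulate_session(cfg, "cued", seed = 4, subject = 1, session_id = 1)
  expect_equal(r2$profile$transitions, recs[[1]]$profile$transitions)
  expect_false(identical(r2$data, recs[[1]]$data))
})

test_that("recordings round-trip through the BDF writer bit-compatibly", {
  cfg <- default_config()
  rec <- simulate_recording(mini_plan(c(0, 1), c(10, 10)),
                            build_sources(cfg, 1)[1:4], test_montage,
                            test_model, fs = 512, seed = 6, noise_sd = 1)
  path <- withr::local_tempfile(fileext = ".bdf")
  write_bdf(rec, path)
  rt <- read_bdf(path)
  expect_equal(rt$labels, rec$labels)
  expect_equal(rt$fs, rec$fs)
  phys_max <- max(1, ceiling(max(abs(range(rec$data)))))
  scale <- 8388607 / phys_max
  quantised <- round(rec$data * scale) / scale
  expect_equal(rt$data[, seq_len(ncol(rec$data))], quantised,
               tolerance = 1e-12)
  # writing the read-back data reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".bdf")
  rt$session_id <- rec$session_id
  write_bdf(rt, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})
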