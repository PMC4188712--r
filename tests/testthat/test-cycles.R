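# Kinematic resampling, cycle detection, outlier exclusion, time
# normalization, CMC and mean envelopes.

test_that("resampling preserves affine traces and sinusoids", {
  # constant
  tr <- resample_sync(rep(5, 100), fs_in = 50, target_fs = 2048)
  expect_true(all(abs(tr$angle - 5) < 1e-12))
  # linear ramp stays exactly linear
  ramp <- seq(0, 10, length.out = 100)
  tr2 <- resample_sync(ramp, fs_in = 50, target_fs = 2048)
  expect_equal(max(abs(diff(diff(tr2$angle)))), 0, tolerance = 1e-10)
  # 1 Hz, 30 deg sinusoid: < 0.5 deg against the analytic signal
  t50 <- seq(0, 5, by = 1 / 50)
  tr3 <- resample_sync(30 * sin(2 * pi * t50), fs_in = 50, target_fs = 2048)
  t2048 <- seq(0, 5, by = 1 / 2048)
  expect_lt(max(abs(tr3$angle - 30 * sin(2 * pi * t2048[seq_along(tr3$angle)]))),
            0.5)
  expect_error(resample_sync(numeric(0)), "empty")
})

test_that("cycle onsets match generator ground truth", {
  cfg <- sim_config(n_cycles = 20, time_jitter = 0, seed = 13)
  kin <- simulate_kinematics(cfg)
  tr <- resample_sync(kin$angle, fs_in = 50, target_fs = cfg$fs)
  cyc <- detect_cycles(tr)
  expect_length(cyc$onsets, 20)
  # the 2 deg rule fires a known delay after the true rise start
  # (2 deg / ramp slope) plus at most two 50 Hz kinematic samples
  delay <- 2 / (cfg$angle_flex - cfg$angle_ext) * cfg$trans_s * cfg$fs
  err <- cyc$onsets - kin$onsets - delay
  expect_true(all(err > -2 * cfg$fs / 50 & err < 2 * cfg$fs / 50))
})

test_that("onset rule: monotone traces and sub-threshold rises yield no cycle", {
  tr <- list(angle = seq(0, 50, length.out = 1000), fs = 50)
  expect_error(detect_cycles(tr), "no cycles")
  # rise of only 1.5 deg after the hold does not trigger an onset
  a <- c(seq(10, 0, length.out = 100), rep(0, 200), seq(0, 1.5, length.out = 50),
         rep(1.5, 200), seq(1.5, 0, length.out = 50), rep(0, 200))
  expect_error(detect_cycles(list(angle = a, fs = 50)), "no cycles")
})

test_that("range-of-motion outliers are excluded by Tukey fences", {
  mk_cycles <- function(rom) {
    structure(list(boundaries = cbind(start = seq_along(rom) * 100L,
                                      end = seq_along(rom) * 100L + 99L),
                   onsets = seq_along(rom) * 100L, rom = rom,
                   kept_mask = rep(TRUE, length(rom)), fs = 50),
              class = "cycle_set")
  }
  # identical ROMs: nothing excluded
  expect_true(all(exclude_outlier_cycles(mk_cycles(rep(60, 10)))$kept_mask))
  # one half-ROM cycle among 19 identical: exactly that one out
  out <- exclude_outlier_cycles(mk_cycles(c(rep(60, 19), 30)))
  expect_equal(which(!out$kept_mask), 20L)
  # two planted outliers among 12
  romj <- c(60 + seq(-0.5, 0.5, length.out = 10), 20, 100)
  out2 <- exclude_outlier_cycles(mk_cycles(romj))
  expect_equal(sort(which(!out2$kept_mask)), c(11L, 12L))
  expect_equal(sum(out2$kept_mask), 10)
  expect_error(exclude_outlier_cycles(mk_cycles(c(1, 2))), "at least 4")
})

test_that("time normalization yields exactly 500 phase points per cycle", {
  g <- grid_layout(2, 2)
  n <- 3 * 4096L
  env <- envelope_matrix(matrix(rep(seq_len(n) / n, 4), 4, byrow = TRUE),
                         fs = 2048, grid = g)
  cyc <- structure(list(boundaries = cbind(start = c(1L, 4097L),
                                           end = c(4097L, 8193L)),
                        onsets = c(1L, 4097L, 8193L), rom = c(1, 1),
                        kept_mask = c(TRUE, TRUE), fs = 2048),
                   class = "cycle_set")
  norm <- time_normalize(env, cyc)
  expect_equal(dim(norm$norm_env), c(4, 2, 500))
  # linear envelope stays linear with preserved endpoints
  expect_equal(norm$norm_env[1, 1, 1], 1 / n, tolerance = 1e-9)
  expect_equal(norm$norm_env[1, 1, 500], 4096 / n, tolerance = 1e-9)
  expect_lt(max(abs(diff(diff(norm$norm_env[1, 1, ])))), 1e-9)
  # constant envelope stays constant
  envc <- envelope_matrix(matrix(2, 4, n), fs = 2048, grid = g)
  normc <- time_normalize(envc, cyc)
  expect_true(all(normc$norm_env == 2))
})

test_that("CMC matches its brute-force definition and known limits", {
  # identical non-constant cycles: CMC = 1
  w <- matrix(rep(sin(seq(0, pi, length.out = 100)), 5), 5, byrow = TRUE)
  expect_equal(cmc(w), 1)
  # two-cycle {t, 2t} example against the loop oracle
  t <- seq(0, 1, length.out = 50)
  w2 <- rbind(t, 2 * t)
  expect_equal(cmc(w2), brute_cmc(w2), tolerance = 1e-12)
  # random waveforms agree with the oracle too
  set.seed(3)
  w3 <- matrix(runif(8 * 40), 8, 40)
  expect_equal(cmc(w3), brute_cmc(w3), tolerance = 1e-12)
  # independent white noise: CMC near 0
  set.seed(4)
  expect_lt(cmc(matrix(rnorm(20 * 500), 20, 500)), 0.2)
  expect_error(cmc(matrix(1, 3, 10)), "flat")
  # invariance to common scaling and common offsets
  expect_equal(cmc(5 * w3), cmc(w3), tolerance = 1e-12)
  expect_equal(cmc(w3 + 7), cmc(w3), tolerance = 1e-10)
})

test_that("mean envelope equals the loop mean", {
  set.seed(5)
  arr <- array(runif(3 * 4 * 10), dim = c(3, 4, 10))
  me <- mean_envelope(arr)
  for (ch in 1:3) {
    for (t in 1:10) {
      expect_equal(me[ch, t], mean(arr[ch, , t]), tolerance = 1e-12)
    }
  }
  # single cycle: identity; a and 3a average to 2a
  a <- matrix(runif(2 * 10), 2, 10)
  arr2 <- array(c(a, 3 * a), dim = c(2, 2, 10))
  arr2[, 1, ] <- a
  arr2[, 2, ] <- 3 * a
  expect_equal(mean_envelope(arr2), 2 * a, tolerance = 1e-12)
})

test_that("cycle boundaries partition the kept span without overlap", {
  tw <- tiny_wrist()
  b <- tw$proc$cycles$boundaries
  expect_true(all(diff(b[, "start"]) > 0))
  expect_true(all(b[-nrow(b), "end"] == b[-1, "start"]))
  expect_lte(sum(b[, "end"] - b[, "start"]), length(tw$proc$trace$angle))
})
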