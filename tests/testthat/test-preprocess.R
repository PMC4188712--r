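# Conditioning chain: band-pass, spectral-interpolation power-line removal,
# envelope extraction, bad-channel detection.

fs <- 2048
tt <- seq(0, 4, by = 1 / fs)
mk_rec <- function(X, grid = grid_layout(2, 4)) {
  emg_recording(t(X), fs = fs, grid = grid)
}

test_that("band-pass rejects out-of-band and preserves in-band components", {
  g <- grid_layout(2, 4)
  n <- length(tt)
  X <- cbind(rep(1, n),                      # DC
             sin(2 * pi * 100 * tt),         # passband
             sin(2 * pi * 10 * tt),          # below the 20 Hz corner
             rnorm(n), rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  out <- bandpass(mk_rec(X))
  mid <- 2000:6000
  expect_lt(max(abs(out$data[1, mid])), 1e-6)
  expect_equal(max(abs(out$data[2, mid])), 1, tolerance = 0.01)
  # forward-backward doubles the order: amplitude response is |H|^2.
  # 4th-order high-pass edge at 20 Hz evaluated at 10 Hz:
  # single pass |H| = 1/sqrt(1 + (20/10)^8), double pass |H|^2.
  att <- max(abs(out$data[3, mid]))
  expect_lt(att, 1 / (1 + (20 / 10)^8))
  expect_error(bandpass(emg_recording(t(X), fs = 800, grid = g)), "Nyquist")
})

test_that("spectral interpolation removes planted lines, preserves the rest", {
  # 16 s record: long enough that spectral leakage of the lines stays
  # inside the +/- 1 Hz interpolation bands
  tl <- (seq_len(16 * fs) - 1) / fs
  n <- length(tl)
  set.seed(1)
  noise <- t(filtfilt_mat(signal::butter(4, c(20, 450) / (fs / 2), "pass"),
                          matrix(rnorm(n * 8), n, 8)))
  lines <- 0.5 * sin(2 * pi * 50 * tl) + 0.3 * sin(2 * pi * 250 * tl)
  X <- noise + rep(1, 8) %o% lines
  rec <- emg_recording(X, fs = fs, grid = grid_layout(2, 4))
  out <- remove_powerline(rec)
  for (f in c(50, 250)) {
    before <- tone_amp(X[1, ], f, fs)
    after <- tone_amp(out$data[1, ], f, fs)
    expect_gt(20 * log10(before / after), 20)
  }
  # broadband (noise) RMS preserved within 2% once the lines are gone
  expect_equal(sqrt(mean(out$data[1, ]^2)), sqrt(mean(noise[1, ]^2)),
               tolerance = 0.02)
})

test_that("spectral interpolation is a near no-op off the harmonic bands", {
  tl <- (seq_len(8192) - 1) / fs
  X <- matrix(rep(sin(2 * pi * 80 * tl) + 0.5 * sin(2 * pi * 175 * tl) +
                    0.3 * sin(2 * pi * 310 * tl), 8),
              nrow = 8, byrow = TRUE)
  rec <- emg_recording(X, fs = fs, grid = grid_layout(2, 4))
  out <- remove_powerline(rec)
  expect_lt(sqrt(mean((out$data - X)^2)) / sqrt(mean(X^2)), 0.001)
  # idempotence: a second pass changes almost nothing
  out2 <- remove_powerline(out)
  expect_lt(sqrt(mean((out2$data - out$data)^2)) / sqrt(mean(out$data^2)),
            0.001)
})

test_that("envelope recovers the mean rectified value and stays nonnegative", {
  X <- matrix(rep(sin(2 * pi * 80 * tt), 8), nrow = 8, byrow = TRUE)
  rec <- emg_recording(X, fs = fs, grid = grid_layout(2, 4))
  env <- envelope(rec)
  mid <- 2000:6000
  expect_equal(mean(env$env[1, mid]), 2 / pi, tolerance = 0.02)
  # zero in, zero out
  env0 <- envelope(emg_recording(matrix(0, 8, 1000), fs = fs,
                                 grid = grid_layout(2, 4)))
  expect_true(all(env0$env == 0))
  # nonnegativity under random inputs
  set.seed(7)
  for (i in 1:20) {
    Xr <- matrix(rnorm(8 * 4000), 8, 4000)
    er <- envelope(emg_recording(Xr, fs = fs, grid = grid_layout(2, 4)))
    expect_true(all(er$env >= 0))
  }
})

test_that("zero-phase filtering leaves burst envelopes unshifted", {
  n <- length(tt)
  x <- rnorm(n) * exp(-(tt - 2)^2 / (2 * 0.2^2))
  X <- matrix(rep(x, 8), nrow = 8, byrow = TRUE)
  env <- envelope(bandpass(mk_rec(t(X))))
  expect_equal(which.max(env$env[1, ]) / fs, 2, tolerance = 0.02)
})

test_that("bad-channel detection flags planted defects, not activity", {
  # identical channels: nothing flagged
  g <- grid_layout(4, 4)
  E <- matrix(rep(abs(sin(seq(0, 20, length.out = 5000))), 16), 16,
              byrow = TRUE)
  env <- envelope_matrix(E + 0.01, fs = fs, grid = g)
  expect_equal(sum(detect_bad_channels(env)), 0)

  # one channel replaced by 100x amplitude noise: exactly that one flagged
  set.seed(21)
  burst <- abs(sin(seq(0, 30, length.out = 5000))) + 0.1
  base <- rep(1, 16) %o% burst * matrix(abs(rnorm(16 * 5000, 1, 0.05)), 16)
  bad <- base
  bad[6, ] <- abs(rnorm(5000, 0, 100))
  envb <- envelope_matrix(bad, fs = fs, grid = g)
  expect_equal(which(detect_bad_channels(envb)), 6L)

  # planted dead contacts in the full generator are recovered
  tw <- tiny_wrist()
  planted <- tw$rec$truth$bad_channels
  found <- which(tw$proc$bad_mask)
  expect_gte(length(intersect(planted, found)) / length(planted), 0.9)
  # and the flagged set stays small (no mass false positives)
  expect_lte(length(found), length(planted) + 5)
})
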