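# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small constructed fixtures.

# CMC evaluated with explicit loops, straight from the definition.
brute_cmc <- function(waves) {
  C <- nrow(waves)
  T <- ncol(waves)
  tbar <- numeric(T)
  for (t in seq_len(T)) tbar[t] <- mean(waves[, t])
  gbar <- mean(waves)
  num <- 0
  den <- 0
  for (c in seq_len(C)) {
    for (t in seq_len(T)) {
      num <- num + (waves[c, t] - tbar[t])^2
      den <- den + (waves[c, t] - gbar)^2
    }
  }
  sqrt(max(0, 1 - (num / (T * (C - 1))) / (den / (C * T - 1))))
}

# COG evaluated with an explicit loop over member electrodes.
brute_cog <- function(electrodes, weights) {
  A <- 0
  sx <- 0
  sy <- 0
  for (i in seq_len(nrow(electrodes))) {
    A <- A + weights[i]
    sx <- sx + weights[i] * electrodes[i, 1]
    sy <- sy + weights[i] * electrodes[i, 2]
  }
  c(sx / A, sy / A)
}

# Gaussian bump map on the standard 14 x 8 grid.
gaussian_map <- function(cx, cy, sigma = 1, amp = 1, grid = grid_layout()) {
  x <- seq_len(grid$n_cols)
  y <- seq_len(grid$n_rows)
  amp * exp(-outer((x - cx)^2, (y - cy)^2, "+") / (2 * sigma^2))
}

# Amplitude of frequency f in x sampled at fs (single-bin DFT).
tone_amp <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}

# Shared small synthetic wrist recording, computed once per test file load.
tiny_wrist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cycles = 6, seed = 42,
                        bad_channels = list(c(3, 2), c(11, 7)))
      rec <- simulate_emg(cfg)
      cache <<- list(cfg = cfg, rec = rec, proc = process_recording(rec))
    }
    cache
  }
})
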