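# Synthetic grid sEMG + joint-angle generator.
#
# Each planted source couples a spatial Gaussian footprint on the electrode
# grid to a nonnegative temporal activation profile defined on the normalized
# movement cycle (500 phase points). The surface signal of a source is its
# activation-modulated broadband carrier (20-450 Hz noise), projected onto
# the grid with the Gaussian weights; channels add source contributions,
# band-limited instrumentation noise, 50 Hz interference and (optionally)
# dead electrodes. Ground truth (source centres, gains, cycle onsets) is
# returned alongside the data so recovery can be tested.

#' Gaussian activation bump on the normalized movement cycle
#'
#' @param peak Phase of the peak in `[0, 1]`.
#' @param width Gaussian width in phase units.
#' @param n_points Number of phase samples (default 500).
#' @return Nonnegative numeric vector of length `n_points`, unit maximum.
#' @export
phase_bump <- function(peak, width, n_points = 500L) {
  phase <- seq(0, 1, length.out = n_points)
  exp(-(phase - peak)^2 / (2 * width^2))
}

#' Planted spatial-temporal source
#'
#' @param center Numeric `(x, y)` centre in electrode-grid units (continuous).
#' @param sigma Isotropic spatial spread in IED units, `> 0`.
#' @param profile Nonnegative temporal activation over the normalized cycle
#'   (length 500 by convention).
#' @param gain Named numeric vector of per-condition amplitude gains; at
#'   least one condition must have gain 1 (the reference).
#' @param label Optional source label.
#' @return An object of class `planted_source`.
#' @export
planted_source <- function(center, sigma, profile,
                           gain = c(neutral = 1), label = NULL) {
  stopifnot(length(center) == 2L, sigma > 0, all(profile >= 0),
            length(gain) >= 1L, !is.null(names(gain)))
  if (!any(abs(gain - 1) < 1e-12)) {
    stop("at least one condition gain must equal 1 (reference condition)",
         call. = FALSE)
  }
  structure(list(center = as.numeric(center), sigma = sigma,
                 profile = as.numeric(profile), gain = gain, label = label),
            class = "planted_source")
}

#' Simulation configuration
#'
#' Bundles the grid, planted sources and acquisition/variability settings of
#' one synthetic task recording. Defaults mirror the acquisition protocol the
#' pipeline is designed for: 2048 samples/s, 2 s target holds, 20 movement
#' cycles for wrist tasks.
#'
#' @param grid A [grid_layout()].
#' @param sources List of [planted_source()] objects.
#' @param n_cycles Number of movement cycles (>= 2).
#' @param hold_s Hold duration at each target position, seconds.
#' @param trans_s Duration of each dynamic transition, seconds.
#' @param angle_flex,angle_ext Target joint angles (degrees) of the flexion
#'   and extension holds; must differ.
#' @param fs EMG sampling rate, samples/s (> 900).
#' @param noise_snr_db Ratio (dB) of source-driven signal power to additive
#'   noise power, averaged over channels.
#' @param amp_jitter Relative SD of the per-cycle activation amplitude.
#' @param time_jitter Relative SD of the per-cycle duration.
#' @param powerline_amp Amplitude of the 50 Hz interference (same arbitrary
#'   units as the source signals); odd harmonics at 150 and 250 Hz are added
#'   at 1/3 and 1/5 of this amplitude.
#' @param bad_channels List of `(x, y)` electrode coordinates replaced by
#'   low-amplitude uncorrelated noise (dead contacts).
#' @param condition_shift_x Ulnar-radial displacement (IED units) applied to
#'   all source centres in the shifted condition.
#' @param shift_condition Condition label receiving `condition_shift_x`.
#' @param seed Integer seed; a fixed seed makes all outputs bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid = grid_layout(),
                       sources = default_wrist_sources(),
                       n_cycles = 20L,
                       hold_s = 2, trans_s = 0.5,
                       angle_flex = 30, angle_ext = -30,
                       fs = 2048,
                       noise_snr_db = 15,
                       amp_jitter = 0.10,
                       time_jitter = 0.05,
                       powerline_amp = 0.2,
                       bad_channels = list(),
                       condition_shift_x = 0,
                       shift_condition = "prone",
                       seed = 1L) {
  stopifnot(inherits(grid, "grid_layout"), fs > 2 * 450, n_cycles >= 2L,
            trans_s > 0, hold_s > 0, angle_flex != angle_ext)
  structure(list(grid = grid, sources = sources,
                 n_cycles = as.integer(n_cycles),
                 hold_s = hold_s, trans_s = trans_s,
                 angle_flex = angle_flex, angle_ext = angle_ext,
                 fs = fs, noise_snr_db = noise_snr_db,
                 amp_jitter = amp_jitter, time_jitter = time_jitter,
                 powerline_amp = powerline_amp, bad_channels = bad_channels,
                 condition_shift_x = condition_shift_x,
                 shift_condition = shift_condition,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default wrist-task sources: three modules with distinct footprints
#'
#' An extensor source active in the second half of the cycle, a flexor source
#' active in the first half, and a weaker third source active around the
#' mid-cycle transition; their phase profiles are nearly non-overlapping so
#' the planted envelope structure has rank 3.
#'
#' @param center_jitter Uniform half-width (IED units) of a per-call random
#'   displacement of the source centres (subject-to-subject anatomy).
#' @param gain_scale Multiplier on all source gains (finger tasks use 0.5).
#' @param prone_gain Named numeric: optional per-source gains in the `prone`
#'   condition (names among `extensor`, `flexor`, `third`).
#' @return List of three [planted_source()] objects.
#' @export
default_wrist_sources <- function(center_jitter = 0, gain_scale = 1,
                                  prone_gain = NULL) {
  jit <- function() if (center_jitter > 0) runif(2, -center_jitter, center_jitter) else c(0, 0)
  g <- function(lab) {
    gg <- c(neutral = 1)
    if (!is.null(prone_gain) && lab %in% names(prone_gain)) {
      gg <- c(neutral = 1, prone = unname(prone_gain[[lab]]))
    } else if (!is.null(prone_gain)) {
      gg <- c(neutral = 1, prone = 1)
    }
    gg
  }
  list(
    planted_source(c(4.5, 3.5) + jit(), sigma = 1.2,
                   profile = gain_scale * phase_bump(0.62, 0.09),
                   gain = g("extensor"), label = "extensor"),
    planted_source(c(10.5, 4.5) + jit(), sigma = 1.2,
                   profile = gain_scale * phase_bump(0.20, 0.09),
                   gain = g("flexor"), label = "flexor"),
    planted_source(c(7.5, 6.5) + jit(), sigma = 1.0,
                   profile = 0.85 * gain_scale * phase_bump(0.42, 0.08),
                   gain = g("third"), label = "third")
  )
}

#' Spatial channel weights of a planted source
#'
#' Isotropic Gaussian footprint evaluated at the electrode positions:
#' `w(x, y) = gain * exp(-((x - cx)^2 + (y - cy)^2) / (2 sigma^2))`.
#'
#' @param source A [planted_source()].
#' @param grid A [grid_layout()].
#' @param gain Amplitude multiplier (default 1; condition gains are applied
#'   by the simulator).
#' @return `n_cols x n_rows` matrix of nonnegative weights, indexed `[x, y]`.
#' @export
spatial_weights <- function(source, grid, gain = 1) {
  cx <- source$center[1]
  cy <- source$center[2]
  if (cx < 1 - 3 * source$sigma || cx > grid$n_cols + 3 * source$sigma ||
      cy < 1 - 3 * source$sigma || cy > grid$n_rows + 3 * source$sigma) {
    warning("source centre lies more than 3*sigma outside the grid; ",
            "it is mostly invisible", call. = FALSE)
  }
  x <- seq_len(grid$n_cols)
  y <- seq_len(grid$n_rows)
  gain * exp(-(outer((x - cx)^2, (y - cy)^2, "+")) / (2 * source$sigma^2))
}

#' Simulate trapezoidal joint-angle cycles
#'
#' Builds the joint-angle trace of a cyclic flexion/extension task: after a
#' lead-in descent to the extension target, each cycle rises to the flexion
#' target, holds, falls back to extension and holds again. Per-cycle duration
#' jitter scales all four segments of a cycle by a common factor. The angle
#' is returned at the kinematic acquisition rate (50 samples/s) together with
#' ground-truth flexion-onset sample indices on the EMG time base.
#'
#' @param cfg A [sim_config()].
#' @return List with `angle` (degrees, 50 samples/s), `fs_angle`,
#'   `onsets` (flexion-onset samples at `cfg$fs`, one per cycle),
#'   `onset_times` (seconds), `cycle_durations` (seconds) and `duration`.
#' @export
simulate_kinematics <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  kin_seed <- spawn_seeds(cfg$seed, 4L)[1L]
  fac <- with_seed(kin_seed, pmax(0.2, 1 + cfg$time_jitter * rnorm(cfg$n_cycles)))
  tr <- cfg$trans_s * fac
  hd <- cfg$hold_s * fac
  # breakpoints of the piecewise-linear angle trace
  bt <- 0
  bv <- 0
  lead <- cfg$trans_s + 0.75 * cfg$hold_s
  bt <- c(bt, cfg$trans_s, lead)
  bv <- c(bv, cfg$angle_ext, cfg$angle_ext)
  onset_times <- numeric(cfg$n_cycles)
  t_cur <- lead
  for (k in seq_len(cfg$n_cycles)) {
    onset_times[k] <- t_cur
    bt <- c(bt, t_cur + tr[k], t_cur + tr[k] + hd[k],
            t_cur + 2 * tr[k] + hd[k], t_cur + 2 * tr[k] + 2 * hd[k])
    bv <- c(bv, cfg$angle_flex, cfg$angle_flex, cfg$angle_ext, cfg$angle_ext)
    t_cur <- t_cur + 2 * tr[k] + 2 * hd[k]
  }
  duration <- t_cur
  fs_angle <- 50
  t50 <- seq(0, duration, by = 1 / fs_angle)
  angle <- approx(bt, bv, xout = t50, rule = 2)$y
  cycle_dur <- 2 * tr + 2 * hd
  list(angle = angle, fs_angle = fs_angle,
       onsets = 1L + as.integer(round(onset_times * cfg$fs)),
       onset_times = onset_times,
       cycle_durations = cycle_dur, duration = duration)
}

# Per-sample cycle phase in [0, 1) and cycle index on the EMG time base.
cycle_phase <- function(cfg, kin) {
  n <- as.integer(floor(kin$duration * cfg$fs))
  tt <- (seq_len(n) - 1L) / cfg$fs
  starts <- kin$onset_times
  ends <- c(starts[-1L], kin$duration)
  idx <- findInterval(tt, starts)
  phase <- numeric(n)
  pre <- idx == 0L
  phase[pre] <- 0.999  # lead-in behaves like the late extension hold
  for (k in seq_along(starts)) {
    sel <- idx == k
    phase[sel] <- (tt[sel] - starts[k]) / (ends[k] - starts[k])
  }
  phase <- pmin(phase, 1 - 1e-9)
  list(phase = phase, cycle = idx, n = n, t = tt)
}

#' Simulate a multi-channel grid sEMG recording
#'
#' @param cfg A [sim_config()].
#' @param condition Condition label; must be present in every source's gain
#'   map. In `cfg$shift_condition` all source centres are displaced by
#'   `cfg$condition_shift_x` along the ulnar-radial (x) axis.
#' @return An [emg_recording()] whose `truth` field carries the planted
#'   source centres (after any condition shift), per-condition gains, spatial
#'   weight maps, temporal profiles and ground-truth cycle onsets.
#' @export
simulate_emg <- function(cfg, condition = "neutral") {
  stopifnot(inherits(cfg, "sim_config"))
  kin <- simulate_kinematics(cfg)
  ph <- cycle_phase(cfg, kin)
  n <- ph$n
  nch <- n_channels(cfg$grid)
  seeds <- spawn_seeds(cfg$seed, 4L)
  src_seeds <- with_seed(seeds[2L], sample.int(.Machine$integer.max - 1L,
                                               length(cfg$sources)))
  shift <- if (identical(condition, cfg$shift_condition)) cfg$condition_shift_x else 0
  bp <- signal::butter(4, c(20, 450) / (cfg$fs / 2), "pass")

  S <- matrix(0, n, nch)
  truth_centers <- matrix(NA_real_, length(cfg$sources), 2L)
  truth_gains <- numeric(length(cfg$sources))
  truth_maps <- vector("list", length(cfg$sources))
  np <- length(cfg$sources[[1L]]$profile)
  for (s in seq_along(cfg$sources)) {
    src <- cfg$sources[[s]]
    if (!condition %in% names(src$gain)) {
      stop("condition '", condition, "' absent from source gain map", call. = FALSE)
    }
    g <- unname(src$gain[[condition]])
    src_shift <- src
    src_shift$center <- src$center + c(shift, 0)
    w <- spatial_weights(src_shift, cfg$grid, gain = g)
    truth_centers[s, ] <- src_shift$center
    truth_gains[s] <- g
    truth_maps[[s]] <- w
    prof_idx <- 1L + as.integer(floor(ph$phase * (np - 1L) + 0.5))
    act <- src$profile[prof_idx]
    comp <- with_seed(src_seeds[s], {
      ampfac <- pmax(0, 1 + cfg$amp_jitter * rnorm(cfg$n_cycles))
      cyc <- pmax(ph$cycle, 1L)
      carrier <- filtfilt_mat(bp, rnorm(n))
      carrier <- carrier / sd(carrier)
      act * ampfac[cyc] * carrier
    })
    S <- S + outer(comp, map_to_channel_vector(w, cfg$grid))
  }

  p_signal <- mean(S^2)
  noise_sd <- sqrt(max(p_signal, 1e-12) * 10^(-cfg$noise_snr_db / 10))
  noise <- with_seed(seeds[3L], {
    N <- matrix(rnorm(n * nch), n, nch)
    N <- filtfilt_mat(bp, N)
    noise_sd * N / sd(N)
  })
  X <- S + noise

  if (cfg$powerline_amp > 0) {
    phases <- with_seed(seeds[4L], runif(nch, 0, 2 * pi))
    for (h in c(1, 3, 5)) {
      arg <- 2 * pi * 50 * h * ph$t
      amp <- cfg$powerline_amp / h
      # sin(arg + phi) expanded so no n x channels trig matrix is formed
      X <- X + outer(sin(arg), amp * cos(phases)) +
        outer(cos(arg), amp * sin(phases))
    }
  }

  bad_mask <- rep(FALSE, nch)
  if (length(cfg$bad_channels)) {
    bad_idx <- vapply(cfg$bad_channels, function(xy)
      coord_to_channel(cfg$grid, xy[1], xy[2]), integer(1))
    bad_mask[bad_idx] <- TRUE
    X[, bad_idx] <- with_seed(seeds[4L] + 1L,
                              matrix(0.25 * noise_sd * rnorm(n * length(bad_idx)),
                                     n, length(bad_idx)))
  }

  truth <- list(centers = truth_centers, gains = truth_gains,
                weight_maps = truth_maps,
                profiles = lapply(cfg$sources, `[[`, "profile"),
                labels = vapply(cfg$sources, function(s) s$label %||% "", ""),
                onsets = kin$onsets, noise_sd = noise_sd,
                condition = condition, shift_x = shift,
                bad_channels = which(bad_mask))
  emg_recording(t(X), fs = cfg$fs, grid = cfg$grid,
                bad_mask = bad_mask,
                meta = list(condition = condition, n_cycles = cfg$n_cycles,
                            seed = cfg$seed),
                truth = truth, kinematics = kin)
}
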