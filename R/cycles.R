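# Movement-cycle segmentation from joint kinematics, range-of-motion outlier
# rejection, time normalization of envelopes onto a 500-point phase axis and
# envelope repeatability (coefficient of multiple correlation).

#' Resample a joint-angle trace and align it with the EMG time base
#'
#' Linear-interpolation resampling of a low-rate kinematic trace (glove data
#' is acquired at 50 samples/s) to the EMG sampling rate.
#'
#' @param angle_raw Numeric angle trace, degrees.
#' @param fs_in Input sampling rate, samples/s (default 50).
#' @param target_fs Output sampling rate, samples/s (default 2048).
#' @param joint,movement Optional labels carried along.
#' @return A `joint_trace`: list with `angle`, `fs`, `joint`, `movement`.
#' @export
resample_sync <- function(angle_raw, fs_in = 50, target_fs = 2048,
                          joint = NA_character_, movement = NA_character_) {
  if (!length(angle_raw)) stop("empty kinematic trace", call. = FALSE)
  stopifnot(all(is.finite(angle_raw)), fs_in > 0, target_fs > 0)
  dur <- (length(angle_raw) - 1L) / fs_in
  t_out <- seq(0, dur, by = 1 / target_fs)
  t_in <- seq(0, dur, by = 1 / fs_in)
  angle <- approx(t_in, angle_raw, xout = t_out, rule = 2)$y
  structure(list(angle = angle, fs = target_fs, joint = joint,
                 movement = movement),
            class = "joint_trace")
}

#' Detect movement-cycle onsets from a joint-angle trace
#'
#' Flexion is mapped to increasing angle. During each extension hold the
#' running extremum (most-extended, i.e. lowest, angle) is tracked; a new
#' flexion onset is declared at the first sample where the angle exceeds
#' that extremum by `delta` degrees. A movement cycle spans consecutive
#' onsets (half-open); the partial segments before the first and after the
#' last onset are discarded.
#'
#' @param trace A `joint_trace` (or a list with `angle` and `fs`).
#' @param delta Onset threshold above the extension extremum, degrees
#'   (default 2).
#' @param polarity `+1` if flexion increases the angle (default), `-1` to
#'   flip the convention.
#' @return A `cycle_set`: list with `boundaries` (two-column matrix of
#'   half-open `[start, end)` sample indices), `onsets`, `rom` (per-cycle
#'   range of motion, degrees), `kept_mask`.
#' @export
detect_cycles <- function(trace, delta = 2, polarity = 1) {
  a <- polarity * trace$angle
  n <- length(a)
  onsets <- integer(0)
  state <- "track_ext"  # tracking the extension extremum
  ext_ref <- a[1L]
  peak <- -Inf
  for (i in seq_len(n)) {
    if (state == "track_ext") {
      if (a[i] < ext_ref) ext_ref <- a[i]
      if (a[i] > ext_ref + delta) {
        onsets <- c(onsets, i)
        state <- "await_descent"
        peak <- a[i]
      }
    } else {
      if (a[i] > peak) peak <- a[i]
      if (a[i] < peak - delta) {
        state <- "track_ext"
        ext_ref <- a[i]
      }
    }
  }
  if (length(onsets) < 2L) stop("no cycles", call. = FALSE)
  starts <- onsets[-length(onsets)]
  ends <- onsets[-1L]
  rom <- vapply(seq_along(starts), function(k) {
    seg <- trace$angle[starts[k]:(ends[k] - 1L)]
    diff(range(seg))
  }, numeric(1))
  structure(list(boundaries = cbind(start = starts, end = ends),
                 onsets = onsets, rom = rom,
                 kept_mask = rep(TRUE, length(starts)),
                 fs = trace$fs),
            class = "cycle_set")
}

#' Exclude cycles with outlying range of motion
#'
#' A cycle is excluded when its range of motion lies outside the Tukey
#' fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the per-task ROM distribution.
#'
#' @param cycles A `cycle_set` with at least 4 cycles.
#' @param k Fence multiplier (default 1.5).
#' @return The `cycle_set` with `kept_mask` updated and the exclusion
#'   fraction in `excluded_frac`.
#' @export
exclude_outlier_cycles <- function(cycles, k = 1.5) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (length(cycles$rom) < 4L) stop("need at least 4 cycles", call. = FALSE)
  q <- quantile(cycles$rom, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- cycles$rom >= q[1] - k * iqr & cycles$rom <= q[2] + k * iqr
  if (mean(!keep) > 0.6) {
    stop("more than 60% of cycles excluded: task invalid", call. = FALSE)
  }
  cycles$kept_mask <- keep
  cycles$excluded_frac <- mean(!keep)
  cycles
}

#' Time-normalize envelopes and angle onto a fixed phase axis
#'
#' Each kept cycle's envelope (per channel) and joint angle are resampled by
#' linear interpolation onto `n_points` equispaced phase points.
#'
#' @param env An [envelope_matrix()].
#' @param cycles A `cycle_set` (with `kept_mask` set).
#' @param angle Joint-angle vector on the same time base as `env`
#'   (optional).
#' @param n_points Phase points per cycle (default 500).
#' @return List with `norm_env` (channels x kept-cycles x `n_points` array),
#'   `norm_angle` (kept-cycles x `n_points`, or `NULL`), `kept` (kept cycle
#'   indices).
#' @export
time_normalize <- function(env, cycles, angle = NULL, n_points = 500L) {
  stopifnot(inherits(env, "envelope_matrix"), inherits(cycles, "cycle_set"))
  kept <- which(cycles$kept_mask)
  if (!length(kept)) stop("no kept cycles", call. = FALSE)
  nch <- nrow(env$env)
  norm_env <- array(0, dim = c(nch, length(kept), n_points))
  norm_angle <- if (!is.null(angle)) matrix(0, length(kept), n_points) else NULL
  for (j in seq_along(kept)) {
    k <- kept[j]
    s <- cycles$boundaries[k, 1L]
    e <- cycles$boundaries[k, 2L] - 1L  # last sample of the half-open cycle
    if (e - s + 1L < 2L) stop("cycle shorter than 2 samples", call. = FALSE)
    pos <- seq(s, e, length.out = n_points)
    i0 <- pmin(floor(pos), e - 1L)
    frac <- pos - i0
    w0 <- 1 - frac
    seg <- env$env[, s:e, drop = FALSE]
    off <- s - 1L
    norm_env[, j, ] <- seg[, i0 - off, drop = FALSE] * rep(w0, each = nch) +
      seg[, i0 - off + 1L, drop = FALSE] * rep(frac, each = nch)
    if (!is.null(angle)) {
      norm_angle[j, ] <- angle[i0] * w0 + angle[i0 + 1L] * frac
    }
  }
  list(norm_env = norm_env, norm_angle = norm_angle, kept = kept,
       n_points = n_points)
}

#' Coefficient of multiple correlation (CMC) of repeated waveforms
#'
#' Waveform repeatability across repeated movement cycles in the within-day
#' form of Kadaba et al.: with C cycles and T phase points,
#' `CMC = sqrt(1 - [sum (y_ct - ybar_t)^2 / (T (C-1))] /
#'                 [sum (y_ct - ybar)^2 / (C T - 1)])`
#' where `ybar_t` is the across-cycle mean at phase t and `ybar` the grand
#' mean. For mutually independent cycles the variance ratio has expectation
#' 1, so CMC is near 0; identical cycles give 1. Values are clipped at 0
#' when the ratio exceeds 1.
#'
#' @param waves Cycles x phase-points numeric matrix (>= 2 cycles).
#' @return Scalar in `[0, 1]`.
#' @export
cmc <- function(waves) {
  waves <- as.matrix(waves)
  C <- nrow(waves)
  T <- ncol(waves)
  if (C < 2L) stop("CMC needs at least 2 cycles", call. = FALSE)
  gbar <- mean(waves)
  tot <- sum((waves - gbar)^2)
  if (tot == 0) stop("flat waveform: zero total variance", call. = FALSE)
  tbar <- colMeans(waves)
  within <- sum(sweep(waves, 2L, tbar)^2)
  ratio <- (within / (T * (C - 1))) / (tot / (C * T - 1))
  sqrt(max(0, 1 - ratio))
}

#' Per-channel CMC over kept cycles
#'
#' @param norm_env Channels x cycles x phase array from [time_normalize()].
#' @return Numeric vector of CMC values, one per channel (NA for channels
#'   with zero variance).
#' @export
channel_cmc <- function(norm_env) {
  vapply(seq_len(dim(norm_env)[1L]), function(ch) {
    w <- norm_env[ch, , , drop = TRUE]
    if (sum((w - mean(w))^2) == 0) return(NA_real_)
    cmc(w)
  }, numeric(1))
}

#' Mean envelope across kept cycles
#'
#' @param norm_env Channels x cycles x phase array.
#' @return Channels x phase matrix of cycle-averaged envelopes.
#' @export
mean_envelope <- function(norm_env) {
  apply(norm_env, c(1L, 3L), mean)
}

#' Identify channels carrying task-related activity
#'
#' A channel counts as active when its envelope peak (95th percentile)
#' exceeds `factor` times its own noise floor (10th percentile): channels
#' without task-locked bursts sit at a nearly constant baseline, so their
#' peak-to-floor ratio stays near 1.
#'
#' @param env An [envelope_matrix()].
#' @param factor Multiple of the per-channel noise floor (default 2).
#' @return Logical vector per channel (FALSE for bad-masked channels).
#' @export
active_channels <- function(env, factor = 2) {
  n <- ncol(env$env)
  # skip the filter-transient edges of the recording
  trim <- if (n > 8 * env$fs) as.integer(2 * env$fs) else 0L
  span <- (1L + trim):(n - trim)
  step <- max(1L, length(span) %/% 20000L)
  E <- env$env[, span[seq(1L, length(span), by = step)], drop = FALSE]
  lo <- apply(E, 1L, quantile, probs = 0.10, names = FALSE)
  hi <- apply(E, 1L, quantile, probs = 0.95, names = FALSE)
  act <- hi > factor * lo
  act & !env$bad_mask
}
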