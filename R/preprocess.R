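# Signal conditioning of raw monopolar grid sEMG:
#   band-pass -> power-line removal -> envelope -> bad-channel detection.
# All filters are zero-phase (forward-backward Butterworth), so envelope
# timing is not skewed relative to the kinematics.

#' Band-pass filter a recording (20-450 Hz, zero phase)
#'
#' 4th-order Butterworth band-pass applied forward-backward, which doubles
#' the effective order and cancels the phase response.
#'
#' @param rec An [emg_recording()].
#' @param low,high Corner frequencies in Hz.
#' @return The filtered [emg_recording()].
#' @export
bandpass <- function(rec, low = 20, high = 450) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$fs <= 2 * high) {
    stop(sprintf(paste0("sampling rate %g is too low: the Nyquist frequency ",
                        "must exceed the %g Hz upper corner"), rec$fs, high),
         call. = FALSE)
  }
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), "pass")
  rec$data <- t(filtfilt_mat(bf, t(rec$data)))
  rec$provenance <- c(rec$provenance,
                      sprintf("bandpass Butterworth order 4 %g-%g Hz, zero phase",
                              low, high))
  rec
}

#' Remove power-line interference by spectral interpolation
#'
#' For each harmonic `k * f0` (k = 1..`n_harmonics`) the magnitude spectrum
#' inside a narrow band (+/- `half_width` Hz) is replaced by linear
#' interpolation of the mean magnitudes of the flanking bands of the same
#' width; phases are retained, so the inverse transform stays real and the
#' spectrum outside the bands is untouched.
#'
#' @param rec An [emg_recording()].
#' @param f0 Fundamental interference frequency, Hz (default 50).
#' @param n_harmonics Number of harmonics removed, fundamental included
#'   (default 5, i.e. 50, 100, ..., 250 Hz).
#' @param half_width Half-width of the replaced band, Hz.
#' @return The cleaned [emg_recording()].
#' @export
remove_powerline <- function(rec, f0 = 50, n_harmonics = 5L, half_width = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  if (f0 * n_harmonics >= rec$fs / 2) {
    stop("highest harmonic lies at or above the Nyquist frequency", call. = FALSE)
  }
  rec$data <- t(spectral_interpolate(t(rec$data), rec$fs, f0, n_harmonics,
                                     half_width))
  rec$provenance <- c(rec$provenance,
                      sprintf("spectral interpolation %g Hz x %d harmonics (+/- %g Hz)",
                              f0, n_harmonics, half_width))
  rec
}

# Core of remove_powerline, operating on a samples x channels matrix.
# The signal is reflection-padded to a fast FFT length; magnitudes inside
# each harmonic band are replaced by linear interpolation between the mean
# magnitudes of the lower and upper flanking bands.
spectral_interpolate <- function(X, fs, f0, n_harmonics, half_width) {
  n <- nrow(X)
  nfft <- stats::nextn(n, c(2, 3, 5))
  if (nfft > n) {
    pad <- X[n:(n - (nfft - n) + 1L), , drop = FALSE]  # even (mirror) extension
    Xp <- rbind(X, pad)
  } else {
    Xp <- X
  }
  F <- stats::mvfft(Xp)
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  for (k in seq_len(n_harmonics)) {
    fk <- k * f0
    band <- which(freqs >= fk - half_width & freqs <= fk + half_width)
    lower <- which(freqs >= fk - 3 * half_width & freqs < fk - half_width)
    upper <- which(freqs > fk + half_width & freqs <= fk + 3 * half_width)
    if (!length(band) || !length(lower) || !length(upper)) next
    magL <- colMeans(abs(F[lower, , drop = FALSE]))
    magU <- colMeans(abs(F[upper, , drop = FALSE]))
    w <- (freqs[band] - (fk - half_width)) / (2 * half_width)
    mirror <- nfft - band + 2L  # conjugate-symmetric bins
    for (ch in seq_len(ncol(F))) {
      new_mag <- (1 - w) * magL[ch] + w * magU[ch]
      old <- F[band, ch]
      old_mag <- abs(old)
      scale <- ifelse(old_mag > 0, new_mag / old_mag, 0)
      F[band, ch] <- old * scale
      F[mirror, ch] <- Conj(F[band, ch])
    }
  }
  Y <- Re(stats::mvfft(F, inverse = TRUE)) / nfft
  Y[seq_len(n), , drop = FALSE]
}

#' Extract sEMG envelopes (rectify + 1 Hz zero-phase low-pass)
#'
#' The envelope is the absolute value of the conditioned signal, low-pass
#' filtered with a forward-backward 4th-order Butterworth filter at 1 Hz.
#' Small negative excursions produced by filter ringing are clipped to 0,
#' because the downstream factorization requires nonnegative input.
#'
#' @param rec An [emg_recording()], already band-passed and cleaned.
#' @param cutoff Low-pass cutoff in Hz (default 1).
#' @return An [envelope_matrix()].
#' @export
envelope <- function(rec, cutoff = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  lf <- signal::butter(4, cutoff / (rec$fs / 2), "low")
  env <- t(filtfilt_mat(lf, abs(t(rec$data)), padlen = min(ncol(rec$data) - 1L,
                                                           as.integer(rec$fs))))
  env[env < 0] <- 0
  envelope_matrix(env, fs = rec$fs, grid = rec$grid, bad_mask = rec$bad_mask,
                  provenance = c(rec$provenance,
                                 sprintf("envelope: |x| -> Butterworth order 4 low-pass %g Hz, zero phase, clipped at 0",
                                         cutoff)))
}

#' Detect channels with bad electrode-skin contact
#'
#' Combines a robust amplitude screen with a spatial-coherence screen.
#' Channels whose log-RMS envelope lies more than `z_thresh` robust z-units
#' (median/MAD) *below* the grid median are flagged as dead contacts.
#' Channels more than `z_thresh` units *above* the median are flagged only
#' when their envelope is also spatially incoherent (maximum absolute
#' correlation with the 4-connected grid neighbours below `cor_high`):
#' genuine muscle activity is spatially smooth across adjacent electrodes,
#' whereas contact artifacts are not. Independently, any channel whose
#' maximum neighbour correlation falls below `cor_thresh` is flagged.
#' Flagged channels are excluded from all downstream maps and statistics.
#'
#' @param env An [envelope_matrix()].
#' @param z_thresh Robust z-score threshold (default 3.5).
#' @param cor_thresh Minimum neighbour correlation for any channel
#'   (default 0.2).
#' @param cor_high Neighbour-correlation guard for high-amplitude outliers
#'   (default 0.5).
#' @return Logical bad-channel mask (existing mask OR new detections).
#' @export
detect_bad_channels <- function(env, z_thresh = 3.5, cor_thresh = 0.2,
                                cor_high = 0.5) {
  stopifnot(inherits(env, "envelope_matrix"))
  E <- env$env
  nch <- nrow(E)
  if (nch < 8L) stop("bad-channel detection needs at least 8 channels", call. = FALSE)
  log_rms <- log(sqrt(rowMeans(E^2)) + 1e-300)
  med <- median(log_rms)
  s <- mad(log_rms)
  z <- if (s > 0) (log_rms - med) / s else rep(0, nch)

  cc <- channel_coords(env$grid)
  # subsample the envelope for the neighbour-correlation screen
  step <- max(1L, ncol(E) %/% 4000L)
  Es <- E[, seq(1L, ncol(E), by = step), drop = FALSE]
  nb_cor <- vapply(seq_len(nch), function(ch) {
    nb <- which(abs(cc$x - cc$x[ch]) + abs(cc$y - cc$y[ch]) == 1L)
    r <- suppressWarnings(abs(cor(Es[ch, ], t(Es[nb, , drop = FALSE]))))
    r[is.na(r)] <- 0
    max(r)
  }, numeric(1))

  mask <- env$bad_mask |
    (z < -z_thresh) |
    (z > z_thresh & nb_cor < cor_high) |
    (nb_cor < cor_thresh)
  if (mean(mask) > 0.5) {
    stop("more than half of the channels look bad: systemic acquisition failure",
         call. = FALSE)
  }
  mask
}

#' Run the full conditioning chain on a raw recording
#'
#' Band-pass, power-line removal, envelope extraction and bad-channel
#' detection in the standard order.
#'
#' @param rec A raw [emg_recording()].
#' @param f0,n_harmonics Power-line settings, see [remove_powerline()].
#' @return An [envelope_matrix()] with the updated bad-channel mask.
#' @export
preprocess <- function(rec, f0 = 50, n_harmonics = 5L) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$fs <= 900) {
    stop("sampling rate too low: the Nyquist frequency must exceed 450 Hz",
         call. = FALSE)
  }
  # single-transpose fast path through the same steps as
  # bandpass() -> remove_powerline() -> envelope()
  X <- t(rec$data)
  bf <- signal::butter(4, c(20, 450) / (rec$fs / 2), "pass")
  X <- filtfilt_mat(bf, X)
  X <- spectral_interpolate(X, rec$fs, f0, n_harmonics, half_width = 1)
  lf <- signal::butter(4, 1 / (rec$fs / 2), "low")
  E <- filtfilt_mat(lf, abs(X), padlen = min(nrow(X) - 1L, as.integer(rec$fs)))
  E[E < 0] <- 0
  env <- envelope_matrix(t(E), fs = rec$fs, grid = rec$grid,
                         bad_mask = rec$bad_mask,
                         provenance = c(rec$provenance,
                                        "bandpass Butterworth order 4 20-450 Hz, zero phase",
                                        sprintf("spectral interpolation %g Hz x %d harmonics (+/- 1 Hz)",
                                                f0, n_harmonics),
                                        "envelope: |x| -> Butterworth order 4 low-pass 1 Hz, zero phase, clipped at 0"))
  env$bad_mask <- detect_bad_channels(env)
  env
}
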