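#' Multi-channel sEMG recording
#'
#' Container for a monopolar grid recording: a channels x samples matrix,
#' its sampling rate, the grid geometry, a bad-channel mask and free-form
#' task metadata. Channels are ordered as in [channel_coords()].
#'
#' @param data Channels x samples numeric matrix (finite).
#' @param fs Sampling rate, samples/s.
#' @param grid A [grid_layout()]; `nrow(data)` must equal its channel count.
#' @param bad_mask Logical per channel; `TRUE` marks a channel excluded from
#'   downstream maps and statistics.
#' @param meta List of task metadata (joint, movement, position, ...).
#' @param truth Optional ground-truth list (synthetic data only).
#' @param kinematics Optional kinematics list as from [simulate_kinematics()].
#' @param provenance Character vector of processing steps applied so far.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, fs, grid, bad_mask = rep(FALSE, nrow(data)),
                          meta = list(), truth = NULL, kinematics = NULL,
                          provenance = character()) {
  data <- as.matrix(data)
  stopifnot(inherits(grid, "grid_layout"), fs > 0,
            nrow(data) == n_channels(grid),
            length(bad_mask) == nrow(data),
            all(is.finite(data)))
  structure(list(data = data, fs = fs, grid = grid,
                 bad_mask = as.logical(bad_mask), meta = meta,
                 truth = truth, kinematics = kinematics,
                 provenance = provenance),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  grid %d x %d, IED %g mm; %d bad channel(s)\n",
              x$grid$n_cols, x$grid$n_rows, x$grid$ied_mm, sum(x$bad_mask)))
  if (length(x$provenance)) {
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Envelope matrix
#'
#' Nonnegative channels x samples envelope with the filter provenance that
#' produced it.
#'
#' @param env Channels x samples nonnegative matrix.
#' @param fs Sampling rate, samples/s.
#' @param grid A [grid_layout()].
#' @param bad_mask Logical per channel.
#' @param provenance Character vector of filter settings.
#' @return An object of class `envelope_matrix`.
#' @export
envelope_matrix <- function(env, fs, grid, bad_mask = rep(FALSE, nrow(env)),
                            provenance = character()) {
  env <- as.matrix(env)
  stopifnot(all(env >= 0), fs > 0, nrow(env) == n_channels(grid))
  structure(list(env = env, fs = fs, grid = grid,
                 bad_mask = as.logical(bad_mask), provenance = provenance),
            class = "envelope_matrix")
}
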