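#' Electrode grid geometry
#'
#' Describes a rectangular surface-EMG electrode grid. Columns run in the
#' ulnar-radial direction around the forearm (coordinate `x`), rows in the
#' proximal-distal direction (coordinate `y`); both are 1-based electrode
#' indices, so one grid unit equals one inter-electrode distance (IED).
#'
#' @param n_cols Number of circumferential columns (default 14).
#' @param n_rows Number of proximal-distal rows (default 8).
#' @param ied_mm Inter-electrode distance in millimetres (default 15).
#' @return An object of class `grid_layout`.
#' @examples
#' g <- grid_layout()
#' n_channels(g)
#' @export
grid_layout <- function(n_cols = 14L, n_rows = 8L, ied_mm = 15) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  stopifnot(n_cols >= 1L, n_rows >= 1L, ied_mm > 0)
  structure(list(n_cols = n_cols, n_rows = n_rows, ied_mm = ied_mm),
            class = "grid_layout")
}

#' @rdname grid_layout
#' @param grid A `grid_layout`.
#' @export
n_channels <- function(grid) grid$n_cols * grid$n_rows

#' Channel index to electrode coordinate map
#'
#' Channels are numbered column-major: channel 1 is electrode (x = 1, y = 1),
#' channel 2 is (1, 2), ..., channel `n_rows + 1` is (2, 1).
#'
#' @param grid A `grid_layout`.
#' @return A data frame with columns `channel`, `x`, `y`.
#' @export
channel_coords <- function(grid) {
  data.frame(
    channel = seq_len(n_channels(grid)),
    x = rep(seq_len(grid$n_cols), each = grid$n_rows),
    y = rep(seq_len(grid$n_rows), times = grid$n_cols)
  )
}

# (x, y) electrode coordinates -> channel index
coord_to_channel <- function(grid, x, y) {
  stopifnot(all(x >= 1), all(x <= grid$n_cols), all(y >= 1), all(y <= grid$n_rows))
  (as.integer(x) - 1L) * grid$n_rows + as.integer(y)
}

# channel vector -> n_cols x n_rows matrix indexed [x, y]
channel_vector_to_map <- function(values, grid) {
  matrix(values, nrow = grid$n_cols, ncol = grid$n_rows, byrow = TRUE)
}

# n_cols x n_rows map -> channel vector
map_to_channel_vector <- function(map, grid) {
  as.vector(t(map))
}
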