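# Zero-phase IIR filtering of channel matrices.
#
# Forward-backward filtering doubles the effective filter order and cancels
# the phase response; edges are handled scipy-style with odd reflection
# padding and a steady-state initial filter state, so step-like onsets do not
# ring into the data.

# Per-unit-step steady state of a direct-form II transposed filter
# (the companion-matrix construction used by scipy.signal.lfilter_zi).
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

#' Zero-phase (forward-backward) IIR filtering of a channel matrix
#'
#' Applies the filter `filt` (as returned by [signal::butter()]) forward and
#' backward down each column of `x`, giving zero phase distortion and the
#' squared magnitude response of the underlying filter.
#'
#' @param filt A filter object with `$b` and `$a` coefficients, or a list
#'   with elements `b` and `a`.
#' @param x Numeric vector or samples x channels matrix.
#' @param padlen Reflection padding length in samples; defaults to
#'   `3 * (filter order)` capped at `nrow(x) - 1`.
#' @return Filtered data with the shape of `x`.
#' @export
filtfilt_mat <- function(filt, x, padlen = NULL) {
  b <- as.numeric(filt$b %||% filt[["b"]])
  a <- as.numeric(filt$a %||% filt[["a"]])
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  n <- nrow(X)
  ns <- max(length(a), length(b)) - 1L
  if (is.null(padlen)) padlen <- 3L * ns
  padlen <- min(padlen, n - 1L)
  zi <- filter_zi(b, a)
  idx_front <- (padlen + 1L):2L
  idx_back <- (n - 1L):(n - padlen)
  front <- 2 * X[rep(1L, padlen), , drop = FALSE] - X[idx_front, , drop = FALSE]
  back <- 2 * X[rep(n, padlen), , drop = FALSE] - X[idx_back, , drop = FALSE]
  Xp <- rbind(front, X, back)
  Y <- .iir_filter_mat(b, a, Xp, zi)
  Y <- .iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE], zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- Y[(padlen + 1L):(padlen + n), , drop = FALSE]
  if (vec) drop(Y) else Y
}

`%||%` <- function(x, y) if (is.null(x)) y else x
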