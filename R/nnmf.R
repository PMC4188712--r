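# Non-negative matrix factorization of concatenated mean envelopes into
# temporal motor modules and spatial coefficient maps, with module-count
# selection by variance accounted for (VAF).
#
# Notation: M (channels x time) ~ A %*% S, with S the N x time temporal
# modules (unit-maximum rows) and A the channels x N spatial coefficients
# whose columns are mapped over the electrode grid.

#' Concatenate per-task mean envelopes
#'
#' Horizontal concatenation of channels x 500 mean-envelope matrices in a
#' fixed, recorded task order; block boundaries are retained so per-task
#' maps can be extracted later.
#'
#' @param mean_envs Named list of channels x n matrices sharing the channel
#'   set (bad channels removed identically).
#' @return Channels x total-columns matrix with attributes `tasks` and
#'   `block_starts`/`block_ends`.
#' @export
concatenate_tasks <- function(mean_envs) {
  stopifnot(length(mean_envs) >= 1L)
  nchs <- vapply(mean_envs, nrow, integer(1))
  if (length(unique(nchs)) != 1L) {
    stop("mean envelopes have mismatched channel sets", call. = FALSE)
  }
  M <- do.call(cbind, mean_envs)
  widths <- vapply(mean_envs, ncol, integer(1))
  ends <- cumsum(widths)
  attr(M, "tasks") <- names(mean_envs) %||% as.character(seq_along(mean_envs))
  attr(M, "block_starts") <- c(1L, head(ends, -1L) + 1L)
  attr(M, "block_ends") <- ends
  M
}

#' Extract one task's column block from a concatenated matrix
#'
#' @param M Matrix from [concatenate_tasks()].
#' @param task Task name or index.
#' @return The original channels x n matrix of that task.
#' @export
task_block <- function(M, task) {
  tasks <- attr(M, "tasks")
  k <- if (is.character(task)) match(task, tasks) else as.integer(task)
  if (is.na(k) || k < 1L || k > length(tasks)) stop("unknown task", call. = FALSE)
  M[, attr(M, "block_starts")[k]:attr(M, "block_ends")[k], drop = FALSE]
}

# One multiplicative-update NMF run (Lee-Seung, Euclidean loss).
nmf_run <- function(M, N, max_iter = 400L, tol = 1e-6, init = NULL) {
  m <- nrow(M)
  n <- ncol(M)
  if (!is.null(init)) {
    A <- init$A
    S <- init$S
  } else {
    scale <- sqrt(mean(M) / N)
    A <- matrix(runif(m * N, 0.1, 1), m, N) * scale
    S <- matrix(runif(N * n, 0.1, 1), N, n) * scale
  }
  eps <- 1e-12
  sse_old <- Inf
  for (it in seq_len(max_iter)) {
    S <- S * (crossprod(A, M)) / (crossprod(A) %*% S + eps)
    A <- A * (M %*% t(S)) / (A %*% tcrossprod(S) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      sse <- sum((M - A %*% S)^2)
      if (is.finite(sse_old) && (sse_old - sse) < tol * max(sse_old, eps)) break
      sse_old <- sse
    }
  }
  list(A = A, S = S, sse = sum((M - A %*% S)^2))
}

#' Fit NNMF with random restarts
#'
#' Minimizes `||M - A S||_F^2` by multiplicative updates from `n_restarts`
#' random nonnegative initializations and keeps the restart with the lowest
#' squared error. The scale indeterminacy is fixed by rescaling each
#' temporal module (row of S) to unit maximum, with the inverse scale pushed
#' into the spatial coefficients A.
#'
#' @param M Nonnegative channels x time matrix (rows with only zeros are
#'   not allowed among kept channels).
#' @param N Number of modules, `1 <= N <= min(dim(M))`.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Master seed; one restart seed is spawned per restart.
#' @param max_iter,tol Multiplicative-update stopping rule.
#' @param init Optional explicit initialization (list with nonnegative `A`,
#'   `S`); when given, a single run from this initialization replaces the
#'   random restarts.
#' @return A `module_decomposition`: list with `A`, `S`, `N`, `sse`, `sst`,
#'   `vaf`, `n_restarts`, `best_restart`, `restart_sse` (per-restart SSE).
#' @export
fit_nnmf <- function(M, N, n_restarts = 100L, seed = 1L,
                     max_iter = 400L, tol = 1e-6, init = NULL) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be nonnegative", call. = FALSE)
  if (N < 1L || N > min(dim(M))) stop("module count N out of range", call. = FALSE)
  if (!is.null(init)) {
    best <- nmf_run(M, N, max_iter, tol, init = init)
    best$restart <- 1L
    n_restarts <- 1L
    restart_sse <- best$sse
  } else {
    restart_seeds <- spawn_seeds(seed, n_restarts)
    best <- NULL
    restart_sse <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(restart_seeds[r], nmf_run(M, N, max_iter, tol))
      restart_sse[r] <- fit$sse
      if (is.null(best) || fit$sse < best$sse) {
        best <- fit
        best$restart <- r
      }
    }
  }
  # unit-max temporal modules; inverse scale into A
  smax <- apply(best$S, 1L, max)
  smax[smax == 0] <- 1
  S <- best$S / smax
  A <- best$A * rep(smax, each = nrow(best$A))
  sst <- sum(M^2)
  structure(list(A = A, S = S, N = as.integer(N), sse = best$sse, sst = sst,
                 vaf = 1 - best$sse / sst, n_restarts = n_restarts,
                 best_restart = best$restart, restart_sse = restart_sse,
                 seed = seed,
                 tasks = attr(M, "tasks"),
                 block_starts = attr(M, "block_starts"),
                 block_ends = attr(M, "block_ends")),
            class = "module_decomposition")
}

#' Variance accounted for by a factorization
#'
#' `VAF = 1 - SSE/SST` with `SSE = sum((M - A S)^2)` and the uncentered
#' total sum of squares `SST = sum(M^2)`, the usual convention in the
#' muscle-synergy literature.
#'
#' @param M Data matrix.
#' @param A,S Factor matrices.
#' @return Scalar VAF.
#' @export
vaf <- function(M, A, S) {
  sst <- sum(M^2)
  if (sst == 0) stop("SST is zero", call. = FALSE)
  1 - sum((M - A %*% S)^2) / sst
}

#' Select the number of modules by the VAF criterion
#'
#' Fits NNMF for increasing N and selects the least number of modules whose
#' VAF reaches `vaf_threshold`. With `early_stop = TRUE` (default) fitting
#' stops at the first qualifying N; otherwise the whole range is fitted and
#' the full VAF curve returned.
#'
#' @param M Nonnegative data matrix.
#' @param n_range Candidate module counts (default `1:10`).
#' @param vaf_threshold VAF criterion (default 0.90).
#' @param n_restarts,seed,... Passed to [fit_nnmf()].
#' @param early_stop Stop fitting once the criterion is met.
#' @return List with `N` (selected count), `vaf_curve` (named by N over the
#'   fitted range), `fits` (the `module_decomposition` per fitted N) and
#'   `threshold_met` (FALSE when no N qualifies; the arg-max is then
#'   returned with a warning).
#' @export
select_module_count <- function(M, n_range = 1:10, vaf_threshold = 0.90,
                                n_restarts = 100L, seed = 1L,
                                early_stop = TRUE, ...) {
  n_range <- sort(unique(as.integer(n_range)))
  fit_seeds <- spawn_seeds(seed, length(n_range))
  vafs <- numeric(0)
  fits <- list()
  for (i in seq_along(n_range)) {
    N <- n_range[i]
    fit <- fit_nnmf(M, N, n_restarts = n_restarts, seed = fit_seeds[i], ...)
    fits[[as.character(N)]] <- fit
    vafs[as.character(N)] <- fit$vaf
    if (early_stop && fit$vaf >= vaf_threshold) break
  }
  qual <- which(vafs >= vaf_threshold)
  if (length(qual)) {
    N_star <- n_range[qual[1L]]
    met <- TRUE
  } else {
    N_star <- n_range[which.max(vafs)]
    met <- FALSE
    warning("no module count reached the VAF threshold; returning the arg-max",
            call. = FALSE)
  }
  list(N = N_star, vaf_curve = vafs, fits = fits, threshold_met = met)
}

#' Similarity links between two module sets
#'
#' Pearson correlation between every pair of temporal modules across two
#' decompositions (e.g. with N and N+1 modules); pairs with `r` above the
#' threshold are linked.
#'
#' @param S_a,S_b Module x time matrices sharing the time axis.
#' @param threshold Correlation threshold (default 0.7).
#' @return List with `links` (data frame `module_a`, `module_b`, `r`) and
#'   the full correlation matrix `r_matrix`. Constant modules are excluded
#'   with a warning.
#' @export
module_similarity <- function(S_a, S_b, threshold = 0.7) {
  stopifnot(ncol(S_a) == ncol(S_b))
  const_a <- apply(S_a, 1L, sd) == 0
  const_b <- apply(S_b, 1L, sd) == 0
  if (any(const_a) || any(const_b)) {
    warning("constant module(s) excluded from similarity analysis", call. = FALSE)
  }
  R <- matrix(NA_real_, nrow(S_a), nrow(S_b))
  ok_a <- which(!const_a)
  ok_b <- which(!const_b)
  if (length(ok_a) && length(ok_b)) {
    R[ok_a, ok_b] <- cor(t(S_a[ok_a, , drop = FALSE]),
                         t(S_b[ok_b, , drop = FALSE]))
  }
  idx <- which(!is.na(R) & R > threshold, arr.ind = TRUE)
  links <- data.frame(module_a = idx[, 1L], module_b = idx[, 2L],
                      r = R[idx])
  links <- links[order(links$module_a, links$module_b), , drop = FALSE]
  rownames(links) <- NULL
  list(links = links, r_matrix = R)
}

#' Match modules across two decompositions
#'
#' Greedy one-to-one assignment by decreasing temporal correlation; only
#' pairs with `r > threshold` are matched.
#'
#' @param S_a,S_b Module x time matrices.
#' @param threshold Minimum correlation (default 0.7).
#' @return Data frame `module_a`, `module_b`, `r` (possibly empty).
#' @export
match_modules <- function(S_a, S_b, threshold = 0.7) {
  sim <- suppressWarnings(module_similarity(S_a, S_b, threshold = -1))
  R <- sim$r_matrix
  out <- data.frame(module_a = integer(0), module_b = integer(0), r = numeric(0))
  repeat {
    if (all(is.na(R))) break
    best <- which(R == max(R, na.rm = TRUE), arr.ind = TRUE)[1L, , drop = FALSE]
    r <- R[best]
    if (is.na(r) || r <= threshold) break
    out <- rbind(out, data.frame(module_a = best[1L], module_b = best[2L], r = r))
    R[best[1L], ] <- NA
    R[, best[2L]] <- NA
  }
  out[order(out$module_a), , drop = FALSE]
}
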