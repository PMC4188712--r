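# Joint-angle reconstruction from monopolar envelope subsets.
#
# A single-hidden-layer perceptron (6 tanh units, linear output) maps the
# instantaneous envelopes of a chosen electrode subset to the joint angle.
# Training minimizes the squared error with Levenberg-Marquardt (analytic
# Jacobian) and early-stops on a held-out validation share of the training
# cycles. Performance is the coefficient of determination r^2 under
# cycle-wise four-fold cross-validation, and subsets (full proximal ring vs
# COG-targeted electrodes) are compared with one-way ANOVA plus the
# Student-Newman-Keuls post-hoc.

#' Select an electrode subset for angle reconstruction
#'
#' `"ring"` selects one full row of electrodes at the most proximal grid row
#' (y = 1, the ring closest to the elbow crease). `"cog"` selects, for each
#' activity cluster, the unmasked electrode nearest to the cluster COG (ties
#' broken toward lower x, then lower y); duplicates are collapsed.
#'
#' @param grid A [grid_layout()].
#' @param kind `"ring"` or `"cog"`.
#' @param clusters List of `activity_cluster` objects (required for
#'   `"cog"`).
#' @param bad_mask Logical per channel; masked electrodes are never
#'   selected.
#' @return An `electrode_subset`: list with `kind`, `members` (matrix with
#'   columns `x`, `y`), `channels` (channel indices).
#' @export
select_subset <- function(grid, kind = c("ring", "cog"), clusters = NULL,
                          bad_mask = rep(FALSE, n_channels(grid))) {
  kind <- match.arg(kind)
  cc <- channel_coords(grid)
  if (kind == "ring") {
    sel <- cc$y == 1L & !bad_mask
    members <- cbind(x = cc$x[sel], y = cc$y[sel])
  } else {
    if (is.null(clusters) || !length(clusters)) {
      stop("no activity clusters available for the COG subset", call. = FALSE)
    }
    avail <- cc[!bad_mask, , drop = FALSE]
    pick <- vapply(clusters, function(cl) {
      g <- cog(cl)
      d2 <- (avail$x - g[["x"]])^2 + (avail$y - g[["y"]])^2
      cand <- which(d2 == min(d2))
      cand <- cand[order(avail$x[cand], avail$y[cand])][1L]
      avail$channel[cand]
    }, integer(1))
    pick <- unique(pick)
    members <- cbind(x = cc$x[pick], y = cc$y[pick])
  }
  structure(list(kind = kind, members = members,
                 channels = coord_to_channel(grid, members[, 1L], members[, 2L])),
            class = "electrode_subset")
}

# ---- MLP internals ---------------------------------------------------------

mlp_unpack <- function(par, p, h) {
  W1 <- matrix(par[seq_len(p * h)], h, p)
  b1 <- par[p * h + seq_len(h)]
  w2 <- par[p * h + h + seq_len(h)]
  b2 <- par[p * h + 2 * h + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(par, X, h) {
  p <- ncol(X)
  th <- mlp_unpack(par, p, h)
  H <- tanh(X %*% t(th$W1) + rep(th$b1, each = nrow(X)))
  list(yhat = drop(H %*% th$w2) + th$b2, H = H, th = th)
}

mlp_jacobian <- function(par, X, h) {
  fw <- mlp_forward(par, X, h)
  n <- nrow(X)
  p <- ncol(X)
  D <- (1 - fw$H^2) * rep(fw$th$w2, each = n)  # n x h
  J <- matrix(0, n, length(par))
  # W1 is unpacked column-major as matrix(h, p): par (k-1)*h + j <-> W1[j, k]
  for (k in seq_len(p)) {
    J[, (k - 1L) * h + seq_len(h)] <- D * X[, k]
  }
  J[, p * h + seq_len(h)] <- D
  J[, p * h + h + seq_len(h)] <- fw$H
  J[, p * h + 2 * h + 1L] <- 1
  J
}

#' Train a joint-angle MLP on envelope inputs
#'
#' Single hidden layer of `hidden` tanh units with a linear output, trained
#' by Levenberg-Marquardt (via [minpack.lm::nls.lm()], analytic Jacobian) in
#' short bursts with early stopping on the validation split: 70% of the
#' training cycles are used for weight updates and 30% for validation, and
#' the weights with the lowest validation error are kept. Inputs are
#' z-scored with statistics from the training split only.
#'
#' @param X Samples x channels envelope matrix.
#' @param y Joint angle per sample, degrees.
#' @param cycle_id Integer cycle label per sample (used for the 70/30
#'   train/validation split by cycle).
#' @param hidden Hidden units (default 6).
#' @param seed Seed for the weight initialization and cycle split.
#' @param max_rounds,iter_per_round Early-stopping schedule.
#' @return An `mlp_model` with `predict` support via [predict_mlp()].
#' @export
train_mlp <- function(X, y, cycle_id = rep(1L, length(y)), hidden = 6L,
                      seed = 1L, max_rounds = 15L, iter_per_round = 10L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite training inputs", call. = FALSE)
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  sdev[sdev == 0] <- 1
  Xz <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  p <- ncol(Xz)
  h <- as.integer(hidden)

  cyc <- unique(cycle_id)
  split <- with_seed(seed, {
    ord <- sample(cyc)
    n_tr <- max(1L, round(0.7 * length(cyc)))
    list(train = ord[seq_len(n_tr)],
         val = if (length(cyc) > n_tr) ord[(n_tr + 1L):length(cyc)] else ord[seq_len(n_tr)])
  })
  tr <- cycle_id %in% split$train
  va <- cycle_id %in% split$val

  npar <- p * h + 2L * h + 1L
  par <- with_seed(seed + 1L, runif(npar, -0.5, 0.5) / sqrt(p))
  resid_fn <- function(pp) y[tr] - mlp_forward(pp, Xz[tr, , drop = FALSE], h)$yhat
  jac_fn <- function(pp) -mlp_jacobian(pp, Xz[tr, , drop = FALSE], h)

  best_par <- par
  best_val <- sum((y[va] - mlp_forward(par, Xz[va, , drop = FALSE], h)$yhat)^2)
  stall <- 0L
  for (round in seq_len(max_rounds)) {
    # hitting maxiter is the normal exit of one burst, not a failure
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iter_per_round, ptol = 1e-10,
                           ftol = 1e-10)))
    par <- coef(fit)
    val_sse <- sum((y[va] - mlp_forward(par, Xz[va, , drop = FALSE], h)$yhat)^2)
    if (val_sse < best_val - 1e-12) {
      best_val <- val_sse
      best_par <- par
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 3L) break
    }
  }
  structure(list(par = best_par, hidden = h, mu = mu, sd = sdev,
                 optimizer = "Levenberg-Marquardt (minpack.lm::nls.lm)",
                 seed = seed, val_sse = best_val),
            class = "mlp_model")
}

#' Predict joint angles from a trained MLP
#'
#' @param model An `mlp_model` from [train_mlp()].
#' @param X Samples x channels envelope matrix.
#' @return Numeric vector of predicted angles.
#' @export
predict_mlp <- function(model, X) {
  Xz <- sweep(sweep(as.matrix(X), 2L, model$mu), 2L, model$sd, "/")
  mlp_forward(model$par, Xz, model$hidden)$yhat
}

#' Coefficient of determination
#'
#' `r^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Scalar (at most 1; negative when worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant target: r^2 undefined", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Cycle-wise four-fold cross-validated angle reconstruction
#'
#' Cycles are partitioned into `folds` folds; for each fold an MLP is
#' trained on the remaining cycles (with an internal 70/30 train/validation
#' split) and evaluated by r^2 on the held-out fold.
#'
#' @param X Samples x channels envelope matrix.
#' @param y Joint angle per sample.
#' @param cycle_id Cycle label per sample (>= 8 distinct cycles).
#' @param folds Number of folds (default 4).
#' @param seed Seed for fold assignment and training.
#' @param ... Passed to [train_mlp()].
#' @return List with `r2` (per fold), `mean`, `sd`, `folds`.
#' @export
crossval_r2 <- function(X, y, cycle_id, folds = 4L, seed = 1L, ...) {
  if (sd(y) == 0) stop("constant angle", call. = FALSE)
  cyc <- unique(cycle_id)
  if (length(cyc) < 2L * folds) {
    stop("need at least ", 2L * folds, " cycles for cycle-wise folding",
         call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    ord <- sample(cyc)
    stats::setNames(rep(seq_len(folds), length.out = length(ord)),
                    as.character(ord))
  })
  fold_id <- fold_of[as.character(cycle_id)]
  r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    model <- train_mlp(X[!te, , drop = FALSE], y[!te], cycle_id[!te],
                       seed = seed + f, ...)
    r2[f] <- r_squared(y[te], predict_mlp(model, X[te, , drop = FALSE]))
  }
  list(r2 = r2, mean = mean(r2), sd = sd(r2), folds = folds)
}

#' Compare electrode subsets: one-way ANOVA + Student-Newman-Keuls
#'
#' One-way ANOVA on cross-validated r^2 values grouped by subset kind,
#' followed by the stepwise Student-Newman-Keuls procedure on the ordered
#' group means (studentized-range critical values at each stretch size).
#'
#' @param ... Named numeric vectors of r^2 values, one per subset kind
#'   (at least two), or a single named list.
#' @param alpha Significance level (default 0.05).
#' @return List with `anova` (`F`, `p`, dfs), `snk` (data frame of pairwise
#'   decisions) and `group_means`.
#' @export
compare_subsets <- function(..., alpha = 0.05) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]]) && is.null(dim(groups[[1L]]))) {
    groups <- groups[[1L]]
  }
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1L]]
  F_val <- tab[["F value"]][1L]
  p_val <- tab[["Pr(>F)"]][1L]
  mse <- tab[["Mean Sq"]][2L]
  df_err <- tab[["Df"]][2L]
  snk <- snk_test(groups, mse = mse, df_err = df_err, alpha = alpha)
  list(anova = list(F = F_val, p = p_val, df1 = tab[["Df"]][1L], df2 = df_err),
       snk = snk,
       group_means = vapply(groups, mean, numeric(1)))
}

# Student-Newman-Keuls stepwise procedure on ordered group means.
# Pairs spanning a stretch of p ordered means are tested against the
# studentized range quantile q(1 - alpha, p, df); a non-significant stretch
# protects all pairs inside it.
snk_test <- function(groups, mse, df_err, alpha = 0.05) {
  means <- sort(vapply(groups, mean, numeric(1)))
  k <- length(means)
  ns <- vapply(groups, length, integer(1))[names(means)]
  out <- data.frame(group_a = character(0), group_b = character(0),
                    diff = numeric(0), q = numeric(0), q_crit = numeric(0),
                    significant = logical(0))
  protected <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      ni <- ns[i]
      nj <- ns[j]
      se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
      q_stat <- (means[j] - means[i]) / se
      q_crit <- ptukey_inv(1 - alpha, span, df_err)
      sig <- !protected[i, j] && q_stat > q_crit
      if (!sig) {
        protected[i:j, i:j] <- TRUE  # all sub-stretches accepted as equal
      }
      out <- rbind(out, data.frame(group_a = names(means)[i],
                                   group_b = names(means)[j],
                                   diff = means[j] - means[i],
                                   q = q_stat, q_crit = q_crit,
                                   significant = sig))
    }
  }
  rownames(out) <- NULL
  out
}

ptukey_inv <- function(p, nmeans, df) {
  stats::qtukey(p, nmeans, df)
}
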