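# Electrode-subset selection, MLP angle regression, cross-validated r^2 and
# the ANOVA + Student-Newman-Keuls subset comparison.

test_that("subset selection is deterministic and respects masks", {
  g <- grid_layout()
  ring <- select_subset(g, "ring")
  expect_equal(nrow(ring$members), 14)
  expect_true(all(ring$members[, "y"] == 1))
  # COG exactly on an electrode picks that electrode
  cl <- activity_cluster(cbind(6, 4), 1)
  s <- select_subset(g, "cog", clusters = list(cl))
  expect_equal(unname(s$members[1, ]), c(6, 4))
  # off-electrode COG picks the brute-force nearest electrode
  cl2 <- activity_cluster(rbind(c(6, 3), c(6, 4), c(7, 4)), c(0.2, 1, 0.55))
  g_cog <- cog(cl2)
  cc <- channel_coords(g)
  d2 <- (cc$x - g_cog["x"])^2 + (cc$y - g_cog["y"])^2
  nearest <- cc[which.min(d2), ]
  s2 <- select_subset(g, "cog", clusters = list(cl2))
  expect_equal(unname(s2$members[1, ]), c(nearest$x, nearest$y))
  # duplicates collapse; masked electrodes are skipped
  s3 <- select_subset(g, "cog", clusters = list(cl, cl))
  expect_equal(nrow(s3$members), 1)
  mask <- rep(FALSE, n_channels(g))
  mask[emgmap:::coord_to_channel(g, 6, 4)] <- TRUE
  s4 <- select_subset(g, "cog", clusters = list(cl), bad_mask = mask)
  expect_false(all(s4$members[1, ] == c(6, 4)))
  expect_error(select_subset(g, "cog", clusters = list()), "no activity")
})

test_that("the MLP represents linear and smooth nonlinear targets", {
  set.seed(14)
  n <- 600
  X <- matrix(runif(n * 3, -1, 1), n, 3)
  cyc <- rep(1:10, each = n / 10)
  # linear target: representable exactly
  y_lin <- 2 * X[, 1] - 3 * X[, 2] + 0.5
  m <- train_mlp(X, y_lin, cyc, seed = 1)
  expect_gt(r_squared(y_lin, predict_mlp(m, X)), 0.999)
  # tanh of one channel: representable nonlinearity
  y_tanh <- tanh(2 * X[, 3])
  m2 <- train_mlp(X, y_tanh, cyc, seed = 2)
  expect_gt(r_squared(y_tanh, predict_mlp(m2, X)), 0.95)
  # shuffled target: no generalization
  y_shuf <- sample(y_lin)
  m3 <- train_mlp(X[cyc <= 7, ], y_shuf[cyc <= 7], cyc[cyc <= 7], seed = 3)
  expect_lt(r_squared(y_shuf[cyc > 7], predict_mlp(m3, X[cyc > 7, ])), 0.2)
  expect_error(train_mlp(X * NA, y_lin, cyc), "non-finite")
})

test_that("r^2 follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("cycle-wise cross-validation recovers a representable mapping", {
  set.seed(15)
  n <- 960
  cyc <- rep(1:12, each = n / 12)
  phase <- rep(seq(0, 2 * pi, length.out = n / 12), 12)
  X <- cbind(sin(phase), cos(phase)) + matrix(rnorm(2 * n, 0, 0.01), n, 2)
  y <- 10 * sin(phase) + 3
  res <- crossval_r2(X, y, cyc, folds = 4, seed = 4)
  expect_length(res$r2, 4)
  expect_gt(res$mean, 0.95)
  expect_error(crossval_r2(X, rep(1, n), cyc), "constant")
  expect_error(crossval_r2(X, y, rep(1:4, each = n / 4)), "at least 8")
})

test_that("ANOVA + SNK separate distinct groups and accept equal ones", {
  set.seed(16)
  # identical groups
  a <- rnorm(8, 0, 0.1)
  res <- compare_subsets(g1 = a, g2 = a)
  expect_gt(res$anova$p, 0.99)
  expect_false(any(res$snk$significant))
  # means 0 vs 5, sd 0.1: decisive
  res2 <- compare_subsets(g1 = rnorm(8, 0, 0.1), g2 = rnorm(8, 5, 0.1))
  expect_lt(res2$anova$p, 1e-6)
  expect_true(all(res2$snk$significant))
  expect_error(compare_subsets(g1 = a), "at least 2")
})

test_that("SNK family-wise error on equal means is near the nominal level", {
  set.seed(17)
  n_sim <- 2000
  fw <- 0
  for (i in seq_len(n_sim)) {
    res <- compare_subsets(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    if (any(res$snk$significant)) fw <- fw + 1
  }
  expect_gt(fw / n_sim, 0.02)
  expect_lt(fw / n_sim, 0.09)
})
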