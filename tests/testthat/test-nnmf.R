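# NNMF: task concatenation, factorization quality, VAF, module-count
# selection and module-set similarity.

test_that("task concatenation records invertible block boundaries", {
  set.seed(1)
  blocks <- list(a = matrix(runif(12), 3), b = matrix(runif(30), 3),
                 c = matrix(runif(15), 3))
  M <- concatenate_tasks(blocks)
  expect_equal(ncol(M), 4 + 10 + 5)
  expect_identical(task_block(M, "b"), blocks$b)
  expect_identical(task_block(M, 3), blocks$c)
  # 14 tasks x 500 -> 7000 columns
  many <- replicate(14, matrix(runif(2 * 500), 2), simplify = FALSE)
  expect_equal(ncol(concatenate_tasks(many)), 7000)
  expect_error(concatenate_tasks(list(matrix(1, 2, 2), matrix(1, 3, 2))),
               "mismatched")
})

test_that("exact low-rank structure is recovered", {
  set.seed(2)
  # rank-1: near-perfect fit at N = 1
  M1 <- outer(runif(8, 0.5, 2), runif(30, 0.5, 2))
  f1 <- fit_nnmf(M1, 1, n_restarts = 5, seed = 1)
  expect_lt(f1$sse / f1$sst, 1e-6)
  # planted rank-3: VAF > 0.999 at N = 3
  A0 <- matrix(runif(10 * 3), 10, 3)
  S0 <- matrix(runif(3 * 60), 3, 60)
  f3 <- fit_nnmf(A0 %*% S0, 3, n_restarts = 20, seed = 2, max_iter = 2000,
                 tol = 1e-10)
  expect_gt(f3$vaf, 0.999)
  # factor constraints
  expect_true(all(f3$A >= 0) && all(f3$S >= 0))
  expect_equal(unname(apply(f3$S, 1, max)), rep(1, 3))
  expect_error(fit_nnmf(M1, 0), "out of range")
  expect_error(fit_nnmf(-M1, 1), "nonnegative")
})

test_that("updates are equivariant to channel permutation given matched init", {
  set.seed(3)
  M <- matrix(runif(8 * 30), 8, 30) + outer(runif(8), runif(30))
  p <- sample(8)
  init <- list(A = matrix(runif(8 * 2, 0.2, 1), 8, 2),
               S = matrix(runif(2 * 30, 0.2, 1), 2, 30))
  initp <- list(A = init$A[p, , drop = FALSE], S = init$S)
  f <- fit_nnmf(M, 2, init = init)
  fp <- fit_nnmf(M[p, ], 2, init = initp)
  expect_equal(fp$A, f$A[p, ], tolerance = 1e-9)
  expect_equal(fp$S, f$S, tolerance = 1e-9)
})

test_that("VAF definition and hand-worked example", {
  M <- matrix(c(1, 3, 2, 4), 2)          # [[1,2],[3,4]] row-wise
  A <- matrix(c(1, 3), 2)                # reconstruction [[1,2],[3,0]]
  S <- matrix(c(1, 2), 1)
  R <- matrix(c(1, 3, 2, 0), 2)
  expect_equal(sum((M - R)^2), 16)
  expect_equal(1 - 16 / sum(M^2), 1 - 16 / 30)
  expect_equal(vaf(M, R, diag(2)), 1 - 16 / 30, tolerance = 1e-12)
  # perfect reconstruction and zero reconstruction
  expect_equal(vaf(M, M, diag(2)), 1)
  expect_equal(vaf(M, 0 * M, diag(2)), 0)
  expect_error(vaf(0 * M, A, S), "zero")
})

test_that("module count selection applies the 90% VAF rule", {
  set.seed(4)
  A0 <- cbind(c(4, 4, 0.2, 0.2, 0.1, 0.1), c(0.1, 0.2, 4, 4, 0.2, 0.1),
              c(0.1, 0.1, 0.3, 0.2, 4, 4))
  S0 <- rbind(phase_bump(0.2, 0.08, 60), phase_bump(0.5, 0.08, 60),
              phase_bump(0.8, 0.08, 60))
  M <- A0 %*% S0 + matrix(runif(6 * 60, 0, 0.05), 6, 60)
  sel <- select_module_count(M, n_range = 1:6, n_restarts = 10, seed = 5)
  expect_equal(sel$N, 3)
  expect_true(sel$threshold_met)
  # VAF(1) already >= 0.9 selects 1
  M1 <- outer(runif(6, 1, 2), runif(60, 1, 2))
  expect_equal(select_module_count(M1, n_range = 1:3, n_restarts = 5,
                                   seed = 6)$N, 1)
})

test_that("VAF is monotone in N and best-of-restarts improves monotonically", {
  set.seed(7)
  M <- matrix(runif(10 * 50), 10, 50) +
    outer(runif(10), runif(50)) + outer(runif(10), runif(50))
  expect_warning(
    sel <- select_module_count(M, n_range = 1:5, n_restarts = 10, seed = 8,
                               vaf_threshold = 2, early_stop = FALSE,
                               max_iter = 1000, tol = 1e-9),
    "arg-max")
  vafs <- unname(sel$vaf_curve)
  expect_true(all(diff(vafs) > -1e-6))
  # reconstruction nonnegative
  f <- sel$fits[["3"]]
  expect_true(all(f$A %*% f$S >= 0))
  # running best SSE never increases with more restarts
  running <- cummin(f$restart_sse)
  expect_true(all(diff(running) <= 0))
})

test_that("module similarity links preserved modules across set sizes", {
  S_N <- rbind(phase_bump(0.3, 0.1, 200), phase_bump(0.7, 0.1, 200))
  S_N1 <- rbind(S_N, phase_bump(0.5, 0.05, 200))
  sim <- module_similarity(S_N, S_N1)
  # every module of the smaller set is linked to itself with r = 1
  self <- sim$links[sim$links$module_a == sim$links$module_b, ]
  expect_equal(nrow(self), 2)
  expect_true(all(abs(self$r - 1) < 1e-12))
  # planted preserved modules + one new -> exactly N links
  expect_equal(nrow(sim$links), 2)
  # independent noise modules: no links
  set.seed(9)
  a <- matrix(rnorm(3 * 500), 3)
  b <- matrix(rnorm(4 * 500), 4)
  expect_equal(nrow(module_similarity(abs(a), abs(b))$links), 0)
  # constant module excluded with warning
  expect_warning(module_similarity(rbind(rep(1, 200), phase_bump(0.5, 0.1, 200)),
                                   S_N), "constant")
})

test_that("module matching is one-to-one and threshold-guarded", {
  S1 <- rbind(phase_bump(0.25, 0.1, 100), phase_bump(0.75, 0.1, 100))
  S2 <- S1[c(2, 1), ]
  m <- match_modules(S1, S2)
  expect_equal(m$module_b[m$module_a == 1], 2)
  expect_equal(m$module_b[m$module_a == 2], 1)
  expect_true(all(m$r > 0.99))
})
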