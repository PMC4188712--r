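# Watershed segmentation of coefficient maps, activity clusters, COG,
# overlap, displacement, barycenter weights and the COG position test.

test_that("unimodal maps give one cluster containing the peak electrode", {
  map <- gaussian_map(7.3, 4.6, sigma = 1)
  cl <- segment_map(map)
  expect_length(cl, 1)
  peak <- which(map == max(map), arr.ind = TRUE)
  keys <- paste(cl[[1]]$electrodes[, 1], cl[[1]]$electrodes[, 2])
  expect_true(paste(peak[1], peak[2]) %in% keys)
})

test_that("well-separated bumps segment into distinct clusters", {
  map <- gaussian_map(4, 4, 1) + gaussian_map(10, 4, 1)
  cl <- segment_map(map)
  expect_length(cl, 2)
  xs <- sort(vapply(cl, function(c) unname(cog(c)["x"]), numeric(1)))
  expect_equal(xs, c(4, 10), tolerance = 0.3)
  # clusters from one map are pairwise disjoint
  k1 <- paste(cl[[1]]$electrodes[, 1], cl[[1]]$electrodes[, 2])
  k2 <- paste(cl[[2]]$electrodes[, 1], cl[[2]]$electrodes[, 2])
  expect_length(intersect(k1, k2), 0)
})

test_that("the 70% membership rule keeps only near-peak electrodes", {
  map <- matrix(0, 14, 8)
  map[5:6, 4] <- 100
  map[7, 4] <- 60
  map[4, 4] <- 60
  cl <- segment_map(map)
  expect_length(cl, 1)
  expect_setequal(paste(cl[[1]]$electrodes[, 1], cl[[1]]$electrodes[, 2]),
                  c("5 4", "6 4"))
  # all member weights >= 0.7 * cluster max
  expect_true(all(cl[[1]]$weights >= 0.7 * max(cl[[1]]$weights)))
})

test_that("low-amplitude watershed regions are discarded as noise", {
  map <- gaussian_map(4, 4, 1)
  map[12, 7] <- 0.05  # isolated speck below the 10% floor
  cl <- segment_map(map)
  expect_length(cl, 1)
  expect_warning(out <- segment_map(matrix(0, 14, 8)), "all-zero")
  expect_length(out, 0)
})

test_that("COG matches the weighted-mean definition", {
  # single electrode
  c1 <- activity_cluster(cbind(5, 3), 2)
  expect_equal(unname(cog(c1)), c(5, 3))
  # hand example: (1,1) weight 1 and (3,1) weight 3
  c2 <- activity_cluster(rbind(c(1, 1), c(3, 1)), c(1, 3))
  expect_equal(unname(cog(c2)), c(2.5, 1))
  # symmetric weights about column 7
  c3 <- activity_cluster(rbind(c(5, 2), c(9, 2), c(6, 5), c(8, 5)),
                         c(2, 2, 1, 1))
  expect_equal(unname(cog(c3)["x"]), 7)
  # random clusters against the loop oracle
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    el <- cbind(sample(1:14, n, replace = TRUE), sample(1:8, n, replace = TRUE))
    w <- runif(n)
    expect_equal(unname(cog(activity_cluster(el, w))), brute_cog(el, w),
                 tolerance = 1e-12)
  }
})

test_that("overlap percentages follow both normalizations and are symmetric", {
  mk <- function(xs) activity_cluster(cbind(xs, 1), rep(1, length(xs)))
  a <- mk(1:4)
  b <- mk(3:8)
  expect_equal(unname(overlap(a, b)), c(100 * 2 / 4, 100 * 2 / 6),
               tolerance = 1e-12)
  expect_equal(overlap(a, b), overlap(b, a))
  expect_equal(unname(overlap(a, a)), c(100, 100))
  expect_equal(unname(overlap(a, mk(9:12))), c(0, 0))
  ov <- overlap(a, b)
  expect_lte(ov["pct_vs_largest"], ov["pct_vs_smallest"])
})

test_that("COG displacement is a coordinate difference in IED units", {
  a <- activity_cluster(cbind(5, 3), 1)
  b <- activity_cluster(cbind(5, 3), 1)
  expect_equal(cog_shift(a, b), 0)
  c2 <- activity_cluster(rbind(c(5, 3), c(7, 3)), c(0.6, 1))  # x = 6.25
  expect_equal(cog_shift(a, c2, axis = "x"), 1.25, tolerance = 1e-12)
  expect_equal(cog_shift(a, c2, axis = "euclidean"), 1.25, tolerance = 1e-12)
})

test_that("planted-source COG is recovered on noise-free maps", {
  set.seed(12)
  for (i in 1:10) {
    cx <- runif(1, 3, 12)
    cy <- runif(1, 2.5, 6.5)
    cl <- segment_map(gaussian_map(cx, cy, 1))
    expect_length(cl, 1)
    expect_lt(sqrt(sum((cog(cl[[1]]) - c(cx, cy))^2)), 0.3)
  }
})

test_that("barycenter weight uses bilinear interpolation", {
  map <- matrix(0, 14, 8)
  map[5, 3] <- 40
  map[6, 3] <- 60
  expect_equal(barycenter_weight(map, c(5.5, 3)), 50)
  expect_equal(barycenter_weight(map, c(5, 3)), 40)
  const <- matrix(7, 14, 8)
  expect_equal(barycenter_weight(const, c(3.21, 6.78)), 7)
  expect_error(barycenter_weight(map, c(0.5, 3)), "outside")
  # ratio of planted amplitudes is recovered exactly on clean maps
  m1 <- gaussian_map(7, 4, 1.2, amp = 1.4)
  m2 <- gaussian_map(7, 4, 1.2, amp = 1.0)
  expect_equal(weight_ratio(m1, m2, c(7, 4), c(7, 4)), 1.4, tolerance = 1e-9)
  expect_error(weight_ratio(m2, 0 * m2, c(7, 4), c(7, 4)), "~0")
})

test_that("the paired Wilcoxon COG test has exact small-sample behaviour", {
  # identical conditions: p = 1 with warning
  x <- matrix(runif(12), 6, 2)
  expect_warning(res <- cog_position_test(x, x, axis = "x"), "zero")
  expect_equal(res$p_value, 1)
  # 8 pairs all shifted by +1: two-sided exact p = 2/2^8
  a <- cbind(1:8, 1:8)
  b <- cbind(1:8 + 1, 1:8)
  expect_equal(cog_position_test(a, b, axis = "x")$p_value, 2 / 256,
               tolerance = 1e-12)
  expect_error(cog_position_test(a[1:3, ], b[1:3, ]), "at least 5")
})

test_that("Wilcoxon type-I error is calibrated near the nominal level", {
  set.seed(13)
  n_sim <- 2000
  rej <- 0
  for (i in seq_len(n_sim)) {
    d <- rnorm(8)
    p <- cog_position_test(cbind(d, d), cbind(numeric(8), numeric(8)),
                           axis = "x")$p_value
    if (p <= 0.05) rej <- rej + 1
  }
  # the exact signed-rank test is discrete and conservative at n = 8
  expect_gt(rej / n_sim, 0.01)
  expect_lt(rej / n_sim, 0.08)
})
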