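# Univariate and half-space-depth overlap statistics.

test_that("univariate overlap reproduces the linear-interpolation worked example", {
  # reference 1..100 vs itself: interval [3.475, 97.525] retains 4..97
  expect_equal(univariate_overlap(1:100, 1:100), 0.94)
  # far-shifted new sample has no overlap
  expect_equal(univariate_overlap(1:100, 1001:1100), 0)
  # new sample inside the central interval overlaps fully
  expect_equal(univariate_overlap(1:100, 40:60), 1)
})

test_that("univariate overlap converges to the coverage level under one distribution", {
  set.seed(42)
  ref <- rnorm(20000)
  new <- rnorm(20000)
  expect_lt(abs(univariate_overlap(ref, new) - 0.95), 0.01)
  expect_lt(abs(univariate_overlap(ref, new, 0.8) - 0.80), 0.01)
})

test_that("univariate overlap is invariant under strictly monotone transforms", {
  set.seed(7)
  ref <- rlnorm(500)
  new <- rlnorm(300, meanlog = 0.5)
  base <- univariate_overlap(ref, new)
  for (f in list(log, sqrt, function(x) 3 * x - 10, function(x) -1 / x)) {
    expect_equal(univariate_overlap(f(ref), f(new)), base)
  }
})

test_that("univariate overlap validates its inputs", {
  expect_error(univariate_overlap(1:100, numeric(0)), "empty")
  expect_error(univariate_overlap(1:10, 1:5), "too small")
})

test_that("1-D rank depth matches direct counting", {
  expect_equal(halfspace_depth_1d(5, 1:10), 0.5)   # min(5, 6)/10
  expect_equal(halfspace_depth_1d(1, 1:10), 0.1)
  expect_equal(halfspace_depth_1d(0, 1:10), 0)     # outside the range
  expect_equal(halfspace_depth_1d(11, 1:10), 0)
  # vectorised
  expect_equal(halfspace_depth_1d(c(0, 1, 5), 1:10), c(0, 0.1, 0.5))
})

test_that("random depth in one dimension equals the rank depth exactly", {
  set.seed(3)
  ref <- rnorm(200)
  pts <- c(ref[1:20], rnorm(20, sd = 3))
  for (nd in c(1, 7, 100)) {
    expect_equal(random_tukey_depth(pts, ref, n_directions = nd, seed = 5),
                 halfspace_depth_1d(pts, ref))
  }
})

test_that("exact 2-D depth agrees with the brute-force angular sweep", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  # centre of a square: every closed half-plane through it keeps an
  # opposite vertex pair, so the minimal slice is 2 of 4
  expect_equal(halfspace_depth_exact_2d(c(0, 0), sq), 0.5)
  expect_equal(brute_depth_2d(c(0, 0), sq), 0.5)
  # a vertex can be sliced off alone (it counts itself on the boundary)
  expect_equal(halfspace_depth_exact_2d(c(1, 1), sq), 0.25)
  expect_equal(brute_depth_2d(c(1, 1), sq), 0.25)
  # far outside the hull
  expect_equal(halfspace_depth_exact_2d(c(9, 9), sq), 0)

  set.seed(11)
  ref <- matrix(rnorm(120), 60, 2)
  qs <- rbind(ref[1:5, ], matrix(rnorm(10, sd = 2), 5, 2))
  for (i in seq_len(nrow(qs))) {
    expect_equal(halfspace_depth_exact_2d(qs[i, ], ref),
                 brute_depth_2d(qs[i, ], ref))
  }
})

test_that("exact 2-D depth is affine invariant", {
  set.seed(12)
  ref <- matrix(rnorm(200), 100, 2)
  a <- matrix(c(2, 0.5, -1, 1.5), 2, 2)   # invertible
  b <- c(3, -7)
  for (p in list(c(0, 0), c(0.5, -0.2), ref[4, ])) {
    expect_equal(
      halfspace_depth_exact_2d(drop(a %*% p + b),
                               t(a %*% t(ref) + b)),
      halfspace_depth_exact_2d(p, ref))
  }
})

test_that("random depth never underestimates the exact depth", {
  set.seed(13)
  ref <- matrix(rnorm(300), 150, 2)
  qs <- matrix(rnorm(60, sd = 1.5), 30, 2)
  exact <- apply(qs, 1, halfspace_depth_exact_2d, reference = ref)
  approx <- random_tukey_depth(qs, ref, n_directions = 200, seed = 2)
  expect_true(all(approx >= exact - 1e-12))
  # and tightens (in expectation, here monotone for nested direction sets
  # is not guaranteed, so compare a small vs large budget on average)
  approx_big <- random_tukey_depth(qs, ref, n_directions = 5000, seed = 2)
  expect_lte(mean(approx_big), mean(approx) + 1e-12)
})

test_that("random depth with many directions matches the exact 2-D oracle", {
  set.seed(14)
  ref <- matrix(rnorm(400), 200, 2)
  qs <- rbind(ref[1:25, ], matrix(rnorm(50), 25, 2))
  exact <- apply(qs, 1, halfspace_depth_exact_2d, reference = ref)
  approx <- random_tukey_depth(qs, ref, n_directions = 5000, seed = 9)
  expect_lt(max(abs(approx - exact)), 0.02)
})

test_that("degenerate reference gives depth 0.5 at the point, 0 elsewhere", {
  ref <- matrix(1, 50, 3)
  d <- random_tukey_depth(rbind(c(1, 1, 1), c(2, 1, 1)), ref,
                          n_directions = 50, seed = 1)
  expect_equal(d, c(0.5, 0))
})

test_that("depth model cutoff covers the nominal reference fraction", {
  ref <- gauss_cloud(1000, seed = 21)
  m <- fit_depth_model(ref, coverage_level = 0.95, n_directions = 300,
                       seed = 4)
  self_cov <- mean(m$depths >= m$cutoff)
  expect_gte(self_cov, 0.95)
  expect_true(all(m$depths >= 0 & m$depths <= 0.5))
  # full coverage pins the cutoff at the minimum depth
  m1 <- fit_depth_model(ref, coverage_level = 1, n_directions = 300, seed = 4)
  expect_equal(m1$cutoff, min(m1$depths))
  expect_equal(mean(m1$depths >= m1$cutoff), 1)
})

test_that("depth model fitting is deterministic under a fixed seed", {
  ref <- gauss_cloud(300, seed = 22)
  m1 <- fit_depth_model(ref, n_directions = 200, seed = 8)
  m2 <- fit_depth_model(ref, n_directions = 200, seed = 8)
  expect_identical(m1$cutoff, m2$cutoff)
  expect_identical(m1$depths, m2$depths)
  m3 <- fit_depth_model(ref, n_directions = 200, seed = 9)
  expect_false(identical(m3$depths, m1$depths))
})

test_that("depth overlap behaves at the extremes", {
  ref <- gauss_cloud(800, seed = 23)
  m <- fit_depth_model(ref, n_directions = 300, seed = 1)
  # the reference cloud scored against itself is at least the nominal level
  expect_gte(depth_overlap(m, ref), 0.95)
  # a cloud far outside the reference hull has zero overlap
  far <- ref + 100
  expect_equal(depth_overlap(m, far), 0)
})

test_that("depth overlap matches coverage for an independent same-distribution sample", {
  ref <- gauss_cloud(2000, seed = 24)
  new <- gauss_cloud(2000, seed = 25)
  m <- fit_depth_model(ref, n_directions = 1000, seed = 2)
  expect_lt(abs(depth_overlap(m, new) - 0.95), 0.03)
})

test_that("depth overlap decreases monotonically with Gaussian mean shift", {
  ref <- gauss_cloud(1200, seed = 26)
  m <- fit_depth_model(ref, n_directions = 400, seed = 3)
  sds <- apply(ref, 2, sd)
  shifts <- c(0, 0.5, 1, 2, 4)
  ov <- vapply(shifts, function(s) {
    depth_overlap(m, sweep(gauss_cloud(800, seed = 27), 2, -s * sds))
  }, numeric(1))
  expect_true(all(diff(ov) <= 1e-12))
  expect_lt(ov[length(ov)], 0.1)
})

test_that("depth overlap is approximately affine invariant", {
  set.seed(30)
  ref <- gauss_cloud(800, seed = 31)[, 1:3]
  new <- gauss_cloud(500, seed = 32)[, 1:3] + 0.3
  a <- matrix(rnorm(9), 3, 3) + diag(3)   # invertible w.p. 1
  b <- c(1, -2, 5)
  ov1 <- depth_overlap(fit_depth_model(ref, n_directions = 800, seed = 6),
                       new)
  ov2 <- depth_overlap(
    fit_depth_model(t(a %*% t(ref) + b), n_directions = 800, seed = 6),
    t(a %*% t(new) + b))
  expect_lt(abs(ov1 - ov2), 0.05)
})

test_that("gait clouds validate metrics and reject missing values", {
  df <- as.data.frame(gauss_cloud(20, seed = 33))
  gc <- gait_cloud(df)
  expect_identical(colnames(gc), gait_metrics())
  df_bad <- df; df_bad$speed[3] <- NA
  expect_error(gait_cloud(df_bad), "missing")
  expect_error(gait_cloud(df[, -1]), "speed")
  m <- fit_depth_model(gait_cloud(as.data.frame(gauss_cloud(120, seed = 34))),
                       n_directions = 50, seed = 1)
  wrong <- gait_cloud(df, metrics = rev(gait_metrics()))
  expect_error(depth_overlap(m, wrong), "do not match")
})
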