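test_that("nw_regress matches the double-loop oracle on random small instances", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    x <- runif(n, 50, 85)
    y <- rnorm(n)
    h <- runif(1, 2, 20)
    grid <- seq(floor(min(x)), ceiling(max(x)))
    expect_equal(nw_regress(x, y, h, grid), oracle_nw(x, y, h, grid),
                 tolerance = 1e-12)
  }
})

test_that("nw_regress reproduces hand-computed values and basic symmetries", {
  # constant response: weighted average of a constant
  expect_equal(nw_regress(c(51, 60, 72), rep(2, 3), h = 7, grid = 50:80),
               rep(2, 31))
  # symmetric weights at the midpoint
  expect_equal(nw_regress(c(50, 70), c(0, 1), h = 10, grid = 60), 0.5)
  # at the left point: (1*0 + e^-2 * 1) / (1 + e^-2)
  expect_equal(nw_regress(c(50, 70), c(0, 1), h = 10, grid = 50),
               exp(-2) / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(nw_regress(c(50, 70), c(0, 1), h = 10, grid = 50), 5),
               0.11920)
})

test_that("NW estimates stay within the response range and flatten as h grows", {
  set.seed(9)
  x <- runif(100, 50, 85); y <- rnorm(100, -0.02 * (x - 50), 0.5)
  est <- nw_regress(x, y, h = 5, grid = 50:85)
  expect_true(all(est >= min(y) & est <= max(y)))
  flat <- nw_regress(x, y, h = 1e6, grid = 50:85)
  expect_equal(flat, rep(mean(y), 36), tolerance = 1e-6)
})

test_that("grid points far outside the data are an error, not NaN", {
  expect_error(nw_regress(c(60, 61), c(0, 1), h = 1, grid = 3000),
               "kernel weights")
})

test_that("bandwidth selection ties break to the smallest candidate on constant data", {
  set.seed(10)
  x <- runif(40, 50, 80); y <- rep(1.5, 40)
  h <- select_bandwidth(x, y, candidates = c(5, 10, 15), seed = 1)
  expect_equal(as.numeric(h), 5)
  expect_equal(unname(attr(h, "cv_mse")), rep(0, 3), tolerance = 1e-20)
})

test_that("CV prefers small bandwidths for sharp structure, large for pure noise", {
  set.seed(11)
  x <- seq(50, 80, length.out = 300)
  y_sharp <- sin((x - 50) / 5) + rnorm(300, 0, 0.01)
  expect_equal(as.numeric(select_bandwidth(x, y_sharp, seed = 2)), 5)
  wins <- sapply(1:10, function(s) {
    y_noise <- rnorm(300, 0, 1)
    as.numeric(select_bandwidth(x, y_noise, seed = s))
  })
  expect_gt(sum(wins == 15), 5)
})

test_that("bootstrap curve summarizes its replicates and is seed-deterministic", {
  set.seed(12)
  x <- runif(60, 55, 80); y <- rnorm(60, 0, 1)
  cv1 <- bootstrap_curve(x, y, h = 10, grid = 55:80, n_boot = 50, seed = 99)
  cv2 <- bootstrap_curve(x, y, h = 10, grid = 55:80, n_boot = 50, seed = 99)
  expect_identical(cv1, cv2)
  expect_equal(cv1$mean, colMeans(cv1$bootstrap))
  expect_equal(cv1$sd, apply(cv1$bootstrap, 2, sd))
  # weighted-average property of every replicate
  expect_true(all(cv1$bootstrap >= min(y) & cv1$bootstrap <= max(y)))
  # constant response: zero spread everywhere
  cvc <- bootstrap_curve(x, rep(3, 60), h = 10, grid = 55:80, n_boot = 20, seed = 1)
  expect_equal(cvc$sd, rep(0, 26), tolerance = 1e-12)
  expect_equal(max(abs(cvc$bootstrap - 3)), 0, tolerance = 1e-12)
})

test_that("the count-matrix bootstrap equals refitting on explicit resamples", {
  set.seed(13)
  n <- 25
  x <- runif(n, 55, 75); y <- rnorm(n)
  cv <- bootstrap_curve(x, y, h = 8, grid = 55:75, n_boot = 6, seed = 7)
  # replay the same RNG stream to recover the resample indices
  idx <- volcurve:::with_seed(7, lapply(1:6, function(b) sample.int(n, n, replace = TRUE)))
  for (b in 1:6) {
    direct <- nw_regress(x[idx[[b]]], y[idx[[b]]], h = 8, grid = 55:75)
    expect_equal(unname(cv$bootstrap[b, ]), direct, tolerance = 1e-10)
  }
})

test_that("bootstrap SD tracks the Monte-Carlo sampling SD of the estimator", {
  gen <- function() {
    x <- runif(200, 50, 80)
    list(x = x, y = -0.02 * (x - 50) + rnorm(200, 0, 0.3))
  }
  set.seed(14)
  d <- gen()
  cv <- bootstrap_curve(d$x, d$y, h = 10, grid = 50:80, n_boot = 100, seed = 1)
  centre <- 10:21  # central ages 59-70
  mc <- replicate(100, {
    dd <- gen()
    nw_regress(dd$x, dd$y, h = 10, grid = 50:80)[centre]
  })
  ratio <- mean(cv$sd[centre]) / mean(apply(mc, 1, sd))
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("curve recovery improves with sample size and is accurate at n=1000", {
  rmse_at <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 50, 85)
    mu <- -0.02 * (x - 50)
    y <- mu + rnorm(n, 0, 0.5)
    grid <- 50:85
    cv <- bootstrap_curve(x, y, h = 5, grid = grid, n_boot = 100, seed = seed)
    central <- grid >= quantile(grid, 0.1) & grid <= quantile(grid, 0.9)
    sqrt(mean((cv$mean[central] - (-0.02 * (grid[central] - 50)))^2))
  }
  r100 <- mean(sapply(1:5, function(s) rmse_at(100, s)))
  r1000 <- mean(sapply(1:5, function(s) rmse_at(1000, s)))
  expect_lt(r1000, r100)
  expect_lt(r1000, 0.15)
})

test_that("CV folds and bootstrap draws use independent seeded streams", {
  set.seed(15)
  x <- runif(80, 52, 82); y <- rnorm(80, -0.02 * (x - 50), 0.5)
  rng <- compute_age_range(x, min_count = 3, window = 2)
  fit_auto <- volume_curve(x, y, rng, seed = 5)
  fit_fixed <- volume_curve(x, y, rng, bandwidth = fit_auto$bandwidth, seed = 5)
  expect_identical(fit_auto$bootstrap, fit_fixed$bootstrap)
  # and the fit is reproducible end to end
  expect_identical(fit_auto, volume_curve(x, y, rng, seed = 5))
})

test_that("predict interpolates the fitted grid and refuses extrapolation", {
  cv <- toy_curve(60:64, c(0, 1, 2, 3, 4))
  expect_equal(predict(cv, c(60, 61.5, 64)), c(0, 1.5, 4))
  expect_error(predict(cv, 59), "outside")
})
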