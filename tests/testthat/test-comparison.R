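test_that("area between curves matches analytic toy geometries", {
  ov <- valid_range(60, 80)
  grid <- 60:80
  flat0 <- toy_curve(grid, rep(0, 21))
  flat05 <- toy_curve(grid, rep(0.5, 21))
  expect_equal(area_between(flat0, flat0, ov), 0)
  expect_equal(area_between(flat0, flat05, ov), 10, tolerance = 1e-12)
  # piecewise-linear curves crossing once: two unit triangles
  g2 <- 60:64
  a <- toy_curve(g2, rep(0, 5))
  b <- toy_curve(g2, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(area_between(a, b, valid_range(60, 64)), 2, tolerance = 1e-12)
})

test_that("area is symmetric and satisfies the triangle inequality", {
  set.seed(16)
  ov <- valid_range(60, 70)
  for (i in 1:20) {
    g <- 60:70
    a <- toy_curve(g, rnorm(11)); b <- toy_curve(g, rnorm(11)); c_ <- toy_curve(g, rnorm(11))
    expect_equal(area_between(a, b, ov), area_between(b, a, ov))
    expect_lte(area_between(a, b, ov),
               area_between(a, c_, ov) + area_between(c_, b, ov) + 1e-12)
  }
})

test_that("disjoint ranges are an explicit error", {
  a <- toy_curve(60:70, rnorm(11))
  expect_error(area_between(a, a, overlap_range(valid_range(50, 55), valid_range(60, 70))),
               "overlap")
})

test_that("chi2 test handles coincident curves and the single-point oracle", {
  g <- 60:70
  same <- toy_curve(g, rep(0.3, 11), sd = rep(0.1, 11),
                    bootstrap = matrix(rnorm(55, 0.3, 0.1), 5))
  res <- chi2_curve_test(same, same, valid_range(60, 70))
  expect_equal(res$chi2, 0)
  expect_equal(res$p_raw, 1)
  # single grid point, d = 1, sd_a = 1, sd_b = 0
  a1 <- toy_curve(60, 1, sd = 1, bootstrap = matrix(c(0, 2, 1), 3))
  b1 <- toy_curve(60, 0, sd = 0, bootstrap = matrix(c(0, 0, 0), 3))
  ov1 <- structure(list(lo = 60L, hi = 60L, valid = TRUE), class = "age_range")
  for (m in c("satterthwaite", "nominal")) {
    r1 <- chi2_curve_test(a1, b1, ov1, method = m)
    expect_equal(r1$chi2, 1)
    expect_equal(r1$df, 1)
    expect_equal(r1$p_raw, pchisq(1, 1, lower.tail = FALSE))
    expect_equal(r1$p_raw, 0.31731, tolerance = 1e-5)
  }
})

test_that("chi2 is invariant under swapping the curves", {
  set.seed(17)
  g <- 60:70
  mk <- function() {
    boot <- matrix(rnorm(20 * 11, 0, 0.2), 20) + rep(rnorm(1), each = 11)
    toy_curve(g, colMeans(boot), sd = apply(boot, 2, sd), bootstrap = boot)
  }
  a <- mk(); b <- mk()
  ra <- chi2_curve_test(a, b, valid_range(60, 70))
  rb <- chi2_curve_test(b, a, valid_range(60, 70))
  expect_equal(ra$chi2, rb$chi2)
  expect_equal(ra$df, rb$df)
  expect_equal(ra$p_raw, rb$p_raw)
})

test_that("zero pooled variance is an error naming the grid point", {
  g <- 60:62
  a <- toy_curve(g, c(0, 0, 0), sd = c(0.1, 0, 0.1))
  b <- toy_curve(g, c(1, 1, 1), sd = c(0.1, 0, 0.1))
  expect_error(chi2_curve_test(a, b, valid_range(60, 62)), "61")
})

test_that("Bonferroni adjustment multiplies by the declared family and caps at 1", {
  expect_equal(bonferroni_adjust(0.002, m = 10), 0.02)
  expect_equal(bonferroni_adjust(0.2, m = 10), 1)
  expect_equal(bonferroni_adjust(0.37), 0.37)  # family of one
  p <- c(0.001, 0.03, 0.9)
  expect_equal(bonferroni_adjust(p), pmin(1, p * 3))
  expect_true(all(bonferroni_adjust(p, 5) >= p))
})

test_that("rank_regions sorts by area with lexicographic ties and respects top_k", {
  cmp <- data.frame(region_code = c("A", "B", "C"), area = c(3, 5, 1))
  expect_equal(rank_regions(cmp, 2)$region_code, c("B", "A"))
  tied <- data.frame(region_code = c("ZZ", "AA", "MM"), area = 2)
  expect_equal(rank_regions(tied, 3)$region_code, c("AA", "MM", "ZZ"))
  expect_equal(nrow(rank_regions(cmp, 10)), 3)
})

test_that("self-comparison yields zero areas and p = 1 everywhere", {
  coh <- generate_cohort(small_config(), seed = 21)
  nc <- normalize_volumes(stratify_cohort(coh)$cohort)
  cmp <- compare_groups(nc, "N", "N",
                        settings = comparison_settings(n_boot = 30, seed = 3))
  expect_true(all(cmp$area == 0))
  expect_true(all(cmp$p_raw == 1))
  expect_false(any(cmp$significant))
})

test_that("an injected single-region effect ranks first in most seeded runs", {
  cfg <- small_config(group_sizes = c(N = 250, AD = 150, V = 10, AV = 10, OP = 10))
  hits <- sapply(1:5, function(s) {
    coh <- generate_cohort(cfg, seed = 100 + s)
    nc <- remove_outliers(normalize_volumes(stratify_cohort(coh)$cohort))
    cmp <- compare_groups(nc, "N", "AD",
                          settings = comparison_settings(n_boot = 50, seed = s))
    rank_regions(cmp, 1)$region_code == "LLENTAV"
  })
  expect_gte(sum(hits), 4)
})

test_that("vs-ALL comparisons are flagged descriptive and ranked by area", {
  coh <- generate_cohort(small_config(), seed = 31)
  nc <- normalize_volumes(stratify_cohort(coh)$cohort)
  cmp <- compare_groups(nc, "N", "ALL",
                        settings = comparison_settings(n_boot = 30, seed = 4))
  expect_true(all(cmp$descriptive))
  expect_equal(cmp$area, sort(cmp$area, decreasing = TRUE))
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$p_adj >= cmp$p_raw))
})
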