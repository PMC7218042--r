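test_that("ICC(A,1) matches the explicit mean-squares oracle", {
  expect_equal(icc_agreement(icc_fixture)$estimate, oracle_icc_a1(icc_fixture),
               tolerance = 1e-12)
  expect_equal(icc_agreement(icc_fixture)$estimate, icc_fixture_value,
               tolerance = 1e-10)
  # any column pair too
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    sub <- icc_fixture[, p]
    expect_equal(icc_agreement(sub)$estimate, oracle_icc_a1(sub),
                 tolerance = 1e-12)
  }
})

test_that("ICC handles the perfect, null and degenerate cases", {
  m <- cbind(c(3, 9, 1, 7, 5), c(3, 9, 1, 7, 5), c(3, 9, 1, 7, 5))
  res <- icc_agreement(m)
  expect_equal(res$estimate, 1.0)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))
  set.seed(4)
  noise <- matrix(rnorm(3000), 1000, 3)   # no subject variance
  expect_lt(abs(icc_agreement(noise)$estimate), 0.1)
  expect_error(icc_agreement(matrix(5, 4, 3)), "zero total variance")
  expect_true(icc_agreement(icc_fixture[1:3, ])$low_n)
})

test_that("ICC is invariant under a common affine transform and bounded by 1", {
  r0 <- icc_agreement(icc_fixture)
  r1 <- icc_agreement(3.7 * icc_fixture - 12)
  expect_equal(r1$estimate, r0$estimate, tolerance = 1e-10)
  expect_equal(r1$ci_low, r0$ci_low, tolerance = 1e-8)
  for (seed in 1:5) {
    m <- make_readings(20, 3, 0.3, 0.1, seed = seed)
    res <- icc_agreement(m)
    expect_lte(res$estimate, 1)
    expect_lte(res$ci_low, res$estimate)
    expect_gte(res$ci_high, res$estimate)
  }
})

test_that("pairwise CV follows the RMS within-pair formula", {
  expect_equal(pairwise_cv(c(5, 8, 2), c(5, 8, 2)), 0)
  expect_equal(pairwise_cv(100, 121), 100 * (21 / sqrt(2)) / 110.5,
               tolerance = 1e-12)
  expect_equal(round(pairwise_cv(100, 121), 2), 13.44)
  x <- c(100, 50, 70); y <- c(121, 48, 77)
  expect_equal(pairwise_cv(10 * x, 10 * y), pairwise_cv(x, y))  # scale-free
  expect_error(pairwise_cv(c(1, -1), c(1, 1)), "positive")
})

test_that("Bland-Altman bias and 2-SD limits behave as defined", {
  r <- bland_altman(c(4, 7, 1), c(4, 7, 1))
  expect_equal(c(r$bias, r$loa_low, r$loa_high), c(0, 0, 0))
  r2 <- bland_altman(c(10, 20, 30), c(7, 17, 27))   # constant difference 3
  expect_equal(c(r2$bias, r2$sd_diff, r2$loa_low, r2$loa_high), c(3, 0, 3, 3))
  set.seed(8)
  d <- rnorm(5000)
  r3 <- bland_altman(d, rep(0, 5000))
  expect_equal(r3$bias, mean(d))
  expect_equal(r3$loa_high - r3$loa_low, 4 * sd(d))
  expect_equal(nrow(r3$points), 5000)
  inside <- mean(d > r3$loa_low & d < r3$loa_high)
  expect_lt(abs(inside - 0.9545), 0.012)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("the normality gate selects the right test family", {
  set.seed(15)
  base <- rnorm(20, 50, 5)
  m <- cbind(A = base, B = base + 3, C = base + 6)  # normal, pure offsets
  res <- compare_readers(m)
  expect_identical(res$family, "parametric")
  expect_true(all(res$pairwise$p_value < 1e-6))
  expect_lt(res$overall$p_value, 1e-6)
  expect_identical(res$overall$method, "two-way ANOVA (observer effect)")

  skewed <- cbind(A = exp(rnorm(30, 0, 1)), B = exp(rnorm(30, 0, 1)),
                  C = exp(rnorm(30, 0, 1)))
  expect_identical(compare_readers(skewed)$family, "non-parametric")
})

test_that("Friedman route matches the rank-sum oracle", {
  res <- compare_readers(friedman_fixture)
  expect_identical(res$family, "non-parametric")  # outlier row fails the gate
  expect_identical(res$overall$method, "Friedman")
  expect_equal(res$overall$statistic, oracle_friedman(friedman_fixture),
               tolerance = 1e-12)
})

test_that("identical columns take the degenerate path, not a p-value", {
  m <- cbind(c(1, 5, 3, 8), c(1, 5, 3, 8), c(1, 5, 3, 8))
  res <- compare_readers(m)
  expect_true(res$overall$degenerate)
  expect_true(all(res$pairwise$degenerate))
  expect_true(all(is.na(res$pairwise$p_value)))
})
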