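test_that("simulated cohorts are complete-block and seed-deterministic", {
  model <- default_cohort_model(n_treatments = 25, n_observers = 3)
  tab <- simulate_cohort(model, seed = 11)
  expect_s3_class(tab, "observer_dose_table")
  expect_equal(nrow(tab), 75)
  expect_true(all(table(tab$treatment_id, tab$observer_id) == 1))
  expect_identical(tab, simulate_cohort(model, seed = 11))
  expect_false(identical(tab$TD_Gy, simulate_cohort(model, seed = 12)$TD_Gy))
  # structural invariants of every generated table
  expect_true(all(tab$TV_ml < tab$TLV_ml))
  expect_equal(tab$THLV_ml, tab$TLV_ml - tab$TV_ml)
})

test_that("zero observer noise makes all observers read identically", {
  model <- default_cohort_model(n_treatments = 8,
                                sigma_within = c(TV = 0, TLV = 0,
                                                 TD = 0, THLD = 0))
  tab <- simulate_cohort(model, seed = 3)
  for (q in c("TV", "TLV", "TD", "THLD")) {
    m <- readings_matrix(tab, q)
    expect_true(all(abs(m - m[, 1]) < 1e-12 * m[, 1]), label = q)
  }
})

test_that("log-scale moments are recovered at large n", {
  model <- default_cohort_model(n_treatments = 10000)
  tab <- suppressWarnings(simulate_cohort(model, seed = 5))
  lx <- log(readings_matrix(tab, "TD"))
  n <- nrow(lx); k <- ncol(lx)
  # within-treatment SD via one-way residual MS recovers sigma_within = 0.14
  msw <- sum((lx - rowMeans(lx))^2) / (n * (k - 1))
  expect_lt(abs(sqrt(msw) - 0.14) / 0.14, 0.02)
  # marginal log mean within 3 Monte-Carlo SEs
  sig_tot <- sqrt(model$sigma_between[["TD"]]^2 + 0.14^2)
  expect_lt(abs(mean(lx) - model$mu_log[["TD"]]), 3 * sig_tot / sqrt(n))
  # natural-scale calibration target (Table-level mean) within 3 SE
  m <- readings_matrix(tab, "TD")
  expect_lt(abs(mean(m) - 238), 3 * sd(m) / sqrt(n))
})

test_that("true_icc follows the variance-ratio formula", {
  base <- list(n_treatments = 10, mu_log = c(TV = 4, TLV = 7, TD = 5, THLD = 3))
  mk <- function(sb, sw)
    cohort_model(n_treatments = 10, mu_log = base$mu_log,
                 sigma_between = c(TV = sb, TLV = sb, TD = sb, THLD = sb),
                 sigma_within = c(TV = sw, TLV = sw, TD = sw, THLD = sw))
  expect_equal(true_icc(mk(0.3, 0), "TD"), 1.0)
  expect_equal(true_icc(mk(0.2, 0.2), "TD"), 0.5)
  expect_equal(true_icc(mk(0.3, 0.1), "TD"), 0.9)
  expect_error(true_icc(mk(0, 0), "TD"), "undefined")
})

test_that("degenerate TV >= TLV draws are retried, then fail informatively", {
  mu <- c(TV = 7, TLV = 7, TD = 5, THLD = 3)  # tumor as large as liver
  model <- cohort_model(n_treatments = 3, mu_log = mu,
                        sigma_between = c(TV = 0.2, TLV = 0.2, TD = 0.1,
                                          THLD = 0.1),
                        sigma_within = c(TV = 0.1, TLV = 0.1, TD = 0.1,
                                         THLD = 0.1))
  expect_warning(tab <- simulate_cohort(model, seed = 2), "redrew")
  expect_true(all(tab$TV_ml < tab$TLV_ml))
  # with no randomness left the violation cannot be repaired
  bad <- cohort_model(n_treatments = 2, mu_log = c(TV = 8, TLV = 7, TD = 5,
                                                   THLD = 3),
                      sigma_between = c(TV = 0, TLV = 0, TD = 0, THLD = 0),
                      sigma_within = c(TV = 0, TLV = 0, TD = 0, THLD = 0))
  expect_error(suppressWarnings(simulate_cohort(bad, seed = 1, max_retries = 5)),
               "incompatible")
})

test_that("lognormal calibration reproduces the requested moments", {
  for (tgt in list(c(238, 120), c(1749, 507), c(45.3, 30.2))) {
    cal <- lognormal_calibration(tgt[1], tgt[2], sigma_within = 0.05)
    s2 <- cal[["sigma_between"]]^2 + 0.05^2
    expect_equal(exp(cal[["mu_log"]] + s2 / 2), tgt[1])
    expect_equal(exp(2 * cal[["mu_log"]] + s2) * (exp(s2) - 1), tgt[2]^2)
  }
  expect_error(lognormal_calibration(100, 1, sigma_within = 0.5), "too small")
})
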