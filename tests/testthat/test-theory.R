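test_that("log-normal calibration matches the closed forms and moment identities", {
  p <- calibrate_lognormal(1, 1)
  expect_equal(p$sigma, sqrt(log(2)), tolerance = 1e-12)
  expect_equal(p$mu, -0.5 * log(2), tolerance = 1e-12)

  p0 <- calibrate_lognormal(3, 0)
  expect_equal(p0$sigma, 0)
  expect_equal(p0$mu, log(3))

  # moment identities hold algebraically for random (mean, sd) pairs
  set.seed(2)
  m <- exp(runif(1000, log(1e-3), log(1e3)))
  s <- m * exp(runif(1000, log(1e-2), log(10)))
  cal <- calibrate_lognormal(m, s)
  expect_equal(exp(cal$mu + cal$sigma^2 / 2), m, tolerance = 1e-12)
  expect_equal((exp(cal$sigma^2) - 1) * m^2, s^2, tolerance = 1e-12)

  expect_error(calibrate_lognormal(0, 1), "positive")
  expect_error(calibrate_lognormal(1, -1), "non-negative")
})

test_that("calibrated log-normal draws reproduce the target moments", {
  set.seed(4)
  x <- fluctscale:::rlnorm_calibrated(2e5, 2, 3)
  # CV = 1.5: sd of sample mean = 3/sqrt(n); variance needs the 4th moment
  expect_lt(abs(mean(x) - 2), 3 * 3 / sqrt(2e5))
  expect_lt(abs(sd(x) - 3), 0.15)
})

test_that("squared-normal calibration solves the two-moment system", {
  p <- calibrate_squared_normal(1, sqrt(2))  # chi-square(1)
  expect_equal(p$m, 0, tolerance = 1e-12)
  expect_equal(p$s, 1, tolerance = 1e-12)

  # identities for a feasible interior case
  p2 <- calibrate_squared_normal(5, 3)
  expect_equal(p2$m^2 + p2$s^2, 5, tolerance = 1e-12)
  expect_equal(2 * p2$s^4 + 4 * p2$m^2 * p2$s^2, 9, tolerance = 1e-12)

  # round trip by simulation
  set.seed(6)
  y <- (p2$m + p2$s * rnorm(2e5))^2
  expect_lt(abs(mean(y) - 5), 4 * 3 / sqrt(2e5))
  expect_lt(abs(var(y) - 9), 0.5)

  # infeasible: sd^2 = 3 * mean^2 exceeds the attainable variance
  expect_error(calibrate_squared_normal(1, sqrt(3)), "no real solution")
})

test_that("analytic exponent is skewness over CV with the G1 estimator", {
  expect_equal(analytic_exponent(c(1, 2, 3)), 0, tolerance = 1e-12)
  expect_error(analytic_exponent(rep(1, 10)), "zero-variance")
  expect_error(analytic_exponent(c(1, 2)), "at least 3")

  # brute-force moment oracle on a fixed 10-value sample
  x <- c(0.12, 0.5, 0.77, 1.3, 2.1, 0.33, 4.2, 0.9, 1.6, 0.05)
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  g1 <- (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  cv <- sd(x) / mean(x)
  expect_equal(analytic_exponent(x), g1 / cv, tolerance = 1e-12)

  # cross-check the skewness estimator against e1071's adjusted form
  expect_equal(fluctscale:::sample_skewness(x),
               e1071::skewness(x, type = 2), tolerance = 1e-12)

  # log-normal population: skew/CV converges to exp(sigma^2) + 2
  set.seed(10)
  z <- exp(sqrt(0.5) * rnorm(1e6))
  expect_lt(abs(analytic_exponent(z) - (exp(0.5) + 2)), 0.2)
})

test_that("iid simulation concentrates near the generating exponent when noise is small", {
  mv <- exact_meanvar(exp(seq(log(0.1), log(10), length.out = 100)),
                      a = 1e-5, b = 2.2)
  b <- iid_simulation_b(mv, n_boot = 30, seed = 1)
  expect_lt(abs(mean(b) - 2.2), 0.05)

  # determinism under a fixed seed
  expect_identical(iid_simulation_b(mv, n_boot = 1, seed = 9),
                   iid_simulation_b(mv, n_boot = 1, seed = 9))
})

test_that("high per-cell skewness inflates the iid exponent beyond 3", {
  # cells with similar means and CV = 2: the sampling artifact dominates
  set.seed(12)
  means <- exp(runif(200, log(0.9), log(1.1)))
  mv <- data.frame(mean_rate = means, var_rate = (2 * means)^2)
  b_percell <- iid_simulation_b(mv, n_boot = 50, seed = 3)
  expect_gt(mean(b_percell), 3)
  b_pooled <- iid_simulation_b(mv, n_boot = 50, seed = 3, calibration = "pooled")
  expect_gt(mean(b_pooled), 3)
})

test_that("bootstrap of the analytic exponent is consistent and reproducible", {
  set.seed(14)
  x <- exp(rnorm(500, 0, 0.8))
  bs <- bootstrap_analytic(x, n_boot = 300, seed = 5)
  expect_length(bs, 300)
  expect_identical(bs, bootstrap_analytic(x, n_boot = 300, seed = 5))
  expect_lt(abs(mean(bs) - analytic_exponent(x)), sd(bs))
  expect_error(bootstrap_analytic(rep(2, 10)), "zero-variance")
})

test_that("theory comparison verdicts reflect the percentile envelopes", {
  samples <- seq(3, 4, length.out = 100)
  cmp <- compare_to_theory(2.2, samples, samples)
  expect_identical(cmp$verdict_analytic, "below")
  expect_identical(cmp$verdict_iid, "below")
  expect_identical(compare_to_theory(median(samples), samples, samples)$verdict_iid,
                   "within")
  expect_identical(compare_to_theory(5, samples, samples)$verdict_iid, "above")
  expect_output(print(cmp), "below")
})
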