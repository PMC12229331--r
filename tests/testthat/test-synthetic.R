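test_that("cell means respect the configured range and seed", {
  cfg <- synthetic_config(n_cells = 20, mean_range = c(0.5, 0.5), seed = 3)
  expect_identical(draw_cell_means(cfg), rep(0.5, 20))

  cfg2 <- synthetic_config(n_cells = 50, mean_range = c(0.01, 10), seed = 9)
  m1 <- draw_cell_means(cfg2)
  m2 <- draw_cell_means(cfg2)
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0.01 & m1 <= 10))

  # growing the grid must not reshuffle existing cells
  cfg3 <- synthetic_config(n_cells = 80, mean_range = c(0.01, 10), seed = 9)
  expect_identical(draw_cell_means(cfg3)[1:50], m1)

  expect_error(synthetic_config(10, mean_range = c(2, 1)), "mean_range")
  expect_error(synthetic_config(10, mean_range = c(-1, 1)), "mean_range")
})

test_that("log of cell means is uniform over the configured decades", {
  cfg <- synthetic_config(n_cells = 1e5, mean_range = c(0.01, 10), seed = 11)
  m <- draw_cell_means(cfg)
  ks <- ks.test(log(m), "punif", log(0.01), log(10))
  expect_gt(ks$p.value, 0.01)
})

test_that("iid series match the calibrated log-normal moments", {
  # zero-variance limit: every draw equals the mean
  expect_equal(as.numeric(simulate_iid_series(0.7, 0, 2.2, n_years = 10, seed = 1)),
               rep(0.7, 10))
  expect_error(simulate_iid_series(-1, 1, 2), "mean")

  # mean = 1, a = 1, b = 2 so that var = 1 exactly
  x <- simulate_iid_series(1, 1, 2, n_years = 1e5, seed = 7)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))
  # sd of the sample variance: sqrt((mu4 - var^2)/n), lognormal kurtosis 38
  expect_lt(abs(var(x) - 1), 4 * sqrt(37 / 1e5))
})

test_that("feedback series reduce to iid at kappa 0 and dampen variance otherwise", {
  s_iid <- simulate_iid_series(2, 0.23, 2.2, seed = 5)
  s_fb0 <- simulate_feedback_series(2, 0.23, 2.2, feedback_kappa = 0, seed = 5)
  expect_identical(as.numeric(s_iid), as.numeric(s_fb0))

  expect_error(simulate_feedback_series(1, 1, 2, feedback_kappa = 1.5), "kappa")
  expect_error(simulate_feedback_series(1, 1, 2, recovery_rho = -0.1), "rho")

  # paired replicates: depletion strictly dampens the temporal variance
  set.seed(42)
  seeds <- sample.int(1e6, 1000)
  v_fb <- vapply(seeds, function(s)
    var(simulate_feedback_series(2, 0.23, 2.2, feedback_kappa = 0.9,
                                 recovery_rho = 0.1, seed = s)), numeric(1))
  v_iid <- vapply(seeds, function(s)
    var(simulate_iid_series(2, 0.23, 2.2, seed = s)), numeric(1))
  expect_lt(mean(v_fb), mean(v_iid))
})

test_that("susceptible pool stays within [0, 1] across many simulations", {
  set.seed(8)
  params <- data.frame(mean = exp(runif(2000, log(0.05), log(20))),
                       kappa = runif(2000, 0.05, 1),
                       rho = runif(2000),
                       f = runif(2000, 0.01, 1))
  ok <- vapply(seq_len(nrow(params)), function(i) {
    s <- simulate_feedback_series(params$mean[i], 0.5, 2.2,
                                  feedback_kappa = params$kappa[i],
                                  recovery_rho = params$rho[i],
                                  susceptible_frac = params$f[i],
                                  n_years = 35, seed = i)
    pool <- attr(s, "pool")
    all(pool >= 0 & pool <= 1) && all(s > 0)
  }, logical(1))
  expect_true(all(ok))
})

test_that("generated datasets obey the physical area bounds", {
  # degenerate: one cell, two years, zero variance
  cfg <- synthetic_config(n_cells = 1, n_years = 2, mean_range = c(1, 1),
                          intercept_a = 0, seed = 1)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 2)
  expect_equal(d$disturbed_area_ha, rep(0.01 * cfg$forest_area, 2))

  set.seed(99)
  for (i in 1:10) {
    cfg <- synthetic_config(n_cells = sample(5:40, 1),
                            n_years = sample(5:35, 1),
                            mean_range = sort(exp(runif(2, log(0.05), log(30)))),
                            intercept_a = runif(1, 0, 3),
                            exponent_b = runif(1, 0.5, 2.5),
                            feedback_kappa = runif(1),
                            seed = i)
    d <- generate_dataset(cfg)
    expect_equal(nrow(d), cfg$n_cells * cfg$n_years)
    expect_true(all(d$disturbed_area_ha >= 0))
    expect_true(all(d$disturbed_area_ha <= d$forest_area_ha))
  }
})

test_that("dataset generation is reproducible and biome labels partition cells", {
  cfg <- synthetic_config(n_cells = 30, n_years = 5,
                          biome_labels = c("boreal", "temperate", "mediterranean"),
                          seed = 4)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$biome), c("boreal", "temperate", "mediterranean"))
})

test_that("stronger feedback flattens the fitted mean-variance scaling", {
  # same config seeds across kappa levels, so the raw draws are shared and
  # only the depletion strength differs
  fit_b <- function(kappa, seed) {
    cfg <- synthetic_config(n_cells = 300, feedback_kappa = kappa, seed = seed)
    mv <- mean_variance(compute_annual_rates(generate_dataset(cfg)))
    taylor_fit(mv)$exponent_b
  }
  b_mean <- vapply(c(0, 0.3, 0.6, 0.9), function(k)
    mean(vapply(1:20, function(s) fit_b(k, s), numeric(1))), numeric(1))
  expect_true(all(diff(b_mean) <= 0))
})
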