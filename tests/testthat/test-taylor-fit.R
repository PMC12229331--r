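test_that("an exact quadratic law is recovered perfectly", {
  fit <- suppressWarnings(taylor_fit(exact_meanvar(c(1, 2, 4), a = 1, b = 2)))
  expect_equal(fit$exponent_b, 2.0, tolerance = 1e-12)
  expect_equal(fit$log_intercept, 0.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$exponent_b && fit$exponent_b <= fit$ci_high)
})

test_that("all three model forms match the normal-equations oracle", {
  set.seed(13)
  mv <- data.frame(mean_rate = exp(runif(50, log(0.1), log(10))))
  mv$var_rate <- 0.3 * mv$mean_rate^2.1 * exp(rnorm(50, 0, 0.4))

  checks <- list(
    power = list(x = log(mv$mean_rate), y = log(mv$var_rate)),
    linear = list(x = mv$mean_rate, y = mv$var_rate),
    exponential = list(x = mv$mean_rate, y = log(mv$var_rate)))
  for (form in names(checks)) {
    fit <- taylor_fit(mv, model = form)
    oracle <- ols_oracle(checks[[form]]$x, checks[[form]]$y)
    expect_equal(fit$exponent_b, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$log_intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }

  # the closed-form hot path agrees with the lm route
  fast <- fluctscale:::ols_simple(log(mv$mean_rate), log(mv$var_rate))
  fit <- taylor_fit(mv)
  expect_equal(fast$slope, fit$exponent_b, tolerance = 1e-12)
  expect_equal(fast$r_squared, fit$r_squared, tolerance = 1e-12)
})

test_that("alternative functional forms are fitted and compared in their own space", {
  means <- seq(0.5, 8, length.out = 20)
  lin <- data.frame(mean_rate = means, var_rate = 2 + 3 * means)
  fits <- suppressWarnings(fit_alternatives(lin))
  expect_equal(fits$linear$exponent_b, 3.0, tolerance = 1e-10)
  expect_equal(fits$linear$r_squared, 1.0, tolerance = 1e-10)

  quad <- exact_meanvar(means, a = 1, b = 2)
  fits2 <- suppressWarnings(fit_alternatives(quad))
  expect_equal(fits2$power$r_squared, 1.0, tolerance = 1e-12)
  expect_gt(fits2$power$r_squared, fits2$linear$r_squared)
  expect_gt(fits2$power$r_squared, fits2$exponential$r_squared)

  tab <- as.data.frame(fits2)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$model_form, c("power", "linear", "exponential"))
})

test_that("zero-mean or zero-variance records are excluded from log fits", {
  mv <- rbind(exact_meanvar(c(1, 2, 4, 8)),
              data.frame(mean_rate = c(0, 3), var_rate = c(2, 0)))
  fit <- suppressWarnings(taylor_fit(mv))
  expect_equal(fit$n_cells, 4)
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$exponent_b, 2.0, tolerance = 1e-12)

  expect_error(taylor_fit(exact_meanvar(c(1, 2))), "fewer than 3")
})

test_that("fit methods behave as a classed model object", {
  set.seed(3)
  mv <- exact_meanvar(exp(runif(40, log(0.2), log(5))), a = 0.5, b = 2.2)
  mv$var_rate <- mv$var_rate * exp(rnorm(40, 0, 0.2))
  fit <- taylor_fit(mv)

  expect_named(coef(fit), c("log_intercept", "exponent_b"))
  expect_equal(unname(predict(fit, data.frame(mean_rate = 2))),
               exp(fit$log_intercept) * 2^fit$exponent_b)
  expect_length(residuals(fit), 40)
  expect_equal(dim(confint(fit)), c(2L, 2L))
  expect_output(print(fit), "exponent b")
  expect_output(print(summary(fit)), "Coefficients")

  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()

  sims <- simulate(fit, nsim = 2, seed = 1)
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(sims, sims2)
  expect_equal(nrow(sims[[1]]), 40)
  # simulated tables scatter around the fitted law
  refit <- taylor_fit(sims[[1]])
  expect_lt(abs(refit$exponent_b - fit$exponent_b), 0.35)
})

test_that("bootstrap CI option produces a valid interval", {
  set.seed(21)
  mv <- exact_meanvar(exp(runif(60, log(0.1), log(10))), a = 0.3, b = 2)
  mv$var_rate <- mv$var_rate * exp(rnorm(60, 0, 0.3))
  fit <- taylor_fit(mv, boot_ci = TRUE, n_boot = 200, seed = 2)
  expect_true(fit$ci_low < fit$exponent_b && fit$exponent_b < fit$ci_high)
  expect_identical(fit$ci_method, "bootstrap")
})

test_that("stratified fits recover per-stratum exponents", {
  set.seed(31)
  make_stratum <- function(b, agent) {
    cfg <- synthetic_config(n_cells = 200, exponent_b = b,
                            agent_label = agent, seed = match(agent, c("x", "y")))
    mv <- mean_variance(compute_annual_rates(generate_dataset(cfg)), grain = 100)
    mv
  }
  mv <- rbind(make_stratum(1.7, "x"), make_stratum(2.2, "y"))
  fits <- stratified_fits(mv, by = "agent")
  expect_length(fits, 2)
  expect_lt(fits$x$exponent_b, fits$y$exponent_b)
  expect_lt(abs(fits$x$exponent_b - 1.7), 0.15)
  expect_lt(abs(fits$y$exponent_b - 2.2), 0.15)

  # single stratum reduces to a plain fit
  one <- stratified_fits(mv[mv$agent == "x", ], by = "agent")
  expect_equal(one$x$exponent_b, taylor_fit(mv[mv$agent == "x", ])$exponent_b)

  expect_error(stratified_fits(mv[0, ], by = "agent"), "empty")
})

test_that("best grain maximizes R-squared with coarse tie-break", {
  tab <- data.frame(grain = c(100, 400), r_squared = c(0.5, 0.9))
  expect_equal(select_best_grain(tab), 400)
  tie <- data.frame(grain = c(100, 400), r_squared = c(0.9, 0.9))
  expect_equal(select_best_grain(tie), 400)
  expect_error(select_best_grain(tab[0, ]), "no fits")

  # noise added only at the fine grain drives selection to the coarse one
  set.seed(17)
  cfg <- synthetic_config(n_cells = 256, seed = 8)
  d <- generate_dataset(cfg)
  mv_list <- lapply(c(100, 1600), function(g) {
    agg <- aggregate_to_grain(d, g)
    r <- compute_annual_rates(agg)
    if (g == 100) r$rate_pct <- r$rate_pct + runif(nrow(r), 0, 5)
    mean_variance(r, grain = g)
  })
  fits <- stratified_fits(do.call(rbind, mv_list), by = "grain")
  expect_equal(select_best_grain(fits), 1600)
})
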