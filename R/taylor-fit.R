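#' Fit Taylor's law to per-cell mean-variance records
#'
#' Fits the mean-variance scaling relationship across cells by ordinary
#' least squares. The default power-law form is fitted on log-log
#' transformed data,
#' \deqn{\log(\mathrm{var}_d) = \log(a) + b \log(\bar{x}_d),}
#' so the slope is the Taylor exponent `b` and the intercept is the
#' natural log of the multiplicative constant `a`. Two alternative forms
#' are available: `"linear"` (\eqn{var = a + b\,\bar{x}}) and
#' `"exponential"` (\eqn{\log(var) = a + b\,\bar{x}}). R-squared is
#' reported in each model's own fitted response space.
#'
#' For the log-transformed forms, records with zero mean or zero variance
#' have an undefined log and are excluded (no pseudo-offset is added); the
#' count is kept in `n_excluded`.
#'
#' @param meanvar Data frame of per-cell records with columns `mean_rate`
#'   and `var_rate` (e.g. from [mean_variance()]).
#' @param model One of `"power"`, `"linear"`, `"exponential"`.
#' @param stratum Optional label (e.g. agent/grain/biome) stored with the
#'   fit.
#' @param conf_level Confidence level for the exponent interval
#'   (default 0.95). The analytic OLS t-interval is used; set
#'   `boot_ci = TRUE` for a cell-resampling bootstrap percentile interval
#'   instead.
#' @param boot_ci Logical; bootstrap the CI by resampling cells.
#' @param n_boot Bootstrap repetitions when `boot_ci = TRUE`.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `"taylor_fit"`: a list with `model_form`,
#'   `exponent_b`, `log_intercept` (intercept in the fitted response
#'   space; the natural log of `a` for the power form), `ci_low`,
#'   `ci_high`, `r_squared`, `n_cells`, `n_excluded`, `stratum`, and the
#'   underlying `lm` fit. Methods: [print()], [summary()], [coef()],
#'   [confint()], [predict()], [residuals()], [plot()], [simulate()].
#' @examples
#' mv <- data.frame(mean_rate = c(1, 2, 4), var_rate = c(1, 4, 16))
#' fit <- taylor_fit(mv)          # exact quadratic law: b = 2, R^2 = 1
#' coef(fit)
#' predict(fit, newdata = data.frame(mean_rate = 3))
#' @export
taylor_fit <- function(meanvar, model = c("power", "linear", "exponential"),
                       stratum = NULL, conf_level = 0.95,
                       boot_ci = FALSE, n_boot = 1000, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.data.frame(meanvar),
            all(c("mean_rate", "var_rate") %in% names(meanvar)))
  keep <- switch(model,
    power = meanvar$mean_rate > 0 & meanvar$var_rate > 0,
    exponential = meanvar$var_rate > 0,
    linear = rep.int(TRUE, nrow(meanvar)))
  keep <- keep & is.finite(meanvar$mean_rate) & is.finite(meanvar$var_rate)
  use <- meanvar[keep, , drop = FALSE]
  n_excluded <- nrow(meanvar) - nrow(use)
  if (nrow(use) < 3)
    stop_domain("taylor_fit: fewer than 3 usable records (%d after excluding %d)",
                nrow(use), n_excluded)
  fit <- switch(model,
    power = stats::lm(log(var_rate) ~ log(mean_rate), data = use),
    linear = stats::lm(var_rate ~ mean_rate, data = use),
    exponential = stats::lm(log(var_rate) ~ mean_rate, data = use))
  cf <- stats::coef(fit)
  b <- unname(cf[2])
  if (boot_ci) {
    n <- nrow(use)
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      x <- switch(model, power = log(use$mean_rate[idx]),
                  use$mean_rate[idx])
      y <- if (model == "linear") use$var_rate[idx] else log(use$var_rate[idx])
      ols_simple(x, y)$slope
    }, numeric(1)))
    ci <- stats::quantile(bs, c((1 - conf_level) / 2, (1 + conf_level) / 2),
                          names = FALSE)
  } else {
    ci <- unname(stats::confint(fit, level = conf_level)[2, ])
  }
  structure(list(call = match.call(),
                 model_form = model,
                 exponent_b = b,
                 log_intercept = unname(cf[1]),
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
                 ci_method = if (boot_ci) "bootstrap" else "t",
                 r_squared = summary(fit)$r.squared,
                 n_cells = nrow(use), n_excluded = n_excluded,
                 stratum = stratum, data = use, lm = fit),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, digits = 3, ...) {
  lab <- switch(x$model_form,
                power = "var = a * mean^b (log-log OLS)",
                linear = "var = a + b * mean",
                exponential = "log(var) = a + b * mean")
  cat("Taylor's-law fit:", lab, "\n")
  if (!is.null(x$stratum)) cat("  stratum:", format(x$stratum), "\n")
  cat(sprintf("  exponent b = %.*f  [%.*f, %.*f] (%d%% %s CI)\n",
              digits, x$exponent_b, digits, x$ci_low, digits, x$ci_high,
              round(100 * x$conf_level), x$ci_method))
  if (x$model_form == "power")
    cat(sprintf("  intercept a = %.*g  (log_intercept = %.*f)\n",
                digits, exp(x$log_intercept), digits, x$log_intercept))
  else
    cat(sprintf("  intercept a = %.*g\n", digits, x$log_intercept))
  cat(sprintf("  R^2 = %.*f on %d cells (%d excluded)\n",
              digits, x$r_squared, x$n_cells, x$n_excluded))
  invisible(x)
}

#' @export
summary.taylor_fit <- function(object, ...) {
  s <- summary(object$lm)
  structure(list(fit = object, coefficients = s$coefficients,
                 sigma = s$sigma, r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared), class = "summary.taylor_fit")
}

#' @export
print.summary.taylor_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (fitted response space):\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.taylor_fit <- function(object, ...) {
  c(log_intercept = object$log_intercept, exponent_b = object$exponent_b)
}

#' @export
confint.taylor_fit <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$lm, level = level)
}

#' Predict the temporal variance at new mean rates
#'
#' @param object A [taylor_fit()] object.
#' @param newdata Data frame with a `mean_rate` column (defaults to the
#'   fitting data).
#' @param ... Unused.
#' @return Predicted variance on the original (untransformed) scale.
#' @export
predict.taylor_fit <- function(object, newdata = NULL, ...) {
  m <- if (is.null(newdata)) object$data$mean_rate else newdata$mean_rate
  a <- object$log_intercept
  b <- object$exponent_b
  switch(object$model_form,
         power = exp(a) * m^b,
         linear = a + b * m,
         exponential = exp(a + b * m))
}

#' @export
residuals.taylor_fit <- function(object, ...) stats::residuals(object$lm, ...)

#' Plot a Taylor's-law fit
#'
#' Scatter of per-cell variance against mean with the fitted curve; both
#' axes are log-scaled for the power form.
#'
#' @param x A [taylor_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.taylor_fit <- function(x, ...) {
  d <- x$data
  loglog <- x$model_form == "power"
  graphics::plot(d$mean_rate, d$var_rate,
                 log = if (loglog) "xy" else "",
                 xlab = "mean disturbance rate (% / yr)",
                 ylab = "temporal variance (%^2)",
                 main = sprintf("Taylor's law (%s): b = %.2f",
                                x$model_form, x$exponent_b), ...)
  m <- seq(min(d$mean_rate), max(d$mean_rate), length.out = 200)
  graphics::lines(m, predict(x, data.frame(mean_rate = m)), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate mean-variance tables from a fitted Taylor's law
#'
#' Parametric simulation from a power-law fit: each cell's annual rates
#' are drawn iid from a log-normal distribution with the cell's mean and a
#' variance given by the fitted law, then per-cell sample means and
#' variances are recomputed. Useful as a parametric bootstrap of the fit.
#'
#' @param object A [taylor_fit()] object with `model_form = "power"`.
#' @param nsim Number of replicate tables.
#' @param seed Optional integer seed.
#' @param mean_rate Cell mean rates to simulate at (defaults to the
#'   fitting data).
#' @param n_years Annual draws per cell (default 35).
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `mean_rate`,
#'   `var_rate`.
#' @export
simulate.taylor_fit <- function(object, nsim = 1, seed = NULL,
                                mean_rate = NULL, n_years = 35, ...) {
  if (object$model_form != "power")
    stop_domain("simulate.taylor_fit: only the power form is generative")
  m <- if (is.null(mean_rate)) object$data$mean_rate else mean_rate
  sd <- sqrt(predict(object, data.frame(mean_rate = m)))
  cal <- calibrate_lognormal(m, sd)
  k <- length(m)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    x <- matrix(exp(rep(cal$mu, each = n_years) +
                      rep(cal$sigma, each = n_years) *
                      stats::rnorm(n_years * k)),
                nrow = n_years, ncol = k)
    data.frame(mean_rate = colMeans(x), var_rate = col_vars(x))
  }))
}
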