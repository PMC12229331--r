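#' Probability of exceeding a disturbance-rate threshold
#'
#' Closed-form upper-tail probability that the annual disturbance rate
#' exceeds `threshold` under the Taylor-scaled log-normal model: the
#' variance at a given mean is `intercept_a * mean^exponent_b`, the
#' log-normal is moment-calibrated (see [calibrate_lognormal()]), and the
#' tail is \eqn{1 - \Phi((\log T - \mu)/\sigma)}. With `intercept_a = 0`
#' the rate is deterministic and the probability is the step function
#' `mean > threshold`.
#'
#' @param mean_rate Mean annual disturbance rate(s), \% per year, > 0.
#' @param intercept_a Taylor intercept `a` (>= 0).
#' @param exponent_b Taylor exponent `b`.
#' @param threshold Threshold rate(s), \% per year, > 0.
#' @return Exceedance probability in `[0, 1]`, vectorized over
#'   `mean_rate`/`threshold`.
#' @examples
#' a <- calibrate_intercept(2, 2.2, 5, 0.016)
#' exceedance_probability(2, a, 2.2, 2.5)  # ~ 0.24
#' @export
exceedance_probability <- function(mean_rate, intercept_a, exponent_b,
                                   threshold) {
  if (any(!is.finite(mean_rate)) || any(mean_rate <= 0))
    stop_domain("exceedance_probability: mean_rate must be > 0")
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop_domain("exceedance_probability: threshold must be > 0")
  if (intercept_a < 0)
    stop_domain("exceedance_probability: intercept_a must be >= 0")
  k <- max(length(mean_rate), length(threshold))
  mean_rate <- rep_len(mean_rate, k)
  threshold <- rep_len(threshold, k)
  if (intercept_a == 0) return(as.numeric(mean_rate > threshold))
  sd <- sqrt(intercept_a * mean_rate^exponent_b)
  cal <- calibrate_lognormal(mean_rate, sd)
  1 - stats::pnorm((log(threshold) - cal$mu) / cal$sigma)
}

#' Recover the Taylor intercept from a target exceedance probability
#'
#' Inverts the forward model of [exceedance_probability()]: finds the
#' intercept `a` such that the Taylor-scaled log-normal with the given
#' mean and exponent exceeds `threshold` with probability `target_prob`.
#' With \eqn{z = \Phi^{-1}(1 - p)} the log-scale SD solves the quadratic
#' \deqn{0.5\sigma^2 - z\sigma + \log(T/\bar{x}) = 0,}
#' and \eqn{a = \bar{x}^{2-b}(e^{\sigma^2} - 1)}. The smaller positive
#' \eqn{\sigma} root is used (the larger root implies a coefficient of
#' variation far outside the empirical mean-variance range). For
#' `threshold > mean` the target probability cannot exceed
#' \eqn{1 - \Phi(\sqrt{2 \log(T/\bar{x})})}; an infeasible target raises
#' an error naming that maximum.
#'
#' @inheritParams exceedance_probability
#' @param target_prob Target exceedance probability in (0, 1).
#' @return The intercept `a`, with the solved log-scale `sigma` attached
#'   as an attribute.
#' @examples
#' # anchor: >5% rate every 62 years (p = 1.6%) at mean 2%/yr, b = 2.2
#' calibrate_intercept(2, 2.2, 5, 0.016)  # ~ 0.227
#' @export
calibrate_intercept <- function(mean_rate, exponent_b, threshold,
                                target_prob) {
  if (!is.finite(mean_rate) || mean_rate <= 0)
    stop_domain("calibrate_intercept: mean_rate must be > 0")
  if (!is.finite(threshold) || threshold <= 0)
    stop_domain("calibrate_intercept: threshold must be > 0")
  if (!is.finite(target_prob) || target_prob <= 0 || target_prob >= 1)
    stop_domain("calibrate_intercept: target_prob must be in (0, 1)")
  z <- stats::qnorm(1 - target_prob)
  c0 <- log(threshold / mean_rate)
  disc <- z^2 - 2 * c0
  if (disc < 0)
    stop_domain(paste0(
      "calibrate_intercept: target_prob %.4g is not attainable; the maximum ",
      "exceedance probability for threshold/mean = %.4g is %.4g"),
      target_prob, threshold / mean_rate,
      1 - stats::pnorm(sqrt(2 * c0)))
  roots <- c(z - sqrt(disc), z + sqrt(disc))
  roots <- roots[roots > 0]
  if (length(roots) == 0)
    stop_domain("calibrate_intercept: no positive sigma root (is threshold <= mean with target_prob < 0.5?)")
  sigma <- min(roots)
  a <- mean_rate^(2 - exponent_b) * (exp(sigma^2) - 1)
  structure(a, sigma = sigma)
}

#' Exceedance probabilities over a scenario grid
#'
#' Evaluates the probability of an annual disturbance rate above each
#' threshold for each mean rate, under Taylor-scaled log-normal dynamics.
#' The default grid is means of 0.5, 1 and 2 \% per year against
#' thresholds of 1.0, 2.5 and 5.0 \%, with exponent 2.2. Probabilities are
#' computed in closed form; setting `n_draws` additionally reports a
#' Monte-Carlo estimate from that many log-normal draws per scenario.
#'
#' @inheritParams exceedance_probability
#' @param mean_rates,thresholds Scenario grid (\% per year).
#' @param n_draws Optional Monte-Carlo draws per scenario (e.g. 10000).
#' @param seed Optional integer seed for the Monte Carlo.
#' @return Data frame with one row per (mean, threshold): `mean_rate`,
#'   `threshold`, `intercept_a`, `exponent_b`, `prob_analytic`, `prob_mc`
#'   (NA without Monte Carlo), `mc_n_draws`, `return_period` (years,
#'   `1/prob_analytic`), `seed`.
#' @export
exceedance_table <- function(mean_rates = c(0.5, 1, 2),
                             thresholds = c(1.0, 2.5, 5.0),
                             intercept_a, exponent_b = 2.2,
                             n_draws = NULL, seed = NULL) {
  grid <- expand.grid(mean_rate = mean_rates, threshold = thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$mean_rate, grid$threshold), , drop = FALSE]
  p <- exceedance_probability(grid$mean_rate, intercept_a, exponent_b,
                              grid$threshold)
  pmc <- rep(NA_real_, nrow(grid))
  if (!is.null(n_draws)) {
    sd <- sqrt(intercept_a * grid$mean_rate^exponent_b)
    pmc <- vapply(seq_len(nrow(grid)), function(i) {
      with_seed(if (is.null(seed)) NULL else spawn_seed(seed, i, stream = 9L), {
        mean(rlnorm_calibrated(n_draws, grid$mean_rate[i], sd[i]) >
               grid$threshold[i])
      })
    }, numeric(1))
  }
  data.frame(mean_rate = grid$mean_rate, threshold = grid$threshold,
             intercept_a = as.numeric(intercept_a), exponent_b = exponent_b,
             prob_analytic = p, prob_mc = pmc,
             mc_n_draws = if (is.null(n_draws)) NA_integer_ else as.integer(n_draws),
             return_period = ifelse(p > 0, 1 / p, Inf),
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             row.names = NULL)
}

#' Return period of an annual exceedance probability
#'
#' @param probability Annual probability in (0, 1].
#' @return Expected number of years between events, `1/probability`.
#' @examples
#' return_period(0.0122)  # ~ 82 years
#' @export
return_period <- function(probability) {
  if (any(!is.finite(probability)) || any(probability <= 0) ||
      any(probability > 1))
    stop_domain("return_period: probability must be in (0, 1]")
  1 / probability
}
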