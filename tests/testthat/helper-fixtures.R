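# Shared fixtures, built in code at test time.

# Exact power-law mean-variance table: var = a * mean^b, no noise.
exact_meanvar <- function(means, a = 1, b = 2) {
  data.frame(mean_rate = means, var_rate = a * means^b)
}

# Cell-year rate table in which every cell's series comes from one common
# log-normal distribution (no mean-variance structure beyond sampling).
null_rate_table <- function(n_cells, n_years, mean = 1, sd = 1) {
  cal <- calibrate_lognormal(mean, sd)
  data.frame(cell_id = rep(sprintf("r%04dc0000", seq_len(n_cells) - 1L),
                           each = n_years),
             rate_pct = exp(cal$mu + cal$sigma * rnorm(n_cells * n_years)))
}

# Hand-rolled normal-equations OLS oracle (independent of the package path).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}
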