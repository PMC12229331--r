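#' Permutation null test for the Taylor exponent
#'
#' Tests the fitted power-law exponent against the null hypothesis of no
#' relationship between mean and variance, in which variability arises from
#' sampling alone. The default scheme (`"pooled"`) pools all cell-year
#' rates of the stratum, randomly reassigns them to cells (preserving each
#' cell's number of years), recomputes per-cell means and variances and
#' refits the log-log power law; the observed exponent is compared to the
#' permuted ones with the one-sided, add-one-corrected p-value
#' \deqn{p = (1 + \#\{b_{perm} \ge b_{obs}\}) / (n_{perm} + 1).}
#' The alternative scheme (`"pairs"`) keeps the per-cell mean-variance
#' pairs intact and shuffles the variances against the means across cells.
#'
#' @param rates Cell-year data frame with columns `cell_id` and `rate_pct`
#'   (from [compute_annual_rates()]), for a single stratum.
#' @param n_perm Number of permutations (>= 1; default 999).
#' @param seed Optional integer seed.
#' @param scheme `"pooled"` (default) or `"pairs"`; see Details.
#' @return An object of class `"tl_permutation"` with `observed_b`,
#'   `permuted_b` (length `n_perm`), `p_value`, `n_perm`, `seed`, `scheme`.
#' @export
permutation_null <- function(rates, n_perm = 999, seed = NULL,
                             scheme = c("pooled", "pairs")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_domain("permutation_null: n_perm must be >= 1")
  if (!all(c("cell_id", "rate_pct") %in% names(rates)))
    stop_domain("permutation_null: need cell_id and rate_pct columns")
  x <- rates$rate_pct
  if (length(unique(x)) < 2)
    stop_domain("permutation_null: degenerate stratum (all rates equal)")
  cells <- as.factor(rates$cell_id)

  fit_b <- function(values) {
    n <- as.vector(rowsum(rep.int(1, length(values)), cells))
    s <- as.vector(rowsum(values, cells))
    m <- s / n
    v <- (as.vector(rowsum(values^2, cells)) - n * m^2) / (n - 1)
    ok <- m > 0 & v > 0
    if (sum(ok) < 3) return(NA_real_)
    ols_simple(log(m[ok]), log(v[ok]))$slope
  }

  b_obs <- fit_b(x)
  if (!is.finite(b_obs))
    stop_domain("permutation_null: observed fit failed (fewer than 3 usable cells)")

  perm <- with_seed(seed, {
    if (scheme == "pooled") {
      vapply(seq_len(n_perm), function(i) fit_b(sample(x)), numeric(1))
    } else {
      n <- as.vector(rowsum(rep.int(1, length(x)), cells))
      s <- as.vector(rowsum(x, cells))
      m <- s / n
      v <- (as.vector(rowsum(x^2, cells)) - n * m^2) / (n - 1)
      ok <- m > 0 & v > 0
      lm_ <- log(m[ok]); lv <- log(v[ok])
      vapply(seq_len(n_perm), function(i)
        ols_simple(lm_, sample(lv))$slope, numeric(1))
    }
  })
  p <- (1 + sum(perm >= b_obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(observed_b = b_obs, permuted_b = perm, p_value = p,
                 n_perm = as.integer(n_perm), seed = seed, scheme = scheme),
            class = "tl_permutation")
}

#' @export
print.tl_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%s reshuffle, %d permutations)\n",
              x$scheme, x$n_perm))
  cat(sprintf("  observed b = %.3f; null b range [%.3f, %.3f]\n",
              x$observed_b, min(x$permuted_b), max(x$permuted_b)))
  cat(sprintf("  one-sided p = %.4g\n", x$p_value))
  invisible(x)
}
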