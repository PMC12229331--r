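# Internal numerical helpers shared across modules.

# Deterministic seed spawning: one global seed, independent substreams per
# (index, stream) so that adding cells/stages never reshuffles existing ones.
# All intermediates stay well below 2^53, so the arithmetic is exact.
spawn_seed <- function(seed, index, stream = 0L) {
  s <- as.double(seed) %% 1000003
  as.integer((s * 7919 + as.double(index) * 104729 +
                as.double(stream) * 15485863) %% 2147483646) + 1L
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses the
# current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Closed-form simple linear regression used in permutation/bootstrap hot
# loops; agrees with lm() to machine precision (tested).
ols_simple <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - my)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       se_slope = sqrt(ss_res / (n - 2) / sxx), n = n)
}

# Column means/variances of a matrix (n-1 denominator), avoiding apply().
col_vars <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  (colSums(x^2) - n * m^2) / (n - 1)
}

# Adjusted Fisher-Pearson (bias-corrected) sample skewness G1.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 observations", call. = FALSE)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 <= 0) stop("skewness undefined for zero-variance sample", call. = FALSE)
  g1 <- (sum((x - m)^3) / n) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
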