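#' Fit all three candidate mean-variance models
#'
#' Fits the power, linear and exponential forms (see [taylor_fit()]) to the
#' same records, for model comparison by R-squared. Each model's R-squared
#' is computed in its own fitted response space, so the comparison is
#' indicative rather than strictly like-for-like.
#'
#' @inheritParams taylor_fit
#' @return A named list of three [taylor_fit()] objects, of class
#'   `"taylor_fit_list"`; see [as.data.frame.taylor_fit_list()].
#' @export
fit_alternatives <- function(meanvar, stratum = NULL, conf_level = 0.95) {
  fits <- lapply(c("power", "linear", "exponential"), function(mod)
    taylor_fit(meanvar, model = mod, stratum = stratum,
               conf_level = conf_level))
  names(fits) <- c("power", "linear", "exponential")
  structure(fits, class = "taylor_fit_list")
}

#' Fit Taylor's law separately within strata
#'
#' Splits the mean-variance records by any combination of `agent`, `grain`
#' and `biome` columns and fits the chosen model within each stratum.
#' Strata with fewer than 3 usable cells are skipped with a warning.
#'
#' @inheritParams taylor_fit
#' @param by Character subset of `c("agent", "grain", "biome")` naming the
#'   stratification columns (they must exist in `meanvar`).
#' @return A `"taylor_fit_list"` named by stratum.
#' @export
stratified_fits <- function(meanvar, by = c("agent", "grain"),
                            model = "power", conf_level = 0.95) {
  if (nrow(meanvar) == 0) stop_domain("stratified_fits: empty input")
  if (!all(by %in% names(meanvar)))
    stop_domain("stratified_fits: missing stratification columns: %s",
                paste(setdiff(by, names(meanvar)), collapse = ", "))
  key <- interaction(meanvar[by], drop = TRUE, sep = ":")
  groups <- split(meanvar, key)
  fits <- list()
  for (nm in names(groups)) {
    f <- tryCatch(
      taylor_fit(groups[[nm]], model = model, stratum = nm,
                 conf_level = conf_level),
      error = function(e) {
        warning(sprintf("stratum %s skipped: %s", nm, conditionMessage(e)))
        NULL
      })
    if (!is.null(f)) fits[[nm]] <- f
  }
  structure(fits, class = "taylor_fit_list")
}

#' @export
print.taylor_fit_list <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Flatten a list of Taylor fits into a table
#'
#' @param x A `"taylor_fit_list"` from [fit_alternatives()] or
#'   [stratified_fits()].
#' @param ... Unused.
#' @return Data frame with one row per fit: `stratum`, `model_form`,
#'   `exponent_b`, `log_intercept`, `ci_low`, `ci_high`, `r_squared`,
#'   `n_cells`, `n_excluded`.
#' @export
as.data.frame.taylor_fit_list <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    f <- x[[nm]]
    data.frame(stratum = if (is.null(f$stratum)) nm else f$stratum,
               model_form = f$model_form,
               exponent_b = f$exponent_b,
               log_intercept = f$log_intercept,
               ci_low = f$ci_low, ci_high = f$ci_high,
               r_squared = f$r_squared,
               n_cells = f$n_cells, n_excluded = f$n_excluded,
               stringsAsFactors = FALSE)
  }))
}

#' Select the best-fitting spatial grain
#'
#' Given power-law fits of the same agent at several grains, returns the
#' grain whose fit has the highest R-squared; ties break towards the
#' coarser grain.
#'
#' @param fits Either a `"taylor_fit_list"` whose elements carry a numeric
#'   `grain` in their fitting data, or a data frame with columns `grain`
#'   and `r_squared`.
#' @return The selected grain (km^2).
#' @export
select_best_grain <- function(fits) {
  if (inherits(fits, "taylor_fit_list")) {
    if (length(fits) == 0) stop_domain("select_best_grain: no fits")
    tab <- data.frame(
      grain = vapply(fits, function(f) unique(f$data$grain)[1], numeric(1)),
      r_squared = vapply(fits, function(f) f$r_squared, numeric(1)))
  } else {
    tab <- as.data.frame(fits)
  }
  if (nrow(tab) == 0) stop_domain("select_best_grain: no fits")
  if (!all(c("grain", "r_squared") %in% names(tab)))
    stop_domain("select_best_grain: need grain and r_squared")
  best <- tab$grain[tab$r_squared == max(tab$r_squared)]
  max(best)
}
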