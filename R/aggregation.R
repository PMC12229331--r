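# Grid aggregation and per-cell temporal moments.

# cell_id convention: "r<row>c<col>" on a 0-based regular grid.
parse_cell_id <- function(cell_id) {
  m <- regmatches(cell_id, regexec("^r([0-9]+)c([0-9]+)$", cell_id))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop_domain("cell_id not of the form r<row>c<col>: %s",
                paste(utils::head(unique(cell_id[bad]), 5), collapse = ", "))
  data.frame(row = as.integer(vapply(m, `[`, character(1), 2)),
             col = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Compute annual disturbance rates
#'
#' Converts cell-year areas into annual disturbance rates: the total area
#' disturbed in a year divided by the forest area of the same cell,
#' expressed as a percentage. Cells with non-positive forest area have an
#' undefined rate and are dropped with a warning (they are not treated as
#' rate 0).
#'
#' @param records Cell-year data frame with columns `cell_id`, `year`,
#'   `agent`, `biome`, `forest_area_ha`, `disturbed_area_ha`.
#' @return The input rows with positive forest area, with an added
#'   `rate_pct` column in `[0, 100]`.
#' @export
compute_annual_rates <- function(records) {
  need <- c("cell_id", "year", "agent", "biome",
            "forest_area_ha", "disturbed_area_ha")
  if (!all(need %in% names(records)))
    stop_domain("compute_annual_rates: missing columns: %s",
                paste(setdiff(need, names(records)), collapse = ", "))
  drop <- !(records$forest_area_ha > 0)
  if (any(drop)) {
    warning(sprintf("compute_annual_rates: excluded %d rows with forest_area <= 0",
                    sum(drop)))
    records <- records[!drop, , drop = FALSE]
  }
  records$rate_pct <- 100 * records$disturbed_area_ha / records$forest_area_ha
  records
}

#' Aggregate cell-year records to a coarser spatial grain
#'
#' Merges blocks of fine grid cells into coarser cells by summing disturbed
#' and forest areas, following the dyadic scheme of doubling the cell width
#' (grain areas 100, 400, 1600, 6400, 25600 km^2 for a 10 km base grid).
#' Totals are exactly conserved, so the coarse rate equals the
#' area-weighted mean of the fine rates.
#'
#' @param records Cell-year data frame (see [compute_annual_rates()]) at
#'   the fine grain, with `cell_id` of the form `r<row>c<col>`.
#' @param target_grain Target cell area in km^2; must be
#'   `fine_grain * 4^k` for integer `k >= 0`.
#' @param fine_grain Cell area of the input grid in km^2 (default 100).
#' @return Cell-year data frame at the target grain. Blocks are anchored at
#'   grid position (0, 0); the biome of a merged cell is the most frequent
#'   biome among its fine cells (alphabetical tie-break).
#' @export
aggregate_to_grain <- function(records, target_grain, fine_grain = 100) {
  if (target_grain < fine_grain)
    stop_domain("aggregate_to_grain: target grain %g is finer than input grain %g",
                target_grain, fine_grain)
  factor <- sqrt(target_grain / fine_grain)
  k <- log2(factor)
  if (abs(k - round(k)) > 1e-9)
    stop_domain("aggregate_to_grain: target %g is not fine_grain * 4^k (cell width must double)",
                target_grain)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(records)
  pos <- parse_cell_id(records$cell_id)
  block_id <- sprintf("r%04dc%04d", pos$row %/% factor, pos$col %/% factor)
  key <- paste(block_id, records$year, records$agent, sep = "\r")
  forest <- rowsum(records$forest_area_ha, key)
  disturbed <- rowsum(records$disturbed_area_ha, key)
  first_idx <- match(rownames(forest), key)
  out <- data.frame(cell_id = block_id[first_idx],
                    year = records$year[first_idx],
                    agent = records$agent[first_idx],
                    stringsAsFactors = FALSE)
  out$forest_area_ha <- as.vector(forest)
  out$disturbed_area_ha <- as.vector(disturbed)
  # modal biome per merged cell (table() is alphabetical, which.max takes
  # the first maximum, so ties break alphabetically)
  biome_by_block <- tapply(records$biome, block_id,
                           function(b) names(which.max(table(b))))
  out$biome <- as.character(biome_by_block[out$cell_id])
  out[order(out$cell_id, out$year, out$agent),
      c("cell_id", "year", "agent", "biome",
        "forest_area_ha", "disturbed_area_ha")]
}

#' Per-cell temporal mean and variance of disturbance rates
#'
#' Computes, for every cell (within agent and biome), the sample mean and
#' sample variance (n-1 denominator) of its annual disturbance rates over
#' the series.
#'
#' @param rates Cell-year data frame with a `rate_pct` column (from
#'   [compute_annual_rates()]).
#' @param grain Optional grain label (km^2) attached as a column.
#' @return Data frame with one row per (cell, agent, biome): `cell_id`,
#'   `agent`, `biome`, `grain`, `mean_rate` (\% per year), `var_rate`
#'   (squared \%), `n_years`.
#' @export
mean_variance <- function(rates, grain = NA_real_) {
  if (!"rate_pct" %in% names(rates))
    stop_domain("mean_variance: no rate_pct column; run compute_annual_rates() first")
  ks <- paste(rates$cell_id, rates$agent, rates$biome, sep = "\r")
  n <- as.vector(rowsum(rep.int(1, length(ks)), ks))
  if (any(n < 2))
    stop_domain("mean_variance: every cell needs at least 2 years (min found: %d)",
                min(n))
  sums <- rowsum(rates$rate_pct, ks)
  m <- as.vector(sums) / n
  # two-pass variance for numerical accuracy
  centred <- rates$rate_pct - m[match(ks, rownames(sums))]
  v <- as.vector(rowsum(centred^2, ks)) / (n - 1)
  first_idx <- match(rownames(sums), ks)
  data.frame(cell_id = rates$cell_id[first_idx],
             agent = rates$agent[first_idx],
             biome = rates$biome[first_idx],
             grain = grain,
             mean_rate = m,
             var_rate = v,
             n_years = n,
             stringsAsFactors = FALSE)
}
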