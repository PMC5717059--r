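# Landscape population projection: habitat-class densities x forest-area
# tables -> adults, breeding females, secure-source-population status, and
# change over time.

#' Canonical habitat class names
#' @return Character vector of the five habitat classes.
#' @export
habitat_classes <- function() {
  c("primary_montane", "primary_lowland_hill", "primary_peat",
    "degraded_lowland_hill", "degraded_peat")
}

#' Habitat-specific densities from a baseline and multiplicative effects
#'
#' Densities per 100 km^2 for the five habitat classes, composed
#' multiplicatively from a primary lowland/hill baseline, a peat/montane
#' multiplier and a degradation multiplier (degraded peat receives both).
#' Defaults correspond to a 49.9% peat/montane deficit and a 31.9%
#' degradation deficit on the meta-regression log scale.
#'
#' @param baseline Density of primary lowland/hill forest, per 100 km^2.
#' @param peat_montane_mult Multiplier for peat and montane classes.
#' @param degraded_mult Multiplier for degraded classes.
#' @param relative_se Relative SE attached to projections (scalar).
#' @return A `density_by_habitat`: named numeric vector over
#'   [habitat_classes()] with attribute `relative_se`.
#' @export
habitat_densities <- function(baseline, peat_montane_mult = 0.501,
                              degraded_mult = 0.681, relative_se = 0.469) {
  stopifnot(baseline >= 0, peat_montane_mult >= 0, degraded_mult >= 0)
  d <- c(
    primary_montane = baseline * peat_montane_mult,
    primary_lowland_hill = baseline,
    primary_peat = baseline * peat_montane_mult,
    degraded_lowland_hill = baseline * degraded_mult,
    degraded_peat = baseline * peat_montane_mult * degraded_mult
  )
  structure(d, relative_se = relative_se, class = "density_by_habitat")
}

#' Project habitat-specific densities onto a landscape area table
#'
#' adults = sum over classes of area_km2 * density / 100 per landscape;
#' per-landscape SE = relative SE x adults; breeding females =
#' round-half-up(adults / 2.9). Totals sum adults and SEs linearly.
#'
#' @param table Long-format data frame with columns `landscape`, `class`
#'   (values in [habitat_classes()]), `area_km2`, and optionally `epoch`.
#' @param dens A [habitat_densities()] vector (or named vector covering
#'   every class present).
#' @return Data frame per landscape (and epoch, if present): `adults`,
#'   `se_adults`, `breeding_females`.
#' @export
project_population <- function(table, dens) {
  stopifnot(all(c("landscape", "class", "area_km2") %in% names(table)),
            all(table$area_km2 >= 0, na.rm = TRUE))
  miss <- setdiff(unique(table$class), names(dens))
  if (length(miss)) {
    stop("no density supplied for habitat class(es): ",
         paste(miss, collapse = ", "))
  }
  rel_se <- attr(dens, "relative_se") %||% 0
  table$contrib <- table$area_km2 * unname(dens[table$class]) / 100
  keys <- if ("epoch" %in% names(table)) c("landscape", "epoch") else
    "landscape"
  agg <- stats::aggregate(table["contrib"], table[keys], sum)
  names(agg)[names(agg) == "contrib"] <- "adults"
  agg$se_adults <- rel_se * agg$adults
  agg$breeding_females <- breeding_females(agg$adults)
  agg
}

#' Breeding females from adult abundance
#'
#' Applies the camera-trap ratio of 1 breeding female per `ratio` total
#' tigers (default 2.9), rounding half up.
#'
#' @param adults Adult abundance (>= 0).
#' @param ratio Total animals per breeding female.
#' @return Integer count(s).
#' @export
#' @examples
#' breeding_females(c(140, 52))  # 48, 18
breeding_females <- function(adults, ratio = 2.9) {
  stopifnot(all(adults >= 0))
  as.integer(round_half_up(adults / ratio))
}

#' Classify a landscape as a secure source population
#'
#' TRUE iff the landscape holds more than 25 breeding females, has a core
#' forest area larger than 1000 km^2, and is near other forests holding at
#' least another 25 breeding females. "Nearby" is supplied by the caller
#' (adjacency is a management judgement, not computed from geometry here).
#'
#' @param bf Breeding females in the landscape.
#' @param core_forest_km2 Core forest area, km^2.
#' @param nearby_bf Breeding females in nearby forests.
#' @return Logical.
#' @export
classify_ssp <- function(bf, core_forest_km2, nearby_bf) {
  stopifnot(all(bf >= 0), all(core_forest_km2 >= 0), all(nearby_bf >= 0))
  bf > 25 & core_forest_km2 > 1000 & nearby_bf >= 25
}

#' Percent change between two epochs
#'
#' `(before - after) / before * 100`, reported to one decimal place
#' (positive = decline).
#'
#' @param before,after Values at the earlier and later epoch; `before > 0`.
#' @return Percent change, one decimal.
#' @export
#' @examples
#' percent_change(742, 618)  # 16.7
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("`before` must be > 0")
  round_half_up((before - after) / before * 100, 1)
}

#' Back-cast an area from a loss percentage
#'
#' Given an end-of-period area and the percent lost over the period,
#' returns the start-of-period area: `area / (1 - loss/100)`.
#'
#' @param area_end Area at the end of the period.
#' @param loss_pct Percent lost over the period (0 <= loss < 100).
#' @return Start-of-period area.
#' @export
backcast_area <- function(area_end, loss_pct) {
  if (any(loss_pct < 0) || any(loss_pct >= 100)) {
    stop("`loss_pct` must be in [0, 100)")
  }
  area_end / (1 - loss_pct / 100)
}

#' Derive the baseline habitat density from published tables
#'
#' The source tables print landscape adult abundances and habitat-class
#' areas but never the habitat-specific densities behind them. This
#' recovers the primary lowland/hill baseline by least squares through the
#' origin: adults_l ~ baseline x (effective class-weighted area_l / 100),
#' with the class weights fixed at the multiplicative meta-regression
#' effects. Only landscapes whose class areas are unambiguous are used.
#'
#' @param areas Long area table (default [sumatra_forest_areas()]), 2012
#'   epoch, with an `ambiguous` flag.
#' @param pops Population table (default [sumatra_population_table()]).
#' @param peat_montane_mult,degraded_mult Class multipliers.
#' @return Baseline density per 100 km^2, with attribute `n_landscapes`.
#' @export
derive_baseline_density <- function(areas = sumatra_forest_areas(),
                                    pops = sumatra_population_table(),
                                    peat_montane_mult = 0.501,
                                    degraded_mult = 0.681) {
  a <- areas[!areas$ambiguous & areas$epoch == 2012, ]
  w <- habitat_densities(1, peat_montane_mult, degraded_mult)
  a$eff <- a$area_km2 * unname(w[a$class]) / 100
  eff <- stats::aggregate(a["eff"], a["landscape"], sum)
  m <- merge(eff, pops[, c("landscape", "adults_2012")], by = "landscape")
  if (nrow(m) < 3) stop("too few unambiguous landscapes to fit")
  b <- sum(m$eff * m$adults_2012) / sum(m$eff^2)
  structure(b, n_landscapes = nrow(m))
}
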