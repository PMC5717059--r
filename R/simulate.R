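# Spatially explicit survey simulator: homogeneous-Poisson activity
# centers and half-normal Bernoulli detections at proximity detectors.

#' Configuration for a simulated spatial capture-recapture survey
#'
#' @param region Numeric length-4 `c(xmin, xmax, ymin, ymax)` in planar km:
#'   the state space over which activity centers are placed.
#' @param true_density Animals per 100 km^2 (> 0, or 0 for an empty
#'   population).
#' @param g0 Per-occasion detection probability at distance zero (0 < g0 < 1).
#' @param sigma_km Half-normal spatial scale ("movement parameter"), km > 0.
#' @param n_occasions Number of sampling occasions K (>= 1).
#' @param seed Integer master seed.
#' @return A `survey_config` list.
#' @export
survey_config <- function(region, true_density, g0, sigma_km, n_occasions,
                          seed = 1L) {
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3])
  if (!is.numeric(true_density) || true_density < 0) {
    stop("`true_density` must be >= 0 (animals per 100 km^2)")
  }
  if (!is.numeric(g0) || g0 <= 0 || g0 >= 1) stop("`g0` must be in (0, 1)")
  if (!is.numeric(sigma_km) || sigma_km <= 0) stop("`sigma_km` must be > 0")
  if (n_occasions < 1) stop("`n_occasions` must be >= 1")
  structure(list(region = as.numeric(region), true_density = true_density,
                 g0 = g0, sigma_km = sigma_km,
                 n_occasions = as.integer(n_occasions),
                 seed = as.integer(seed)),
            class = "survey_config")
}

#' @noRd
region_area_km2 <- function(region) {
  (region[2] - region[1]) * (region[4] - region[3])
}

#' Simulate activity centers from a homogeneous Poisson process
#'
#' The number of centers is Poisson with mean `true_density * area / 100`
#' and locations are uniform over the rectangular state space.
#'
#' @param config A [survey_config()].
#' @return An `activity_centers` object: matrix of coordinates with the
#'   region and expected count as attributes.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(derive_seed(config$seed, "population"))
  mu <- config$true_density * region_area_km2(config$region) / 100
  n <- stats::rpois(1, mu)
  xy <- cbind(
    x_km = stats::runif(n, config$region[1], config$region[2]),
    y_km = stats::runif(n, config$region[3], config$region[4])
  )
  structure(xy, region = config$region, expected_n = mu,
            class = c("activity_centers", "matrix", "array"))
}

#' Simulate a capture history with half-normal detection
#'
#' Each animal x detector x occasion is an independent Bernoulli trial with
#' p = g0 exp(-d^2 / (2 sigma^2)), d the distance from the animal's
#' activity center to the detector (binary proximity detectors: several
#' animals may be recorded at one detector on one occasion). Only detected
#' individuals appear in the returned history.
#'
#' A warning is issued when the state space does not extend at least
#' 4 sigma beyond the detector hull, since edge effects then bias density
#' estimation.
#'
#' @param centers An `activity_centers` object (or 2-column matrix).
#' @param traps A `trap_array`.
#' @param g0,sigma_km,n_occasions Detection parameters as in
#'   [survey_config()].
#' @param seed Integer seed.
#' @return A `capture_history`: list with `detections` (individuals x traps
#'   x occasions binary array), `traps`, `n_occasions`, and the number of
#'   simulated (including undetected) animals as attribute `n_simulated`.
#' @export
simulate_captures <- function(centers, traps, g0, sigma_km, n_occasions,
                              seed = 1L) {
  if (!is.numeric(g0) || g0 <= 0 || g0 >= 1) stop("`g0` must be in (0, 1)")
  if (!is.numeric(sigma_km) || sigma_km <= 0) stop("`sigma_km` must be > 0")
  xy <- unclass(centers)
  tm <- as_trap_matrix(traps)
  region <- attr(centers, "region")
  if (!is.null(region)) {
    margin <- min(min(tm[, 1]) - region[1], region[2] - max(tm[, 1]),
                  min(tm[, 2]) - region[3], region[4] - max(tm[, 2]))
    if (margin < 4 * sigma_km) {
      warning(sprintf(
        "state space extends only %.1f km beyond the trap array (< 4 sigma = %.1f km)",
        margin, 4 * sigma_km))
    }
  }
  set.seed(seed)
  n <- nrow(xy); J <- nrow(tm); K <- as.integer(n_occasions)
  if (n == 0) {
    return(new_capture_history(array(0L, dim = c(0, J, K)), traps, K, n))
  }
  d2 <- outer(xy[, 1], tm[, 1], "-")^2 + outer(xy[, 2], tm[, 2], "-")^2
  p <- g0 * exp(-d2 / (2 * sigma_km^2))  # n x J
  det <- array(stats::rbinom(n * J * K, 1L, rep(as.vector(p), K)),
               dim = c(n, J, K))
  caught <- apply(det, 1, max) > 0
  det <- det[caught, , , drop = FALSE]
  if (sum(caught)) {
    dimnames(det) <- list(sprintf("A%03d", which(caught)),
                          traps$trap_id, NULL)
  }
  new_capture_history(det, traps, K, n)
}

#' @noRd
new_capture_history <- function(detections, traps, n_occasions, n_simulated = NA) {
  out <- list(detections = detections, traps = traps,
              n_occasions = as.integer(n_occasions))
  attr(out, "n_simulated") <- n_simulated
  class(out) <- "capture_history"
  validate_capture_history(out)
}

#' @noRd
validate_capture_history <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  d <- ch$detections
  stopifnot(length(dim(d)) == 3, dim(d)[3] == ch$n_occasions,
            dim(d)[2] == nrow(ch$traps))
  if (dim(d)[1] > 0 && any(apply(d, 1, sum) == 0)) {
    stop("every individual in a capture history must have >= 1 detection")
  }
  ch
}

#' @export
print.capture_history <- function(x, ...) {
  d <- dim(x$detections)
  cat(sprintf("Capture history: %d individuals x %d traps x %d occasions, %d detections\n",
              d[1], d[2], d[3], sum(x$detections)))
  invisible(x)
}

#' Number of individuals in a capture history
#' @param ch A `capture_history`.
#' @return Integer count of distinct detected individuals (M_t+1).
#' @export
n_individuals <- function(ch) dim(ch$detections)[1]

# individuals x traps matrix of detection counts (over occasions)
#' @noRd
capture_counts <- function(ch) {
  apply(ch$detections, c(1, 2), sum)
}

#' Configuration for a simulated multi-study density dataset
#'
#' Defaults emulate the structure recovered by the meta-regression: a
#' baseline log density for primary lowland/hill forest, multiplicative
#' deficits for peat/montane forest and for logged landscapes, a small
#' positive annual time trend, landscape-level random effects, and
#' log-normal observation noise whose scale is each record's relative
#' standard error.
#'
#' @param n_landscapes Number of landscapes.
#' @param estimates_per_landscape Integer range (length-2) of estimates per
#'   landscape, sampled uniformly.
#' @param beta0 Baseline log density (log animals per 100 km^2).
#' @param effect_peatmontane,effect_logged,effect_year Log-scale
#'   coefficients. Defaults correspond to a 49.9% peat/montane deficit, a
#'   31.9% logging deficit, and a 4.9%/yr increase.
#' @param tau Landscape random-effect standard deviation (log scale, >= 0).
#' @param relative_se_range Interval for each record's simulated relative
#'   standard error; must lie in (0, 1.5).
#' @param year_range Calendar years sampled uniformly; the model centers
#'   year at 1996.
#' @param seed Integer seed.
#' @return A `meta_sim_config` list.
#' @export
meta_sim_config <- function(n_landscapes = 60,
                            estimates_per_landscape = c(1, 3),
                            beta0 = log(1.12),
                            effect_peatmontane = log(0.501),
                            effect_logged = log(0.681),
                            effect_year = 0.048,
                            tau = 0.15,
                            relative_se_range = c(0.3, 0.9),
                            year_range = c(1996, 2014),
                            seed = 1L) {
  stopifnot(n_landscapes >= 2, length(estimates_per_landscape) == 2,
            estimates_per_landscape[1] >= 1)
  if (tau < 0) stop("`tau` must be >= 0")
  if (relative_se_range[1] <= 0 || relative_se_range[2] >= 1.5 ||
      relative_se_range[1] > relative_se_range[2]) {
    stop("`relative_se_range` must lie within (0, 1.5)")
  }
  structure(as.list(environment()), class = "meta_sim_config")
}

#' Simulate a multi-study density dataset
#'
#' Generates study-level density records with the structure the
#' meta-regression assumes: true log density is a linear function of forest
#' type, disturbance and (centered) year plus a landscape random intercept;
#' the observed log density adds Normal noise with standard deviation equal
#' to the record's relative SE. All records within a landscape share one
#' random-effect draw and one set of landscape covariates.
#'
#' @param config A [meta_sim_config()].
#' @return Data frame of density records with both observed and generating
#'   quantities (`density`, `se_density`, `true_density`,
#'   `landscape_effect`, covariates, and CR bookkeeping columns usable by
#'   the standardization stage).
#' @export
simulate_meta_dataset <- function(config = meta_sim_config()) {
  stopifnot(inherits(config, "meta_sim_config"))
  set.seed(derive_seed(config$seed, "meta-dataset"))
  L <- config$n_landscapes
  n_per <- sample(seq(config$estimates_per_landscape[1],
                      config$estimates_per_landscape[2]), L, replace = TRUE)
  u <- stats::rnorm(L, 0, config$tau)
  forest_type <- sample(c("lowland-hill", "peat-montane"), L, TRUE,
                        prob = c(0.7, 0.3))
  disturbance <- sample(c("primary", "logged"), L, TRUE)
  rows <- vector("list", L)
  id <- 0L
  for (l in seq_len(L)) {
    n <- n_per[l]
    year <- round(stats::runif(n, config$year_range[1], config$year_range[2]))
    eta <- config$beta0 +
      config$effect_peatmontane * (forest_type[l] == "peat-montane") +
      config$effect_logged * (disturbance[l] == "logged") +
      config$effect_year * (year - 1996)
    s <- stats::runif(n, config$relative_se_range[1],
                      config$relative_se_range[2])
    y <- eta + u[l] + stats::rnorm(n, 0, s)
    dens <- exp(y)
    method <- sample(c("CR", "SCR"), n, TRUE)
    mcp <- stats::runif(n, 100, 800)
    side <- sqrt(mcp)                      # square-grid summary geometry
    buffer <- ifelse(method == "CR", stats::runif(n, 2, 7),
                     stats::runif(n, 9, 14))
    area <- dilated_area(mcp, 4 * side, buffer)
    n_hat <- ifelse(method == "CR", dens * area / 100, NA_real_)
    rows[[l]] <- data.frame(
      study_id = sprintf("SIM%03d", id + seq_len(n)),
      landscape = sprintf("L%03d", l),
      year = year, method = method,
      density = dens, se_density = s * dens,
      true_density = exp(eta + u[l]),
      landscape_effect = u[l],
      forest_type = forest_type[l], disturbance = disturbance[l],
      deforestation_rate = stats::runif(n, 0, 4),
      n_hat = n_hat, se_n = s * n_hat,
      mcp_area_km2 = mcp, mcp_perimeter_km = 4 * side,
      original_buffer_km = buffer,
      trap_days = round(stats::runif(n, 1500, 6000)),
      n_cameras = round(stats::runif(n, 30, 90)),
      stringsAsFactors = FALSE
    )
    id <- id + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
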