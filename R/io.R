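# Readers/writers for the table formats, run configuration, and the
# end-to-end pipeline runner. CSV dialect: UTF-8, comma separator, header
# mandatory, decimal point. Coordinates are always planar km (no CRS).

STUDIES_MANDATORY <- c("study_id", "landscape", "year", "method",
                       "density", "se_density")
STUDIES_NUMERIC <- c("year", "density", "se_density", "n_hat", "se_n",
                     "mcp_area_km2", "mcp_perimeter_km",
                     "original_buffer_km", "deforestation_rate",
                     "trap_days", "n_cameras")

#' Read a studies table of density records
#'
#' Validates the mandatory columns, coerces the numeric columns (rows with
#' malformed numbers are collected into one error report naming the rows),
#' preserves unknown columns, and flags which CR records are correctable
#' (abundance and hull geometry present).
#'
#' @param path CSV path.
#' @return Data frame of density records with a `correctable` column.
#' @export
read_studies_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(STUDIES_MANDATORY, names(raw))
  if (length(missing)) {
    stop("studies table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- character(0)
  for (cl in intersect(STUDIES_NUMERIC, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    malformed <- which(!is.na(raw[[cl]]) & raw[[cl]] != "" & is.na(v))
    if (length(malformed)) {
      bad <- c(bad, sprintf("column %s, row(s) %s", cl,
                            paste(malformed, collapse = ", ")))
    }
    raw[[cl]] <- v
  }
  if (length(bad)) {
    stop("malformed numeric value(s): ", paste(bad, collapse = "; "))
  }
  if (!all(raw$method %in% c("CR", "SCR", "corrected"))) {
    stop("`method` must be one of CR, SCR, corrected")
  }
  raw$correctable <- raw$method == "CR" &
    !is.na(raw$n_hat %||% NA) &
    !is.na(raw$mcp_area_km2 %||% NA) &
    !is.na(raw$mcp_perimeter_km %||% NA)
  raw
}

#' Write a studies table
#' @param studies Data frame of density records.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_studies_table <- function(studies, path) {
  utils::write.csv(studies, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a trap layout CSV (`session`, `trap_id`, `x_km`, `y_km`)
#' @param traps A `trap_array`.
#' @param path CSV path.
#' @return The path (write) or a `trap_array` (read).
#' @export
write_traps_csv <- function(traps, path) {
  utils::write.csv(traps[, c("session", "trap_id", "x_km", "y_km")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_traps_csv
#' @export
read_traps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("session", "trap_id", "x_km", "y_km") %in% names(d)))
  class(d) <- c("trap_array", "data.frame")
  d
}

#' Write / read a capture CSV (`session`, `individual_id`, `occasion`,
#' `trap_id`)
#'
#' The long format stores one row per detection; `read_captures_csv`
#' rebuilds the binary individuals x traps x occasions array against a
#' trap layout.
#'
#' @param ch A `capture_history` (write) .
#' @param path CSV path.
#' @param traps A `trap_array` (read).
#' @param n_occasions Number of occasions (read; detections beyond it are
#'   rejected).
#' @param session Session label.
#' @return The path (write) or a `capture_history` (read).
#' @export
write_captures_csv <- function(ch, path, session = "S1") {
  idx <- which(ch$detections == 1L, arr.ind = TRUE)
  ids <- dimnames(ch$detections)[[1]] %||%
    sprintf("A%03d", seq_len(dim(ch$detections)[1]))
  d <- data.frame(session = session,
                  individual_id = ids[idx[, 1]],
                  occasion = idx[, 3],
                  trap_id = ch$traps$trap_id[idx[, 2]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$individual_id, d$occasion, d$trap_id), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_captures_csv
#' @export
read_captures_csv <- function(path, traps, n_occasions) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("session", "individual_id", "occasion", "trap_id") %in%
                  names(d)))
  if (any(d$occasion < 1 | d$occasion > n_occasions)) {
    stop("occasion outside 1..n_occasions")
  }
  if (!all(d$trap_id %in% traps$trap_id)) {
    stop("unknown trap_id in captures: ",
         paste(setdiff(d$trap_id, traps$trap_id), collapse = ", "))
  }
  ids <- sort(unique(d$individual_id))
  arr <- array(0L, dim = c(length(ids), nrow(traps), n_occasions),
               dimnames = list(ids, traps$trap_id, NULL))
  arr[cbind(match(d$individual_id, ids), match(d$trap_id, traps$trap_id),
            d$occasion)] <- 1L
  new_capture_history(arr, traps, n_occasions)
}

#' Default run configuration
#'
#' All pipeline constants with their defaults: the 1.96 sigma standard
#' buffer and 2.45 sigma home-range multipliers, the 2.9 breeding-female
#' ratio, secure-source-population thresholds, survey simulation settings,
#' and optimizer tolerances. Every run writes its resolved configuration
#' alongside the outputs.
#'
#' @param ... Overrides of the defaults (unknown names are rejected).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    buffer_quantile_mult = 1.96,
    home_range_quantile_mult = 2.45,
    bf_ratio = 2.9,
    ssp_min_bf = 25,
    ssp_min_core_km2 = 1000,
    survey = list(grid_rows = 8, grid_cols = 8, spacing_km = 1.5,
                  true_density = 2, g0 = 0.05, sigma_km = 2.5,
                  n_occasions = 90, region_margin_sigma = 4),
    mask_cell_km = 1.0,
    meta_terms = c("forest_type", "disturbance"),
    meta_method = "ML",
    n_meta_landscapes = 60,
    optim_reltol = 1e-10
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, ov)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file with a subset of [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, ov)
}

#' Run the full pipeline on simulated inputs
#'
#' Executes simulate -> fit (SCR) -> standardize -> meta-regression ->
#' project, writing every stage's outputs and a machine-readable manifest
#' (file names and MD5 hashes) into `out_dir`. Deterministic under a fixed
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
pipeline_run <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
    p
  }
  sv <- config$survey
  # stage 1: simulate one survey
  traps <- place_traps(sv$grid_rows, sv$grid_cols, sv$spacing_km)
  ext <- sv$region_margin_sigma * sv$sigma_km
  region <- c(min(traps$x_km) - ext, max(traps$x_km) + ext,
              min(traps$y_km) - ext, max(traps$y_km) + ext)
  scfg <- survey_config(region, sv$true_density, sv$g0, sv$sigma_km,
                        sv$n_occasions, seed = config$seed)
  centers <- simulate_population(scfg)
  ch <- simulate_captures(centers, traps, sv$g0, sv$sigma_km,
                          sv$n_occasions,
                          seed = derive_seed(config$seed, "captures"))
  paths <- c(paths, write_traps_csv(traps, file.path(out_dir, "traps.csv")))
  if (n_individuals(ch) > 0) {
    paths <- c(paths,
               write_captures_csv(ch, file.path(out_dir, "captures.csv")))
  }
  # stage 2: SCR fit -> standard buffer
  mask <- make_mask(traps, ext, cell_km = config$mask_cell_km)
  fit <- fit_scr(list(list(capthist = ch, mask = mask)))
  sigma_hat <- unname(scr_coef(fit, "sigma"))
  buffer <- config$buffer_quantile_mult * sigma_hat
  save_json(list(
    estimates = fit$estimates[, c("parameter", "estimate", "se")],
    loglik = fit$loglik, sigma_hat_km = sigma_hat,
    standard_buffer_km = buffer,
    home_range_km2 = home_range_area(sigma_hat,
                                     config$home_range_quantile_mult)
  ), "scr_fit.json")
  # stage 3: simulated studies table, standardized with the fitted buffer
  studies <- simulate_meta_dataset(meta_sim_config(
    n_landscapes = config$n_meta_landscapes,
    seed = derive_seed(config$seed, "meta")))
  std <- standardize_studies(studies, buffer)
  paths <- c(paths,
             write_studies_table(std, file.path(out_dir, "standardized.csv")))
  # stage 4: meta-regression
  mfit <- fit_meta_lmm(meta_records(std), config$meta_terms,
                       method = config$meta_method)
  save_json(list(beta = mfit$beta, tau2 = mfit$tau2,
                 sigma2_eps = mfit$sigma2_eps, loglik = mfit$loglik,
                 aicc = aicc(mfit), marginal_r2 = marginal_r2(mfit)),
            "meta_fit.json")
  # stage 5: projection onto the packaged landscape table
  base <- exp(mfit$beta$estimate[mfit$beta$term == "(Intercept)"])
  pm <- exp_or_default(mfit, "forest_typepeat-montane")
  dg <- exp_or_default(mfit, "disturbancelogged")
  dens <- habitat_densities(base, pm, dg,
                            relative_se = mean(meta_records(std)$s))
  areas <- sumatra_forest_areas()
  proj <- project_population(areas[!areas$ambiguous, ], dens)
  p <- file.path(out_dir, "projection.csv")
  utils::write.csv(proj, p, row.names = FALSE)
  paths <- c(paths, p)
  save_json(unclass(config), "config.json")
  manifest <- list(
    files = lapply(stats::setNames(nm = basename(paths)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))),
    seed = config$seed
  )
  save_json(manifest, "manifest.json")
  invisible(manifest)
}

#' @noRd
exp_or_default <- function(fit, term, default = 1) {
  i <- match(term, fit$beta$term)
  if (is.na(i)) default else exp(fit$beta$estimate[i])
}
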