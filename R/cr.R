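# Non-spatial closed-population capture-recapture: M0 abundance,
# movement-based buffers, and the density quotient D = N / A.

#' M0 log-likelihood
#'
#' Closed-population likelihood with constant detection probability:
#' L(N, p) = N! / (N - M)! * p^n (1 - p)^(NK - n), where M is the number of
#' distinct individuals, K the number of occasions and n the total number
#' of individual-occasion captures. N is treated as continuous via the
#' gamma function.
#'
#' @param N Abundance (>= M).
#' @param p Per-occasion capture probability in (0, 1).
#' @param m Distinct individuals M_t+1.
#' @param n_capt Total individual-occasion captures.
#' @param k Occasions.
#' @return Log-likelihood value.
#' @export
m0_loglik <- function(N, p, m, n_capt, k) {
  if (N < m || p <= 0 || p >= 1) return(-Inf)
  lgamma(N + 1) - lgamma(N - m + 1) + n_capt * log(p) +
    (N * k - n_capt) * log(1 - p)
}

#' Closed-population M0 abundance estimate
#'
#' Maximizes the M0 likelihood over continuous N >= M_t+1 (profiling
#' p_hat = n / (N K)); the standard error comes from the observed
#' information matrix in (N, logit p). When every individual is caught on
#' every occasion the likelihood is maximized at the boundary p = 1,
#' N = M_t+1, and a zero-variance warning is issued.
#'
#' @param history A `capture_history`.
#' @return An `abundance_estimate`: list with `n_hat`, `se_n`, `m_t1`,
#'   `p_hat`, `k`, `model_tag`.
#' @export
#' @examples
#' tr <- place_traps(2, 2, 1)
#' det <- array(0L, dim = c(3, 4, 4))
#' det[cbind(1:3, 1:3, 1:3)] <- 1L  # three animals caught once each
#' # estimate_abundance_m0 needs >= 2 occasions with partial detection
estimate_abundance_m0 <- function(history) {
  stopifnot(inherits(history, "capture_history"))
  m <- n_individuals(history)
  k <- history$n_occasions
  if (m == 0) stop("no detections: M0 abundance is undefined")
  if (k < 2) stop("at least 2 occasions are required to identify p")
  # occasion-level captures (caught anywhere on the grid that occasion)
  occ <- apply(history$detections, c(1, 3), max)
  n_capt <- sum(occ)
  if (n_capt == m * k) {
    warning("all individuals caught on all occasions: p_hat = 1 boundary, zero-variance N_hat = M_t+1")
    return(new_abundance(m, 0, m, 1, k))
  }
  prof <- function(N) m0_loglik(N, n_capt / (N * k), m, n_capt, k)
  upper <- m
  while (prof(upper * 2 + 10) > prof(upper) && upper < m * 1e6) {
    upper <- upper * 2 + 10
  }
  opt <- stats::optimize(prof, interval = c(m, upper * 2 + 10), maximum = TRUE,
                         tol = 1e-9)
  n_hat <- opt$maximum
  # when capture probability is high the maximum sits at N = M_t+1, where
  # the factorial term has an infinite derivative: report the boundary
  if (n_hat < m + 1e-6 || prof(m) >= prof(n_hat)) {
    est <- new_abundance(m, 0, m, n_capt / (m * k), k)
    attr(est, "boundary") <- TRUE
    return(est)
  }
  p_hat <- n_capt / (n_hat * k)
  neg <- function(par) {
    -m0_loglik(par[1], stats::plogis(par[2]), m, n_capt, k)
  }
  se_n <- tryCatch({
    h <- pracma::hessian(neg, c(n_hat, stats::qlogis(p_hat)))
    v <- solve(h)
    sqrt(max(v[1, 1], 0))
  }, error = function(e) NA_real_)
  new_abundance(n_hat, se_n, m, p_hat, k)
}

#' @noRd
new_abundance <- function(n_hat, se_n, m, p_hat, k, tag = "M0") {
  structure(list(n_hat = n_hat, se_n = se_n, m_t1 = m, p_hat = p_hat,
                 k = k, model_tag = tag),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("%s abundance: N_hat = %.2f (SE %.2f), M_t+1 = %d, p_hat = %.3f over %d occasions\n",
              x$model_tag, x$n_hat, x$se_n, x$m_t1, x$p_hat, x$k))
  invisible(x)
}

#' Mean maximum distance moved between capture locations
#'
#' For each individual detected at two or more distinct detectors, the
#' maximum pairwise distance between its capture locations; MMDM is the
#' mean of those maxima. Half of it (see [half_mmdm()]) is the traditional
#' non-spatial buffer width.
#'
#' @param history A `capture_history`.
#' @return MMDM in km, with the number of contributing individuals as
#'   attribute `n_moved`.
#' @export
mmdm <- function(history) {
  stopifnot(inherits(history, "capture_history"))
  cc <- capture_counts(history)
  tm <- as_trap_matrix(history$traps)
  maxima <- c()
  for (i in seq_len(nrow(cc))) {
    at <- which(cc[i, ] > 0)
    if (length(at) >= 2) {
      maxima <- c(maxima, max(stats::dist(tm[at, , drop = FALSE])))
    }
  }
  if (length(maxima) == 0) {
    stop("MMDM undefined: no individual was recaptured at a second detector")
  }
  structure(mean(maxima), n_moved = length(maxima))
}

#' @rdname mmdm
#' @export
half_mmdm <- function(history) {
  out <- mmdm(history)
  structure(as.numeric(out) / 2, n_moved = attr(out, "n_moved"))
}

#' Non-spatial capture-recapture density
#'
#' D_hat = N_hat / A_hat expressed per 100 km^2, with the standard error
#' inherited from N_hat: SE(D) = SE(N) / A. The relative SE of the density
#' therefore equals that of the abundance exactly.
#'
#' @param n_hat An `abundance_estimate` (or list with `n_hat`, `se_n`).
#' @param area An `effective_area` (or list with `area_km2`).
#' @param ... Extra columns stored on the record (e.g. `landscape`,
#'   `year`).
#' @return One-row data frame (`density_estimate`) with `method = "CR"`,
#'   `density`, `se_density` (per 100 km^2), and the area bookkeeping.
#' @export
cr_density <- function(n_hat, area, ...) {
  if (area$area_km2 <= 0) stop("effective area must be positive")
  d <- n_hat$n_hat / area$area_km2 * 100
  se <- n_hat$se_n / area$area_km2 * 100
  out <- data.frame(method = "CR", n_hat = n_hat$n_hat, se_n = n_hat$se_n,
                    mcp_area_km2 = area$mcp_area_km2,
                    mcp_perimeter_km = area$mcp_perimeter_km,
                    original_buffer_km = area$buffer_km,
                    area_km2 = area$area_km2,
                    density = d, se_density = se,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("density_estimate", "data.frame")
  out
}
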