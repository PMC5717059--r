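# Weighted mixed-model meta-regression of log standardized densities.
#
# Response: y = log(density). Each record carries a known relative SE
# s = se_density / density, which is the sampling SE of y on the log scale.
# Default variance model ("scaled" convention, matching lmer-style
# weights): Var(y_i) = sigma2_eps * s_i^2 + tau2 within-landscape
# clustering through a landscape random intercept. The meta-analytic
# fixed-known-variance convention Var(y_i) = s_i^2 + tau2 is available as
# `variance = "fixed"`.

#' Build meta-regression records from a studies table
#'
#' Computes the log-density response and its known relative SE, and the
#' covariate encodings used throughout: forest type baseline
#' `"lowland-hill"`, disturbance baseline `"primary"`, year centered at
#' 1996.
#'
#' @param studies Data frame with `density`, `se_density`, `landscape`, and
#'   any covariates among `forest_type`, `disturbance`, `year`,
#'   `deforestation_rate`.
#' @return Data frame with `y`, `s`, `landscape` and encoded covariates.
#' @export
meta_records <- function(studies) {
  stopifnot(all(c("density", "se_density", "landscape") %in% names(studies)))
  keep <- is.finite(studies$density) & studies$density > 0 &
    is.finite(studies$se_density) & studies$se_density > 0
  d <- studies[keep, , drop = FALSE]
  out <- data.frame(
    y = log(d$density),
    s = d$se_density / d$density,
    landscape = as.character(d$landscape),
    stringsAsFactors = FALSE
  )
  if (!is.null(d$forest_type)) {
    out$forest_type <- factor(d$forest_type,
                              levels = c("lowland-hill", "peat-montane"))
  }
  if (!is.null(d$disturbance)) {
    out$disturbance <- factor(d$disturbance, levels = c("primary", "logged"))
  }
  if (!is.null(d$year)) out$year_c <- d$year - 1996
  if (!is.null(d$deforestation_rate)) {
    out$deforestation_rate <- d$deforestation_rate
  }
  out
}

#' @noRd
meta_design <- function(records, fixed_terms) {
  if (length(fixed_terms) == 0) {
    X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    terms <- gsub("^year$", "year_c", fixed_terms)
    missing <- setdiff(terms, names(records))
    if (length(missing)) stop("unknown covariate(s): ",
                              paste(missing, collapse = ", "))
    f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    X <- stats::model.matrix(f, records)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; aliased terms among: ",
         paste(colnames(X), collapse = ", "))
  }
  X
}

# Gaussian (RE)ML objective with GLS-profiled beta. Returns the fit pieces.
#' @noRd
meta_gls <- function(y, X, s, landscape, sigma2, tau2, reml = FALSE) {
  n <- length(y)
  Z <- stats::model.matrix(~ 0 + factor(landscape))
  V <- diag(sigma2 * s^2, n) + tau2 * tcrossprod(Z)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  q <- sum(r * Vi_r)
  ll <- -0.5 * (n * log(2 * pi) + logdetV + q)
  if (reml) {
    p <- ncol(X)
    ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * determinant(XtViX)$modulus[1]
  }
  list(ll = ll, beta = drop(beta), vcov_beta = solve(XtViX), fitted = drop(X %*% beta))
}

#' Fit a weighted mixed-model meta-regression
#'
#' Maximizes the Gaussian likelihood of log densities with known relative
#' SEs, a landscape random intercept, and fixed effects given by
#' `fixed_terms`. Beta is profiled out by generalized least squares inside
#' a low-dimensional optimization over the variance parameters; the
#' tau2 = 0 boundary is checked explicitly and reported with a flag.
#'
#' @param records Data frame from [meta_records()] (columns `y`, `s`,
#'   `landscape`, covariates), or a studies table (auto-converted).
#' @param fixed_terms Character vector of covariate names (empty for
#'   intercept-only). `"year"` is accepted as shorthand for the centered
#'   `year_c`.
#' @param method `"ML"` (default; required for LRT/AICc) or `"REML"`.
#' @param variance `"scaled"` (default): Var = sigma2_eps s^2 + tau2, two
#'   variance parameters; `"fixed"`: Var = s^2 + tau2, one variance
#'   parameter (classical meta-analysis convention).
#' @param fix_tau2 Optional fixed value for the landscape variance
#'   (e.g. `0` to drop the random intercept); it is then not counted as an
#'   estimated parameter.
#' @return A `meta_fit`: list with `beta` (data frame: term, estimate, se,
#'   z, p), `tau2`, `sigma2_eps`, `loglik`, `method`, `variance`, `n`,
#'   `n_varpar`, `boundary`, plus the design pieces used.
#' @export
fit_meta_lmm <- function(records, fixed_terms = character(0),
                         method = c("ML", "REML"),
                         variance = c("scaled", "fixed"),
                         fix_tau2 = NULL) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  if (!all(c("y", "s") %in% names(records))) records <- meta_records(records)
  stopifnot(all(is.finite(records$y)), all(records$s > 0))
  if (length(unique(records$landscape)) < 2) {
    stop("at least 2 landscapes are required")
  }
  y <- records$y; s <- records$s; g <- records$landscape
  X <- meta_design(records, fixed_terms)
  reml <- method == "REML"
  # crude initial scale from a weighted residual variance
  w0 <- 1 / s^2
  b00 <- solve(crossprod(X, w0 * X), crossprod(X, w0 * y))
  v0 <- max(sum(w0 * (y - X %*% b00)^2) / length(y), 1e-4)
  if (!is.null(fix_tau2)) {
    stopifnot(fix_tau2 >= 0)
    if (variance == "scaled") {
      o <- stats::optimize(function(ls2)
        -meta_gls(y, X, s, g, exp(ls2), fix_tau2, reml)$ll,
        c(log(v0) - 15, log(v0) + 15))
      sigma2 <- exp(o$minimum)
    } else sigma2 <- 1
    fit <- meta_gls(y, X, s, g, sigma2, fix_tau2, reml)
    se <- sqrt(diag(fit$vcov_beta))
    z <- fit$beta / se
    beta <- data.frame(term = colnames(X), estimate = unname(fit$beta),
                       se = unname(se), z = unname(z),
                       p = unname(2 * stats::pnorm(-abs(z))),
                       stringsAsFactors = FALSE)
    return(structure(list(
      beta = beta, tau2 = fix_tau2, sigma2_eps = sigma2, loglik = fit$ll,
      method = method, variance = variance, n = length(y),
      n_varpar = if (variance == "scaled") 1L else 0L,
      boundary = FALSE, fixed_terms = fixed_terms, X = X, y = y, s = s,
      landscape = g, fitted = fit$fitted, vcov_beta = fit$vcov_beta),
      class = "meta_fit"))
  }
  obj <- function(phi) {
    if (variance == "scaled") {
      -meta_gls(y, X, s, g, exp(phi[1]), exp(phi[2]), reml)$ll
    } else {
      -meta_gls(y, X, s, g, 1, exp(phi[1]), reml)$ll
    }
  }
  if (variance == "scaled") {
    starts <- list(log(c(v0, v0 / 2)), log(c(v0 / 2, v0)), log(c(1, 0.05)))
  } else {
    starts <- list(log(v0), log(v0 / 4), log(0.05))
  }
  best <- NULL
  if (variance == "fixed") {
    o <- stats::optimize(obj, c(log(v0) - 18, log(v0) + 8))
    best <- list(par = o$minimum, value = o$objective)
  } else {
    for (st in starts) {
      o <- tryCatch(stats::optim(st, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  }
  if (is.null(best)) stop("meta-regression variance optimization failed")
  phi <- best$par
  if (variance == "scaled") {
    sigma2 <- exp(phi[1]); tau2 <- exp(phi[2])
  } else {
    sigma2 <- 1; tau2 <- exp(phi[1])
  }
  # boundary check: profile with tau2 = 0
  bobj <- function(ls2) -meta_gls(y, X, s, g, exp(ls2), 0, reml)$ll
  ob <- if (variance == "scaled") {
    stats::optimize(bobj, c(log(v0) - 12, log(v0) + 12))
  } else {
    list(objective = -meta_gls(y, X, s, g, 1, 0, reml)$ll,
         minimum = 0)
  }
  boundary <- FALSE
  if (ob$objective <= best$value + 1e-8 || tau2 < 1e-10) {
    boundary <- TRUE
    tau2 <- 0
    if (variance == "scaled") sigma2 <- exp(ob$minimum)
  }
  fit <- meta_gls(y, X, s, g, sigma2, tau2, reml)
  se <- sqrt(diag(fit$vcov_beta))
  z <- fit$beta / se
  beta <- data.frame(term = colnames(X), estimate = unname(fit$beta),
                     se = unname(se), z = unname(z),
                     p = unname(2 * stats::pnorm(-abs(z))),
                     stringsAsFactors = FALSE)
  structure(list(beta = beta, tau2 = tau2, sigma2_eps = sigma2,
                 loglik = fit$ll, method = method, variance = variance,
                 n = length(y), n_varpar = if (variance == "scaled") 2L else 1L,
                 boundary = boundary, fixed_terms = fixed_terms,
                 X = X, y = y, s = s, landscape = g, fitted = fit$fitted,
                 vcov_beta = fit$vcov_beta),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Meta-regression mixed model (%s, %s variance), n = %d, logLik = %.3f\n",
              x$method, x$variance, x$n, x$loglik))
  print(x$beta, row.names = FALSE, digits = 4)
  cat(sprintf("tau2 (landscape) = %.4f%s, sigma2_eps = %.4f\n", x$tau2,
              if (x$boundary) " [boundary]" else "", x$sigma2_eps))
  invisible(x)
}

#' Likelihood-ratio test between nested meta-regression fits
#'
#' @param fit_null,fit_alt `meta_fit` objects fitted by ML on the same
#'   records, with the null's fixed effects nested in the alternative's.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "meta_fit"), inherits(fit_alt, "meta_fit"))
  if (fit_null$method != "ML" || fit_alt$method != "ML") {
    stop("LRT requires ML fits (REML likelihoods with different fixed effects are not comparable)")
  }
  if (fit_null$n != fit_alt$n) stop("fits use different numbers of records")
  k0 <- ncol(fit_null$X); k1 <- ncol(fit_alt$X)
  if (k1 < k0) stop("`fit_alt` must be the larger model")
  chi2 <- max(2 * (fit_alt$loglik - fit_null$loglik), 0)
  df <- k1 - k0
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Small-sample corrected AIC for a meta-regression fit
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), with k counting fixed effects
#' plus variance parameters (tau2 and, under the scaled convention,
#' sigma2_eps).
#'
#' @param fit A `meta_fit` fitted by ML.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  if (fit$method != "ML") stop("AICc is computed from ML fits")
  k <- ncol(fit$X) + fit$n_varpar
  n <- fit$n
  if (n <= k + 1) stop("n must exceed k + 1 for the AICc correction")
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Marginal R-squared of a meta-regression fit
#'
#' Variance of the fixed-effect predictions divided by the total modeled
#' variance (fixed + landscape random intercept + mean residual sampling
#' variance). Lies in \[0, 1).
#'
#' @param fit A `meta_fit`.
#' @return Marginal R-squared.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  vf <- mean((fit$fitted - mean(fit$fitted))^2)
  resid_var <- if (fit$variance == "scaled") {
    fit$sigma2_eps * mean(fit$s^2)
  } else {
    mean(fit$s^2)
  }
  vf / (vf + fit$tau2 + resid_var)
}

#' Convert a log-scale coefficient to a percent effect
#'
#' `(exp(beta) - 1) * 100`. With `rebase = TRUE` returns the effect seen
#' from the other side of the contrast, `(1 / exp(beta) - 1) * 100` (e.g. a
#' -31.9% logging deficit re-bases to +46.8% for primary forest).
#'
#' @param beta_log Log-scale coefficient(s).
#' @param rebase Logical; invert the contrast direction.
#' @return Percent effect(s).
#' @export
#' @examples
#' effect_percent(log(0.681))            # -31.9
#' effect_percent(log(0.681), rebase = TRUE)  # +46.8
effect_percent <- function(beta_log, rebase = FALSE) {
  stopifnot(is.finite(beta_log))
  if (rebase) (1 / exp(beta_log) - 1) * 100 else (exp(beta_log) - 1) * 100
}
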