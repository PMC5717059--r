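# Shared numerical helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published population tables round
#' half up (e.g. 52 adults / 2.9 = 17.93 -> 18). This helper matches that
#' convention for non-negative inputs.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(17.5)  # 18
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise log-sum-exp of a matrix
#' @noRd
col_log_sum_exp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
}

#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one master seed and a stage label, so replicates and stages are
#' independently reproducible. The result always fits in a 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"population"`, `"captures.7"`).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 7919) %% 2147483629L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
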