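# Shared fixtures, all built in code.

# capture history from an individuals x traps x occasions array
toy_history <- function(det, traps) {
  tigertrend:::new_capture_history(det, traps, dim(det)[3])
}

# history with given per-individual occasion-capture patterns at chosen
# traps: `at` is a list, one entry per individual, of trap indices visited
# on successive occasions (0 = not caught that occasion)
history_from_visits <- function(at, traps, n_occasions) {
  det <- array(0L, dim = c(length(at), nrow(traps), n_occasions))
  for (i in seq_along(at)) {
    v <- at[[i]]
    for (k in seq_along(v)) if (v[k] > 0) det[i, v[k], k] <- 1L
  }
  toy_history(det, traps)
}

# brute-force M0 maximizer: profile p over a fine continuous-N grid
m0_grid_oracle <- function(m, n_capt, k, n_max = 500, step = 1e-3) {
  grid <- seq(m, n_max, by = step)
  ll <- vapply(grid, function(N)
    tigertrend::m0_loglik(N, n_capt / (N * k), m, n_capt, k), 0)
  grid[which.max(ll)]
}

# naive loop-based SCR log-likelihood (independent of the vectorized path)
scr_loglik_oracle <- function(ch, mask, d_per100, g0, sigma) {
  keep <- mask$stratum != "excluded"
  a <- attr(mask, "cell_area_km2")
  mx <- mask$x_km[keep]; my <- mask$y_km[keep]
  tm <- cbind(ch$traps$x_km, ch$traps$y_km)
  K <- ch$n_occasions
  n <- tigertrend::n_individuals(ch)
  Y <- apply(ch$detections, c(1, 2), sum)
  Lambda <- 0
  lam <- rep(0, n)
  for (s in seq_along(mx)) {
    p <- g0 * exp(-((mx[s] - tm[, 1])^2 + (my[s] - tm[, 2])^2) /
                    (2 * sigma^2))
    pdot <- 1 - prod((1 - p)^K)
    Lambda <- Lambda + d_per100 / 100 * a * pdot
    if (n > 0) {
      for (i in seq_len(n)) {
        Pi <- prod(choose(K, Y[i, ]) * p^Y[i, ] * (1 - p)^(K - Y[i, ]))
        lam[i] <- lam[i] + d_per100 / 100 * a * Pi
      }
    }
  }
  if (n == 0) return(-Lambda)
  -Lambda + sum(log(lam)) - lfactorial(n)
}

# standard small survey used by several stochastic tests
default_survey <- function(seed = 1) {
  traps <- tigertrend::place_traps(8, 8, 1.5)
  cfg <- tigertrend::survey_config(c(-10, 20.5, -10, 20.5),
                                   true_density = 2, g0 = 0.05,
                                   sigma_km = 2.5, n_occasions = 90,
                                   seed = seed)
  list(traps = traps, config = cfg)
}
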