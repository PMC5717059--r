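# SCR likelihood and fitting: half-normal kernel, oracle equivalence on
# tiny instances, session/stratum bookkeeping, movement summaries.

test_that("half-normal kernel evaluates exactly", {
  expect_equal(halfnormal_p(0, 0.3, 2), 0.3)
  expect_equal(halfnormal_p(2 * sqrt(2 * log(2)), 0.3, 2), 0.15)
  expect_equal(halfnormal_p(4, 0.1, 2), 0.1 * exp(-2), tolerance = 1e-12)
  expect_error(halfnormal_p(1, 0.1, 0), "sigma")
  expect_error(halfnormal_p(-1, 0.1, 1), ">= 0")
})

test_that("single-cell likelihood matches the closed-form hand expression", {
  tr <- place_traps(2, 1, 100)[1, , drop = FALSE]
  class(tr) <- c("trap_array", "data.frame")
  mask <- data.frame(x_km = 1.2, y_km = 0.5, stratum = "forest")
  class(mask) <- c("habitat_mask", "data.frame")
  attr(mask, "cell_area_km2") <- 4
  K <- 5; y <- 2
  det <- array(0L, dim = c(1, 1, K)); det[1, 1, 1:y] <- 1L
  ch <- toy_history(det, tr)
  D <- 3; g0 <- 0.2; sigma <- 1.5
  p <- g0 * exp(-(1.2^2 + 0.5^2) / (2 * sigma^2))
  pdot <- 1 - (1 - p)^K
  Lambda <- D / 100 * 4 * pdot
  lam <- D / 100 * 4 * choose(K, y) * p^y * (1 - p)^(K - y)
  by_hand <- -Lambda + log(lam) - lfactorial(1)
  pars <- c(logD = log(D), logit_g0 = qlogis(g0), log_sigma = log(sigma))
  got <- scr_loglik(pars, list(list(capthist = ch, mask = mask)))
  expect_equal(got, by_hand, tolerance = 1e-12)
})

test_that("vectorized likelihood equals the naive summation oracle", {
  tr <- place_traps(2, 2, 2)
  mask <- make_mask(tr, 4, cell_km = 0.5)
  # three animals with scattered detections over 4 occasions
  visits <- list(c(1, 2, 0, 1), c(3, 0, 3, 0), c(0, 4, 2, 0))
  ch <- history_from_visits(visits, tr, 4)
  for (pars in list(c(2, 0.3, 1.2), c(5, 0.1, 2), c(0.7, 0.6, 0.8))) {
    got <- scr_loglik(c(logD = log(pars[1]), logit_g0 = qlogis(pars[2]),
                        log_sigma = log(pars[3])),
                      list(list(capthist = ch, mask = mask)))
    want <- scr_loglik_oracle(ch, mask, pars[1], pars[2], pars[3])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("excluded mask cells contribute exactly zero", {
  tr <- place_traps(3, 3, 1.5)
  mask <- make_mask(tr, 3, cell_km = 0.75)
  ch <- history_from_visits(list(c(1, 5, 1), c(9, 0, 9)), tr, 3)
  pars <- c(logD = log(2), logit_g0 = qlogis(0.2), log_sigma = log(1))
  # mark the eastern half excluded vs physically removing those cells
  excl <- mask
  excl$stratum[excl$x_km > 1.6] <- "excluded"
  kept <- mask[mask$x_km <= 1.6, ]
  class(kept) <- class(mask)
  attr(kept, "cell_area_km2") <- attr(mask, "cell_area_km2")
  ll1 <- scr_loglik(pars, list(list(capthist = ch, mask = excl)))
  ll2 <- scr_loglik(pars, list(list(capthist = ch, mask = kept)))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("multi-session likelihood is the sum of session likelihoods", {
  tr <- place_traps(3, 3, 1.5)
  mask <- make_mask(tr, 3, cell_km = 0.75)
  ch1 <- history_from_visits(list(c(1, 5, 1), c(9, 0, 9)), tr, 3)
  ch2 <- history_from_visits(list(c(2, 2, 0), c(0, 6, 7), c(3, 0, 0)), tr, 3)
  pars <- c(logD = log(2), logit_g0 = qlogis(0.2), log_sigma = log(1))
  s1 <- list(capthist = ch1, mask = mask)
  s2 <- list(capthist = ch2, mask = mask)
  expect_equal(scr_loglik(pars, list(s1, s2)),
               scr_loglik(pars, list(s1)) + scr_loglik(pars, list(s2)),
               tolerance = 1e-12)
})

test_that("duplicated sessions with shared parameters leave the MLE fixed", {
  # the two-flank device: two copies of one session constrained to share
  # D, g0, sigma double the log-likelihood, so the maximizer is unchanged
  set.seed(12)
  tr <- place_traps(5, 5, 1.5)
  cfg <- survey_config(c(-8, 14, -8, 14), 4, 0.15, 1.8, 20, seed = 21)
  pop <- simulate_population(cfg)
  ch <- suppressWarnings(simulate_captures(pop, tr, 0.15, 1.8, 20, seed = 22))
  expect_gte(n_individuals(ch), 3)  # this seed yields a usable history
  mask <- make_mask(tr, 6, cell_km = 1)
  s <- list(capthist = ch, mask = mask)
  f1 <- fit_scr(list(s))
  f2 <- fit_scr(list(s, s))
  expect_equal(f2$working$mle, f1$working$mle, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("mask refinement changes the likelihood negligibly", {
  tr <- place_traps(4, 4, 1.5)
  ch <- history_from_visits(list(c(1, 2, 1, 0), c(6, 6, 0, 10),
                                 c(16, 0, 11, 0)), tr, 4)
  pars <- c(logD = log(2), logit_g0 = qlogis(0.15), log_sigma = log(1.5))
  ll_half <- scr_loglik(pars, list(list(capthist = ch,
                                        mask = make_mask(tr, 6, 0.5))))
  ll_quarter <- scr_loglik(pars, list(list(capthist = ch,
                                           mask = make_mask(tr, 6, 0.25))))
  expect_lt(abs(ll_half - ll_quarter), 1e-2)
})

test_that("rescaling coordinates and sigma leaves fitted g0 invariant", {
  set.seed(5)
  tr <- place_traps(4, 4, 1.5)
  cfg <- survey_config(c(-6, 10.5, -6, 10.5), 6, 0.2, 1.2, 15, seed = 31)
  pop <- simulate_population(cfg)
  ch <- suppressWarnings(simulate_captures(pop, tr, 0.2, 1.2, 15, seed = 32))
  expect_gte(n_individuals(ch), 3)
  mask <- make_mask(tr, 4.8, cell_km = 0.6)
  f1 <- fit_scr(list(list(capthist = ch, mask = mask)))
  # scale the world by 3: traps, mask (cell area by 9)
  sc <- function(df, cols) { df[cols] <- df[cols] * 3; df }
  tr3 <- sc(tr, c("x_km", "y_km"))
  ch3 <- ch; ch3$traps <- tr3
  mask3 <- sc(mask, c("x_km", "y_km"))
  attr(mask3, "cell_area_km2") <- attr(mask, "cell_area_km2") * 9
  f3 <- fit_scr(list(list(capthist = ch3, mask = mask3)))
  g1 <- as.numeric(scr_coef(f1, "g0")); g3 <- as.numeric(scr_coef(f3, "g0"))
  expect_equal(g3, g1, tolerance = 1e-3)
  expect_equal(as.numeric(scr_coef(f3, "sigma")),
               3 * as.numeric(scr_coef(f1, "sigma")), tolerance = 1e-3)
  expect_equal(as.numeric(scr_coef(f3, "D")),
               as.numeric(scr_coef(f1, "D")) / 9, tolerance = 1e-3)
})

test_that("home-range and buffer summaries follow their closed forms", {
  expect_equal(round(home_range_area(4.59)), 397)
  expect_equal(home_range_area(1, 1), pi)
  # sqrt of chi-squared(2) 95% quantile is the exact 2-D 95% radius
  expect_equal(sqrt(qchisq(0.95, 2)), 2.4477, tolerance = 1e-4)
  expect_equal(pchisq(2.4477^2, 2), 0.95, tolerance = 1e-4)

  b <- standard_buffer(4.59, 0.95)
  expect_equal(round(as.numeric(b), 1), 9.0)
  expect_equal(round(attr(b, "se"), 2), 1.86)
  expect_equal(standard_buffer(1), 1.96)
  expect_equal(standard_buffer(2 * 3.1), 2 * standard_buffer(3.1))
  expect_error(standard_buffer(0), "> 0")
})

test_that("stratified masks estimate one density per stratum", {
  # two-stratum simulation: western forest at full density, eastern
  # non-forest at a fraction of it
  tr <- place_traps(6, 6, 1.5)
  set.seed(77)
  region <- c(-7.5, 15, -7.5, 15)
  n_f <- rpois(1, 8 / 100 * 11.25 * 22.5)
  n_n <- rpois(1, 2.4 / 100 * 11.25 * 22.5)
  pts <- rbind(
    cbind(runif(n_f, -7.5, 3.75), runif(n_f, -7.5, 15)),
    cbind(runif(n_n, 3.75, 15), runif(n_n, -7.5, 15)))
  centers <- structure(pts, region = region,
                       class = c("activity_centers", "matrix", "array"))
  ch <- suppressWarnings(simulate_captures(centers, tr, 0.3, 1.2, 25,
                                           seed = 78))
  mask <- make_mask(tr, 6, cell_km = 0.75, stratum_fun = function(x, y)
    ifelse(x < 3.75, "forest", "nonforest"))
  fit <- fit_scr(list(list(capthist = ch, mask = mask)))
  d <- scr_coef(fit, "D")
  expect_equal(sort(names(d)), c("logD.forest", "logD.nonforest"))
  expect_gt(d[["logD.forest"]], d[["logD.nonforest"]])
})
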