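# Weighted mixed-model meta-regression: closed-form reductions,
# cross-checks against independent mixed-model implementations, and the
# model-selection machinery.

make_meta_data <- function(n_landscapes = 30, seed = 1, ...) {
  meta_records(simulate_meta_dataset(
    meta_sim_config(n_landscapes = n_landscapes, seed = seed, ...)))
}

test_that("intercept-only fit without clustering is the weighted mean", {
  set.seed(2)
  rec <- data.frame(y = rnorm(12), s = runif(12, 0.2, 1),
                    landscape = paste0("L", 1:12))
  fit <- fit_meta_lmm(rec, character(0), fix_tau2 = 0)
  wm <- sum(rec$y / rec$s^2) / sum(1 / rec$s^2)
  expect_equal(fit$beta$estimate, wm, tolerance = 1e-8)
})

test_that("equal weights without clustering reduce to OLS", {
  set.seed(3)
  rec <- data.frame(y = rnorm(15, 2), s = rep(1, 15),
                    landscape = paste0("L", 1:15))
  fit <- fit_meta_lmm(rec, character(0), fix_tau2 = 0)
  expect_equal(fit$beta$estimate, mean(rec$y), tolerance = 1e-8)
  # ML variance (divisor n)
  expect_equal(fit$sigma2_eps, mean((rec$y - mean(rec$y))^2),
               tolerance = 1e-4)
})

test_that("fit agrees with lme4 under the scaled-weights convention", {
  skip_if_not_installed("lme4")
  d <- make_meta_data(25, seed = 6)
  fit <- fit_meta_lmm(d, c("forest_type", "disturbance", "year"))
  lf <- lme4::lmer(y ~ forest_type + disturbance + year_c +
                     (1 | landscape),
                   data = d, weights = 1 / s^2, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))
  expect_equal(unname(fit$beta$estimate), unname(lme4::fixef(lf)),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_eps, vc$vcov[2], tolerance = 1e-3)
})

test_that("fixed-variance convention agrees with metafor", {
  skip_if_not_installed("metafor")
  d <- make_meta_data(25, seed = 9)
  fit <- fit_meta_lmm(d, c("forest_type", "disturbance"),
                      variance = "fixed")
  mf <- metafor::rma.mv(y, V = s^2,
                        mods = ~ forest_type + disturbance,
                        random = ~ 1 | landscape, data = d, method = "ML")
  expect_equal(unname(fit$beta$estimate), unname(as.numeric(mf$beta)),
               tolerance = 1e-4)
  expect_equal(fit$tau2, mf$sigma2, tolerance = 1e-4)
  expect_equal(unname(fit$beta$se), unname(mf$se), tolerance = 1e-4)
})

test_that("fit is invariant to record ordering", {
  d <- make_meta_data(20, seed = 11)
  f1 <- fit_meta_lmm(d, c("forest_type", "disturbance"))
  set.seed(1); perm <- sample(nrow(d))
  f2 <- fit_meta_lmm(d[perm, ], c("forest_type", "disturbance"))
  expect_equal(f1$beta$estimate, f2$beta$estimate, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the aliased terms", {
  d <- make_meta_data(10, seed = 4)
  d$dup <- as.numeric(d$forest_type == "peat-montane")
  d$forest_num <- d$dup  # perfectly aliased pair
  expect_error(fit_meta_lmm(d, c("dup", "forest_num")), "rank deficient")
  expect_error(fit_meta_lmm(d, "no_such_term"), "unknown covariate")
})

test_that("likelihood-ratio test follows the chi-squared tail", {
  d <- make_meta_data(25, seed = 13)
  f0 <- fit_meta_lmm(d, "forest_type")
  expect_equal(lrt(f0, f0), list(chi2 = 0, df = 0, p_value = 1))
  # manufactured nested fits with a known deviance difference
  f1 <- f0
  f1$loglik <- f0$loglik + 6.46
  f1$X <- cbind(f0$X, z1 = rnorm(nrow(f0$X)), z2 = rnorm(nrow(f0$X)))
  out <- lrt(f0, f1)
  expect_equal(out$chi2, 12.92)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(12.92, 2, lower.tail = FALSE))
  expect_equal(out$p_value, exp(-6.46), tolerance = 1e-10)  # ~0.0016
  fr <- fit_meta_lmm(d, "forest_type", method = "REML")
  expect_error(lrt(fr, f1), "ML")
})

test_that("AICc applies the small-sample correction", {
  fake <- structure(list(loglik = 0, X = matrix(1, 10, 1), n = 10L,
                         n_varpar = 0L, method = "ML"),
                    class = "meta_fit")
  expect_equal(aicc(fake), 2 + 2 * 1 * 2 / 8)  # 2.5
  fake$n <- 2L
  expect_error(aicc(fake), "exceed")
  # AICc exceeds AIC and model selection finds the generating covariate
  d <- make_meta_data(40, seed = 17, effect_year = 0)
  f_true <- fit_meta_lmm(d, c("forest_type", "disturbance"))
  f_null <- fit_meta_lmm(d, character(0))
  expect_gt(aicc(f_true), -2 * f_true$loglik + 2 * (ncol(f_true$X) + 2))
  expect_lt(aicc(f_true), aicc(f_null))
})

test_that("marginal R2 spans its limits", {
  d <- make_meta_data(20, seed = 21)
  f0 <- fit_meta_lmm(d, character(0))
  expect_equal(marginal_r2(f0), 0)
  # strong fixed effects, vanishing noise: R2 near 1
  d2 <- make_meta_data(25, seed = 22, tau = 1e-4,
                       relative_se_range = c(1e-3, 2e-3))
  f2 <- fit_meta_lmm(d2, c("forest_type", "disturbance", "year"))
  r2 <- marginal_r2(f2)
  expect_gt(r2, 0.99); expect_lt(r2, 1)
  f1 <- fit_meta_lmm(d, c("forest_type", "disturbance"))
  expect_gte(marginal_r2(f1), 0); expect_lt(marginal_r2(f1), 1)
})

test_that("percent-effect conversions match their log-scale inverses", {
  expect_equal(round(effect_percent(log(0.681)), 1), -31.9)
  expect_equal(effect_percent(0), 0)
  expect_equal(round(effect_percent(log(0.681), rebase = TRUE), 1), 46.8)
  expect_equal(round(effect_percent(log(0.501)), 1), -49.9)
  expect_equal(round(effect_percent(0.048 * 1), 1), 4.9)
})

test_that("meta-regression recovers generating coefficients", {
  d <- make_meta_data(60, seed = 25)
  fit <- fit_meta_lmm(d, c("forest_type", "disturbance", "year"))
  truth <- c(log(1.12), log(0.501), log(0.681), 0.048)
  ci_lo <- fit$beta$estimate - 1.96 * fit$beta$se
  ci_hi <- fit$beta$estimate + 1.96 * fit$beta$se
  expect_true(all(ci_lo <= truth & truth <= ci_hi))
})
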