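sdm_W <- function() row_standardize(make_lattice_weights(16, "rook"))

test_that("fixing rho = 0 with no Durbin terms reproduces two-way within OLS", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 6, rho = 0.3, beta = c(1, -0.5),
                          phi = c(0.2, 0.1), seed = 3)
  f0 <- fit_sdm(d, "y", c("x1", "x2"), W, lag_x = character(0), rho_fixed = 0)
  ols <- lm(y ~ x1 + x2 + factor(region) + factor(year), data = d)
  expect_equal(unname(f0$beta), unname(coef(ols)[c("x1", "x2")]),
               tolerance = 1e-8)
})

test_that("the concentrated likelihood is maximized at the reported rho", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 8, rho = 0.4, seed = 5)
  f <- fit_sdm(d, "y", c("x1", "x2"), W)
  f0 <- fit_sdm(d, "y", c("x1", "x2"), W, rho_fixed = 0)
  expect_gte(f$loglik, f0$loglik)
  # nearby rho values do not beat the optimum
  fm <- fit_sdm(d, "y", c("x1", "x2"), W, rho_fixed = f$rho - 0.02)
  fp <- fit_sdm(d, "y", c("x1", "x2"), W, rho_fixed = f$rho + 0.02)
  expect_gte(f$loglik, fm$loglik)
  expect_gte(f$loglik, fp$loglik)
})

test_that("effect decomposition matches the analytic special cases", {
  # rho = 0, phi = 0: direct = beta, indirect = 0 exactly
  Wm <- row_standardize(ring4())$w
  ep <- ecoeff:::effect_point(0, c(x1 = 1.7), c(W_x1 = 0), Wm, "x1")
  expect_equal(ep$direct, 1.7)
  expect_equal(ep$indirect, 0)

  # 2-region symmetric W, rho = 0.5, beta = 1, phi = 0:
  # (I - rho W)^{-1} = [[1, .5], [.5, 1]] / 0.75
  W2 <- matrix(c(0, 1, 1, 0), 2)
  ep2 <- ecoeff:::effect_point(0.5, c(x1 = 1), c(W_x1 = 0), W2, "x1")
  expect_equal(ep2$direct, 1 / 0.75)
  expect_equal(ep2$total, 2)
  expect_equal(ep2$indirect, 2 - 1 / 0.75)
})

test_that("total = direct + indirect for every regressor of a real fit", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 8, rho = 0.3, seed = 11)
  f <- fit_sdm(d, "y", c("x1", "x2"), W)
  eff <- effects_decomposition(f, draws = 150, seed = 2)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-9)
  expect_true(all(eff$direct_se > 0))
})

test_that("rho estimates are invariant to a consistent region relabelling", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 6, rho = 0.35, seed = 7)
  f1 <- fit_sdm(d, "y", c("x1", "x2"), W)
  perm <- withr::with_seed(1, sample(16))
  W2 <- eco_weights(W$w[perm, perm], ids = W$ids[perm], standardized = TRUE)
  f2 <- fit_sdm(d, "y", c("x1", "x2"), W2)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-6)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("parameters are recovered with small bias on moderate panels", {
  W <- row_standardize(make_lattice_weights(30, "random-k", k = 4, seed = 2))
  est <- sapply(1:20, function(s) {
    d <- simulate_sdm_panel(W, n_years = 10, rho = 0.3, beta = c(1, 1),
                            phi = c(0.2, 0.2), seed = 100 + s)
    f <- fit_sdm(d, "y", c("x1", "x2"), W)
    c(f$rho, f$beta[1], f$phi[1])
  })
  bias <- rowMeans(est) - c(0.3, 1, 0.2)
  expect_lt(max(abs(bias)), 0.1)
})

test_that("Wald reductions have the right df and detect strong Durbin terms", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 10, rho = 0.3, beta = c(1, 1),
                          phi = c(1.5, 1.5), seed = 13)
  f <- fit_sdm(d, "y", c("x1", "x2"), W)
  wt <- wald_reduction_tests(f)
  expect_equal(wt$df, c(2, 2))
  expect_lt(wt$p[wt$test == "SAR"], 0.01)  # phi = 1.5 is unmissable

  f_sar <- fit_sdm(d, "y", c("x1", "x2"), W, lag_x = character(0))
  expect_error(wald_reduction_tests(f_sar), class = "ecoeff_domain_error")
})

test_that("time-lagged regressors shift the sample and keep the interface", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 8, rho = 0.3, seed = 17)
  f <- fit_sdm(d, "y", c("x1", "x2"), W, xlag_periods = 1)
  expect_equal(f$n_years, 7)
  expect_true(is.finite(f$loglik))
})

test_that("collinear regressors fail with the offending column named", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 6, rho = 0.3, seed = 19)
  d$x3 <- d$x1
  expect_error(fit_sdm(d, "y", c("x1", "x2", "x3"), W, lag_x = character(0)),
               class = "ecoeff_rank_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  W <- sdm_W()
  d <- simulate_sdm_panel(W, n_years = 6, rho = 0.3, seed = 23)
  f <- fit_sdm(d, "y", c("x1", "x2"), W)
  td <- tidy(f)
  expect_setequal(td$term, c("rho", "x1", "x2", "W_x1", "W_x2"))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_equal(gl$nobs, 15 * 5)
  expect_equal(gl$rho, f$rho)
})
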