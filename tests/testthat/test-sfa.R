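cobb_douglas <- function() {
  c(lnx1 = 0.5, lnx2 = 0.3, lnx3 = 0.1, t = 0.02, `(Intercept)` = 1)
}

sim_frontier_panel <- function(seed, n = 30, TT = 10, ...) {
  d <- simulate_panel(n, TT, beta = cobb_douglas(), zero_rest = TRUE,
                      seed = seed, ...)
  X <- translog_design(d[, c("capital", "labour", "energy")], t = d$year,
                       center = TRUE)
  list(data = d, X = X,
       Xcd = X[, c("t", "lnx1", "lnx2", "lnx3", "(Intercept)")])
}

test_that("translog design expands to the 15 stated columns", {
  d <- data.frame(a = c(1, exp(1)), b = c(1, 1), cc = c(1, 1))
  X <- translog_design(d, t = c(0, 1))
  expect_equal(ncol(X), 15)
  expect_equal(unname(X[1, ]), c(rep(0, 14), 1))  # logs of 1 at t = 0
  r2 <- X[2, ]
  expect_equal(unname(r2[c("lnx1", "lnx1_2", "t_lnx1")]), c(1, 1, 1))
  expect_equal(unname(r2[c("lnx1_lnx2", "lnx1_lnx3", "lnx2_lnx3")]), c(0, 0, 0))
  expect_equal(unname(r2[c("t", "t2")]), c(1, 1))
  expect_error(translog_design(data.frame(a = -1, b = 1, cc = 1), t = 1),
               class = "ecoeff_domain_error")
})

test_that("the panel likelihood equals direct numeric integration", {
  yr <- c(1, 2, 3, 1, 2, 3)
  groups <- list(1:3, 4:6)
  eps <- withr::with_seed(42, rnorm(6, 0, 0.5))
  mu <- 0.4; eta <- 0.3; sigma2 <- 0.3; gamma <- 0.6
  su <- sqrt(gamma * sigma2); sv <- sqrt((1 - gamma) * sigma2)
  ll_num <- 0
  for (g in groups) {
    e <- eps[g]; h <- exp(-eta * (yr[g] - max(yr[g])))
    f <- integrate(function(u) {
      sapply(u, function(ui) {
        prod(dnorm(e + h * ui, 0, sv)) * dnorm(ui, mu, su) / pnorm(mu / su)
      })
    }, 0, Inf, rel.tol = 1e-12)$value
    ll_num <- ll_num + log(f)
  }
  expect_equal(ecoeff:::bc92_loglik(eps, groups, yr, mu, eta, sigma2, gamma),
               ll_num, tolerance = 1e-10)
})

test_that("the efficiency predictor equals its conditional-expectation integral", {
  yr <- c(1, 2, 3); groups <- list(1:3)
  eps <- withr::with_seed(9, rnorm(3, 0, 0.4))
  mu <- 0.2; eta <- 0.25; sigma2 <- 0.25; gamma <- 0.55
  su <- sqrt(gamma * sigma2); sv <- sqrt((1 - gamma) * sigma2)
  h <- exp(-eta * (yr - 3))
  num <- integrate(function(u) sapply(u, function(ui) {
    exp(-h[2] * ui) * prod(dnorm(eps + h * ui, 0, sv)) * dnorm(ui, mu, su)
  }), 0, Inf, rel.tol = 1e-12)$value
  den <- integrate(function(u) sapply(u, function(ui) {
    prod(dnorm(eps + h * ui, 0, sv)) * dnorm(ui, mu, su)
  }), 0, Inf, rel.tol = 1e-12)$value
  te <- ecoeff:::bc92_te(eps, groups, yr, mu, eta, sigma2, gamma)
  expect_equal(te[2], num / den, tolerance = 1e-10)
  expect_true(all(te > 0 & te <= 1))
})

test_that("frontier estimates recover decay and inefficiency share", {
  sp <- sim_frontier_panel(1, mu = 0.5, eta = 0.4, sigma2 = 0.2, gamma = 0.6)
  f <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                    starts = 2, seed = 1)
  expect_gt(f$eta, 0)
  expect_equal(f$eta, 0.4, tolerance = 0.1)
  expect_equal(f$gamma, 0.6, tolerance = 0.25)
  expect_true(all(f$te$te > 0 & f$te$te <= 1))
  # TE should rise toward the last period when eta > 0
  te_by_year <- tapply(f$te$te, f$te$year, mean)
  expect_gt(te_by_year[length(te_by_year)], te_by_year[1])
})

test_that("restrictions pin parameters and order log-likelihoods by nesting", {
  sp <- sim_frontier_panel(2, mu = 0.5, eta = 0.4, sigma2 = 0.2, gamma = 0.6)
  full <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                       starts = 2, seed = 1)
  no_eta <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                         restrict = list(eta = 0), starts = 2, seed = 1)
  ols <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                      restrict = list(gamma = 0))
  expect_equal(no_eta$eta, 0)
  expect_equal(ols$gamma, 0)
  expect_gte(full$loglik, no_eta$loglik - 1e-6)
  expect_gte(no_eta$loglik, ols$loglik - 1e-6)
})

test_that("likelihood-ratio machinery respects nesting and boundaries", {
  sp <- sim_frontier_panel(3, mu = 0.5, eta = 0.4, sigma2 = 0.2, gamma = 0.6)
  full <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                       starts = 2, seed = 1)
  same <- lr_test(full, full, df = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$decision, "fail")

  ols <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                      restrict = list(gamma = 0))
  lt <- lr_test(full, ols, df = 3, boundary = TRUE)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$decision, "reject")  # strong simulated inefficiency

  expect_error(lr_test(ols, full, df = 3), class = "ecoeff_nesting_error")
})

test_that("a pure-noise frontier drives the inefficiency share to zero", {
  # null diagnostic uses the half-normal time-invariant specification
  # (mu = eta = 0); with mu free the null is not identified
  g <- sapply(1:10, function(s) {
    sp <- sim_frontier_panel(400 + s, sigma_u2 = 0, sigma_v2 = 0.1)
    f <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "bc92", log_y = TRUE,
                      restrict = list(mu = 0, eta = 0), starts = 1, seed = 1)
    f$gamma
  })
  expect_lt(median(g), 0.05)
  expect_lt(mean(g), 0.15)
})

test_that("pooled half-normal frontier fits and reports TE in range", {
  sp <- sim_frontier_panel(5, mu = 0, eta = 0, sigma2 = 0.3, gamma = 0.5)
  f <- fit_frontier(sp$data, "gdp", sp$Xcd, model = "pooled", log_y = TRUE,
                    starts = 2, seed = 1)
  expect_true(all(f$te$te > 0 & f$te$te <= 1))
  expect_true(is.finite(f$loglik))
  gl <- glance(f)
  expect_equal(gl$model, "pooled")
  expect_true(gl$mean_te <= 1)
})
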