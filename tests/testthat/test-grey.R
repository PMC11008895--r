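test_that("accumulation and its inverse are exact inverses", {
  x <- withr::with_seed(1, runif(12, 1, 100))
  expect_equal(diff(c(0, cumsum(x))), x)
})

test_that("GM(1,1) on geometric data matches the closed-form least squares", {
  # On exactly geometric data with ratio r the mean-sequence regression has
  # zero residual and a_hat = 2(1-r)/(1+r) (derivable by substituting the
  # geometric AGO into the grey equation).
  x <- c(100, 90, 81, 72.9)
  m <- fit_gm11(x)
  r <- 0.9
  expect_equal(m$a, 2 * (1 - r) / (1 + r), tolerance = 1e-10)
  # restored values are geometric with ratio exp(-a_hat)
  expect_equal(m$fitted[3:4] / m$fitted[2:3], rep(exp(-m$a), 2),
               tolerance = 1e-10)
  expect_lt(max(abs(m$rel_errors[-1])), 0.1)  # percent scale

  # horizon-1 forecast continues the fitted geometric sequence
  fc <- forecast(m, 1)
  expect_equal(fc$gm, m$fitted[4] * exp(-m$a), tolerance = 1e-8)
  expect_equal(fc$combined, fc$gm)
  expect_error(forecast(m, 0), class = "ecoeff_domain_error")
})

test_that("GM(1,1) round-trips the synthetic generator at its default decay", {
  g <- simulate_grey_series(10)
  m <- fit_gm11(g)
  expect_lt(abs(m$a - 0.0034), 1e-8)
  expect_lt(abs(m$u - 15800) / 15800, 1e-5)
  expect_lt(max(abs(m$rel_errors[-1])), 1e-2)
})

test_that("degenerate and invalid series hit the documented branches", {
  expect_warning(m <- fit_gm11(c(5, 5, 5, 5)), "constant")
  expect_equal(m$fitted, rep(5, 4), tolerance = 1e-9)
  expect_error(fit_gm11(c(1, 2, 3)), class = "ecoeff_domain_error")
  expect_error(fit_gm11(c(1, -2, 3, 4)), class = "ecoeff_domain_error")
})

test_that("relative errors reproduce the published cells and handle edge cases", {
  tab <- carbon_sink_series()
  gm <- relative_errors(tab$actual, tab$gm_sim)
  expect_equal(gm$error_pct[tab$year == 2017], -3.27)
  expect_equal(gm$error_pct[tab$year == 2020], 1.92)
  gnn <- relative_errors(tab$actual, tab$gnn_sim)
  expect_equal(gnn$error_pct[tab$year == 2014], -1.34)

  same <- relative_errors(c(3, 4), c(3, 4))
  expect_equal(same$error_pct, c(0, 0))
  expect_equal(attr(same, "mean_abs_pct"), 0)
  expect_error(relative_errors(c(0, 1), c(1, 1)), class = "ecoeff_domain_error")
  expect_error(relative_errors(1:3, 1:2), class = "ecoeff_format_error")
})

test_that("posterior grading follows the published bands literally", {
  expect_equal(grey_grade(0.30, 0.96), 1L)
  expect_equal(grey_grade(0.66, 0.69), 4L)
  expect_equal(grey_grade(0.50, 0.75), 3L)  # fails grade-2 C bound
  expect_equal(grey_grade(0.35, 0.96), 2L)  # C bound is strict
  expect_equal(grey_grade(0.34, 0.95), 2L)  # P bound is strict
  expect_equal(grey_grade(0.64, 0.71), 3L)
  # every (C, P) pair maps to exactly one grade
  grid <- expand.grid(C = seq(0, 1, 0.05), P = seq(0, 1, 0.05))
  g <- mapply(grey_grade, grid$C, grid$P)
  expect_true(all(g %in% 1:4))
})

test_that("posterior diagnostics compute the variance-ratio test", {
  g <- simulate_grey_series(10, noise_sd = 20, seed = 2)
  m <- fit_gm11(g)
  d <- posterior_diagnostics(m)
  expect_equal(d$C, d$s2 / d$s1)
  expect_true(d$P >= 0 && d$P <= 1)
  expect_equal(d$grade, grey_grade(d$C, d$P))
  # a good fit on a smooth series grades 1
  expect_equal(posterior_diagnostics(fit_gm11(simulate_grey_series(10)))$grade, 1L)
})

test_that("back-propagation training is seeded, capable and guarded", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * x - 0.5
  net1 <- train_bp(x, y, hidden = 3, lr = 0.1, epochs = 5000, seed = 4)
  net2 <- train_bp(x, y, hidden = 3, lr = 0.1, epochs = 5000, seed = 4)
  expect_identical(net1$W1, net2$W1)
  expect_identical(net1$W2, net2$W2)
  expect_lt(net1$mse, 1e-3)
  pred <- drop(predict(net1, x))
  expect_lt(max(abs(pred - y)), 0.2)

  expect_error(train_bp(matrix(1, 1, 1), 1), class = "ecoeff_domain_error")
  expect_error(train_bp(rep(3, 5), 1:5), class = "ecoeff_degenerate_error")
})

test_that("the corrector vanishes (relatively) on a noiseless grey series", {
  # the grey fit of its own noiseless series leaves only the O(a^2)
  # discrete/continuous restoration residue, so corrections are at most of
  # that (relative ~1e-6) order, and exactly zero for a constant residual
  g <- simulate_grey_series(10, noise_sd = 0)
  hy <- grey_bp_hybrid(g, window = 3, seed = 1)
  expect_lt(max(abs(hy$fitted$correction / hy$fitted$actual)), 1e-5)
  expect_equal(hy$fitted$combined, hy$fitted$gm + hy$fitted$correction)
  fc <- forecast(hy, 2)
  expect_lt(max(abs(fc$combined / fc$gm - 1)), 1e-5)
})

test_that("combined minus grey equals the network correction everywhere", {
  g <- simulate_grey_series(12, noise_sd = 40, seed = 6)
  hy <- grey_bp_hybrid(g, window = 3, seed = 2, epochs = 2000)
  expect_equal(hy$fitted$combined - hy$fitted$gm, hy$fitted$correction)
  fc <- forecast(hy, 3)
  expect_equal(fc$combined - fc$gm, fc$correction)
  expect_error(grey_bp_hybrid(g[1:4], window = 4), class = "ecoeff_domain_error")
})

test_that("residual correction improves the in-sample fit on noisy series", {
  gains <- sapply(1:10, function(s) {
    g <- simulate_grey_series(12, noise_sd = 60, seed = s)
    hy <- grey_bp_hybrid(g, window = 3, seed = s, epochs = 4000)
    n <- nrow(hy$fitted)
    idx <- (hy$window + 2):n  # periods the corrector actually touches
    err <- function(v) mean(abs((hy$fitted$actual[idx] - v[idx]) / hy$fitted$actual[idx]))
    err(hy$fitted$gm) - err(hy$fitted$combined)
  })
  expect_gte(median(gains), 0)
})

test_that("published mean errors follow from the printed error columns", {
  tab <- carbon_sink_series()
  expect_equal(mean_abs_error(tab$gm_err_pct[-1]), 1.53)
  expect_equal(mean_abs_error(tab$gnn_err_pct[-1]), 0.52)
})
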