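#' Tidy a spatial Durbin fit
#'
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @return Tibble with one row per parameter (`rho`, the betas and the
#'   spatially lagged phis): `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.sdm_fit <- function(x, ...) {
  est <- c(rho = x$rho, x$beta, x$phi)
  keep <- names(est)
  se <- sqrt(diag(x$vcov))[keep]
  z <- est / se
  tibble(term = keep, estimate = unname(est), std.error = unname(se),
         statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))))
}

#' Glance at a spatial Durbin fit
#'
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @return One-row tibble: `rho`, `sigma2`, `logLik`, `nobs`, `n_regions`,
#'   `n_years`, `effects`.
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble(rho = x$rho, sigma2 = x$sigma2, logLik = x$loglik, nobs = x$nobs,
         n_regions = x$n_regions, n_years = x$n_years, effects = x$effects)
}

#' Tidy a stochastic frontier fit
#'
#' @param x an `sfa_fit`.
#' @param ... unused.
#' @return Tibble `term`, `estimate`: frontier coefficients followed by
#'   `mu`, `eta`, `sigma2`, `gamma`.
#' @export
tidy.sfa_fit <- function(x, ...) {
  tibble(term = c(names(x$beta), "mu", "eta", "sigma2", "gamma"),
         estimate = unname(c(x$beta, x$mu, x$eta, x$sigma2, x$gamma)))
}

#' Glance at a stochastic frontier fit
#'
#' @param x an `sfa_fit`.
#' @param ... unused.
#' @return One-row tibble: `logLik`, `sigma2`, `gamma`, `mu`, `eta`,
#'   `mean_te`, `nobs`, `model`, `boundary_gamma`.
#' @export
glance.sfa_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sigma2 = x$sigma2, gamma = x$gamma,
         mu = x$mu, eta = x$eta, mean_te = mean(x$te$te), nobs = x$nobs,
         model = x$model, boundary_gamma = x$boundary_gamma)
}

#' Tidy a GM(1,1) fit
#'
#' @param x a `gm11`.
#' @param ... unused.
#' @return Tibble `term` (`a`, `u`), `estimate`.
#' @export
tidy.gm11 <- function(x, ...) {
  tibble(term = c("a", "u"), estimate = c(x$a, x$u))
}

#' Glance at a GM(1,1) fit
#'
#' @param x a `gm11`.
#' @param ... unused.
#' @return One-row tibble: `a`, `u`, ratio `exp(-a)`, posterior `C`, `P`,
#'   `grade`, mean absolute relative error (%), `nobs`.
#' @export
glance.gm11 <- function(x, ...) {
  d <- posterior_diagnostics(x)
  tibble(a = x$a, u = x$u, ratio = exp(-x$a), C = d$C, P = d$P,
         grade = d$grade, mean_abs_err_pct = mean_abs_error(x$rel_errors[-1]),
         nobs = length(x$data))
}
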