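#' Default translog frontier coefficients for the panel generator
#'
#' Named in the order of the frontier design matrix of [translog_design()]:
#' time trend, log inputs, their squares, trend-input interactions and
#' pairwise input cross terms, plus the intercept.  The defaults are the
#' coefficient set used throughout the package's worked examples; pass a
#' named subset to override individual terms (unnamed terms keep defaults).
#'
#' @return Named numeric vector of 15 coefficients.
#' @export
default_frontier <- function() {
  c(t = 0.4379, lnx1 = 0.4962, lnx2 = 0.3148, lnx3 = -0.0147,
    t2 = 0.0351, lnx1_2 = 0.4269, lnx2_2 = 0.7643, lnx3_2 = -0.1597,
    t_lnx1 = -0.3179, t_lnx2 = -0.4792, t_lnx3 = 0.1398,
    lnx1_lnx2 = 0.5984, lnx1_lnx3 = -0.1743, lnx2_lnx3 = -0.1291,
    `(Intercept)` = 3.7643)
}

#' Simulate a provincial production panel with a known frontier
#'
#' Generates a balanced region-year panel from a translog (or restricted)
#' stochastic production frontier with time-decaying inefficiency:
#' \deqn{\ln y_{it} = TL(\ln x_{it}, t;\beta) + v_{it} - u_{it},\qquad
#'       u_{it} = e^{-\eta (t - T)} u_i,}
#' where \eqn{u_i} is drawn from a normal distribution with mean `mu` and
#' variance `sigma_u2` truncated at zero, and \eqn{v_{it} \sim N(0,
#' \sigma_v^2)}.  Inputs (capital, labour, energy) are drawn log-uniformly
#' over `input_ranges`; the translog is evaluated on logs centred at their
#' geometric means (the standard normalisation that makes first-order
#' coefficients elasticities at the sample mean and keeps the quadratic
#' terms numerically tame), with the time index centred likewise.  Carbon is
#' a positive monotone function of energy, `carbon_c * energy^carbon_kappa`
#' with multiplicative lognormal noise.
#'
#' Instead of `sigma_u2`/`sigma_v2` you may give the frontier-analysis
#' parameterization `sigma2` (= total variance) and `gamma` (= inefficiency
#' share), which is how the fitted models report themselves.
#'
#' @param n_regions,n_years panel dimensions.
#' @param beta named frontier coefficients; see [default_frontier()].
#'   Omitted names default; e.g. a Cobb-Douglas frontier is
#'   `beta = c(lnx1 = .5, lnx2 = .3, lnx3 = .1, t = .02, "(Intercept)" = 1)`
#'   with `zero_rest = TRUE`.
#' @param zero_rest if `TRUE`, coefficients not named in `beta` are zero
#'   rather than the package defaults.
#' @param mu,eta inefficiency location and time-decay rate.
#' @param sigma_u2,sigma_v2 inefficiency and noise variances.
#' @param sigma2,gamma alternative parameterization; both must be given.
#' @param input_ranges list of length-2 ranges for capital, labour, energy.
#' @param carbon_c,carbon_kappa,carbon_sdlog carbon generation parameters.
#' @param seed integer seed.
#' @return A tibble with columns `region`, `year`, `capital`, `labour`,
#'   `energy`, `gdp`, `carbon`, plus a `truth` attribute (tibble of the
#'   latent `u_it` and `te = exp(-u_it)`) retrievable with
#'   [simulation_truth()].
#' @export
simulate_panel <- function(n_regions = 30, n_years = 10,
                           beta = NULL, zero_rest = FALSE,
                           mu = 0.5, eta = 0.4137,
                           sigma_u2 = NULL, sigma_v2 = NULL,
                           sigma2 = 0.2143, gamma = 0.6429,
                           input_ranges = list(capital = c(361, 165425),
                                               labour = c(245, 6826),
                                               energy = c(310, 44026)),
                           carbon_c = 5, carbon_kappa = 0.9,
                           carbon_sdlog = 0.1,
                           seed = 1) {
  if (is.null(sigma_u2) != is.null(sigma_v2)) {
    abort("give both sigma_u2 and sigma_v2, or neither", class = "ecoeff_domain_error")
  }
  if (is.null(sigma_u2)) {
    sigma_u2 <- gamma * sigma2
    sigma_v2 <- (1 - gamma) * sigma2
  }
  if (sigma_u2 < 0 || sigma_v2 < 0 || sigma_u2 + sigma_v2 <= 0) {
    abort("need sigma_u2 >= 0, sigma_v2 >= 0 and their sum > 0",
          class = "ecoeff_domain_error")
  }
  b <- resolve_frontier(beta, zero_rest)
  withr::with_seed(seed, {
    regions <- sprintf("R%02d", seq_len(n_regions))
    grid <- tidyr::expand_grid(region = regions, year = seq_len(n_years))
    draw_input <- function(rng) exp(runif(nrow(grid), log(rng[1]), log(rng[2])))
    grid$capital <- draw_input(input_ranges$capital)
    grid$labour <- draw_input(input_ranges$labour)
    grid$energy <- draw_input(input_ranges$energy)
    X <- translog_design(grid[, c("capital", "labour", "energy")],
                         t = grid$year, center = TRUE)
    lf <- drop(X %*% b[colnames(X)])
    # sigma_u2 = 0 switches inefficiency off entirely (TE identically 1)
    u_i <- if (sigma_u2 == 0) rep(0, n_regions) else
      rtruncnorm_pos(n_regions, mu, sqrt(sigma_u2))
    decay <- exp(-eta * (grid$year - n_years))
    u_it <- decay * u_i[match(grid$region, regions)]
    v_it <- rnorm(nrow(grid), 0, sqrt(sigma_v2))
    grid$gdp <- exp(lf + v_it - u_it)
    grid$carbon <- carbon_c * grid$energy^carbon_kappa *
      exp(rnorm(nrow(grid), 0, carbon_sdlog))
    truth <- tibble(region = grid$region, year = grid$year,
                    u = u_it, te = exp(-u_it))
    attr(grid, "ecoeff_truth") <- truth
    grid
  })
}

resolve_frontier <- function(beta, zero_rest) {
  b <- default_frontier()
  if (zero_rest) b[] <- 0
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), names(b))
    if (length(unknown)) {
      abort(sprintf("unknown frontier coefficient(s): %s",
                    paste(unknown, collapse = ", ")), class = "ecoeff_domain_error")
    }
    b[names(beta)] <- beta
  }
  b
}

# truncated-at-zero normal draws (the Battese-Coelli inefficiency law)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Latent truths of a simulated panel
#'
#' @param data a tibble returned by [simulate_panel()].
#' @return Tibble of `region`, `year`, true inefficiency `u` and technical
#'   efficiency `te`.
#' @export
simulation_truth <- function(data) {
  truth <- attr(data, "ecoeff_truth")
  if (is.null(truth)) {
    abort("no latent-truth sidecar on this data; was it made by simulate_panel()?",
          class = "ecoeff_domain_error")
  }
  truth
}

#' Simulate a spatial Durbin panel with known coefficients
#'
#' Draws, for each year, the reduced form of the spatial Durbin model
#' \deqn{Y_t = (I - \rho W)^{-1} (X_t\beta + W X_t\varphi + \mu + \nu_t 1 +
#' \varepsilon_t)} with region effects \eqn{\mu_i} and year effects
#' \eqn{\nu_t} drawn \eqn{N(0, \cdot)}.  Regressors are iid standard normal.
#'
#' @param W a row-standardized [eco_weights] object.
#' @param n_years number of periods.
#' @param rho spatial autoregressive coefficient; must lie inside the
#'   stability interval `(1/min(eigen(W)), 1)`.
#' @param beta,phi coefficient vectors (recycled to a common length = number
#'   of regressors).
#' @param sigma2 idiosyncratic error variance.
#' @param sigma2_mu,sigma2_nu region/year effect variances.
#' @param seed integer seed.
#' @return Tibble `region`, `year`, `y`, `x1..xk`, with the effect draws in
#'   attributes `mu` and `nu`.
#' @export
simulate_sdm_panel <- function(W, n_years = 20, rho = 0.3,
                               beta = c(1, 1), phi = c(0.2, 0.2),
                               sigma2 = 1, sigma2_mu = 0.1, sigma2_nu = 0.1,
                               seed = 1) {
  W <- as_eco_weights(W)
  if (!W$standardized) {
    abort("W must be row-standardized for simulate_sdm_panel",
          class = "ecoeff_domain_error")
  }
  k <- max(length(beta), length(phi))
  beta <- rep_len(beta, k); phi <- rep_len(phi, k)
  ev <- Re(eigen(W$w, only.values = TRUE)$values)
  lo <- 1 / min(ev)
  if (rho <= lo || rho >= 1) {
    abort(sprintf("rho = %.3f outside the stability interval (%.3f, 1)", rho, lo),
          class = "ecoeff_domain_error")
  }
  n <- length(W$ids)
  Ainv <- solve(diag(n) - rho * W$w)
  withr::with_seed(seed, {
    mu <- rnorm(n, 0, sqrt(sigma2_mu))
    nu <- rnorm(n_years, 0, sqrt(sigma2_nu))
    out <- purrr::map_dfr(seq_len(n_years), function(tt) {
      X <- matrix(rnorm(n * k), n, k)
      eps <- rnorm(n, 0, sqrt(sigma2))
      rhs <- X %*% beta + W$w %*% X %*% phi + mu + nu[tt] + eps
      df <- tibble(region = W$ids, year = tt, y = unname(drop(Ainv %*% rhs)))
      colnames(X) <- paste0("x", seq_len(k))
      dplyr::bind_cols(df, as_tibble(X))
    })
    attr(out, "mu") <- setNames(mu, W$ids)
    attr(out, "nu") <- nu
    out
  })
}

#' Simulate a GM(1,1)-recoverable positive series
#'
#' Produces a series whose restored values follow the exact GM(1,1) pattern:
#' `x(1) = x1` and, for `t >= 2`,
#' `x(t) = (x1 - u/a) * exp(-a (t-1)) * (1 - exp(a))`, plus optional additive
#' Gaussian noise.  With `noise_sd = 0` the output is exactly recovered by
#' [fit_gm11()] (same `a`, `u` to numerical precision).  Defaults emulate a
#' smooth, slowly declining national aggregate (order 1.5e4, in 1e4 t) of
#' the kind the grey forecaster is applied to.
#'
#' @param n series length (>= 4).
#' @param a development coefficient (decline rate when positive).
#' @param u grey input term.
#' @param x1 base-period value.
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return Numeric series of length `n`.
#' @export
simulate_grey_series <- function(n = 10, a = 0.0034, u = 15800, x1 = 15783,
                                 noise_sd = 0, seed = 1) {
  if (n < 4) {
    abort("grey series needs length >= 4 to be identifiable",
          class = "ecoeff_domain_error")
  }
  t <- 2:n
  x <- c(x1, (x1 - u / a) * exp(-a * (t - 1)) * (1 - exp(a)))
  if (noise_sd > 0) {
    x <- x + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  if (any(x <= 0)) {
    abort("simulated grey series would be nonpositive; adjust (a, u, x1, noise_sd)",
          class = "ecoeff_domain_error")
  }
  x
}
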