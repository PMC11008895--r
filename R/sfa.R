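#' Translog production-frontier design matrix
#'
#' Builds the 15-column flexible log-quadratic design in three inputs with a
#' time trend: `t`, `lnx1..lnx3`, `t2`, the squared logs, the trend-input
#' interactions, the pairwise log cross terms, and an intercept.  Squares
#' and cross terms are plain products (no 1/2 factor).  With
#' `center = TRUE` logs are centred at their geometric means and the trend
#' at its mean, the usual normalisation under which first-order coefficients
#' are elasticities at the sample mean; the same centring must then be used
#' when interpreting coefficients.
#'
#' @param data data frame holding the three input columns (order: capital,
#'   labour, energy or any fixed order you adopt).
#' @param t numeric time index (e.g. year number).
#' @param inputs names of the three input columns; defaults to the first
#'   three columns of `data`.
#' @param center centre logs and trend before expanding (default FALSE).
#' @return Numeric matrix with 15 named columns including `(Intercept)`.
#' @export
translog_design <- function(data, t, inputs = names(data)[1:3], center = FALSE) {
  if (length(inputs) != 3) {
    abort("translog_design expects exactly 3 inputs", class = "ecoeff_domain_error")
  }
  X <- as.matrix(data[, inputs, drop = FALSE])
  if (any(!is.finite(X)) || any(X <= 0)) {
    abort("inputs must be strictly positive for the translog",
          class = "ecoeff_domain_error")
  }
  L <- log(X)
  tt <- as.numeric(t)
  if (center) {
    L <- sweep(L, 2, colMeans(L))
    tt <- tt - mean(tt)
  }
  l1 <- L[, 1]; l2 <- L[, 2]; l3 <- L[, 3]
  out <- cbind(t = tt, lnx1 = l1, lnx2 = l2, lnx3 = l3,
               t2 = tt^2, lnx1_2 = l1^2, lnx2_2 = l2^2, lnx3_2 = l3^2,
               t_lnx1 = tt * l1, t_lnx2 = tt * l2, t_lnx3 = tt * l3,
               lnx1_lnx2 = l1 * l2, lnx1_lnx3 = l1 * l3, lnx2_lnx3 = l2 * l3,
               `(Intercept)` = 1)
  out
}

#' Fit a stochastic production frontier with time-varying inefficiency
#'
#' Maximum-likelihood estimation of the panel frontier
#' \deqn{\ln y_{it} = x_{it}'\beta + v_{it} - u_{it}}
#' with \eqn{v_{it} \sim N(0, \sigma_v^2)} and, under `model = "bc92"`,
#' time-decaying inefficiency \eqn{u_{it} = e^{-\eta(t - T_i)} u_i},
#' \eqn{u_i \sim N^+(\mu, \sigma_u^2)} (normal truncated at zero).  The
#' variance parameters are reported in the \eqn{(\sigma^2, \gamma)}
#' parameterization, \eqn{\sigma^2 = \sigma_u^2 + \sigma_v^2} and
#' \eqn{\gamma = \sigma_u^2/\sigma^2 \in [0,1]}, the share of the composite
#' error variance due to inefficiency.  `model = "pooled"` ignores the panel
#' structure and fits the cross-sectional normal/half-normal frontier
#' (each observation its own \eqn{u_{it}}, \eqn{\mu = \eta = 0}).
#'
#' Optimization is multi-start BFGS on transformed parameters
#' (\eqn{\log\sigma^2}, \eqn{\mathrm{logit}\,\gamma}) with numerical
#' gradients, tolerance 1e-8; the best of `starts` seeded starts is kept.
#' Individual parameters can be pinned with `restrict` (e.g.
#' `list(mu = 0)`, `list(eta = 0)`, or `list(gamma = 0)` which collapses the
#' model to OLS) — this is how the nested models for the likelihood-ratio
#' tests are built.
#'
#' Technical efficiency is predicted as
#' \eqn{TE_{it} = E[e^{-u_{it}} \mid \varepsilon_i] \in (0, 1]}, the
#' standard conditional-expectation predictor.
#'
#' @param data long panel.
#' @param y name of the (log) output column, or of the output if
#'   `log_y = TRUE`.
#' @param design design matrix from [translog_design()] (or any numeric
#'   matrix with an intercept column), one row per row of `data`.
#' @param region,year key column names.
#' @param model `"bc92"` or `"pooled"`.
#' @param log_y take logs of `data[[y]]` first?
#' @param restrict named list of parameters to pin: any of `mu`, `eta`,
#'   `gamma` (gamma only to 0).
#' @param starts number of seeded optimizer starts.
#' @param seed integer seed for the extra starts.
#' @return An `sfa_fit` object: `beta`, `mu`, `eta`, `sigma2`, `gamma`,
#'   `loglik`, `te` (tibble region, year, te), `convergence`,
#'   `boundary_gamma` flag.
#' @export
fit_frontier <- function(data, y, design, region = "region", year = "year",
                         model = c("bc92", "pooled"), log_y = FALSE,
                         restrict = list(), starts = 5, seed = 1) {
  model <- match.arg(model)
  yv <- data[[y]]
  if (log_y) {
    if (any(yv <= 0)) abort("output must be positive to take logs",
                            class = "ecoeff_domain_error")
    yv <- log(yv)
  }
  Xd <- as.matrix(design)
  stopifnot(nrow(Xd) == length(yv))
  reg <- as.character(data[[region]])
  yr <- as.numeric(data[[year]])
  groups <- split(seq_along(yv), reg)
  kb <- ncol(Xd)
  ols <- lm.fit(Xd, yv)
  b0 <- ols$coefficients
  s2_0 <- mean(ols$residuals^2)
  fix <- list(mu = restrict$mu, eta = restrict$eta, gamma = restrict$gamma)
  if (!is.null(fix$gamma) && fix$gamma != 0) {
    abort("gamma can only be restricted to 0 (no inefficiency)",
          class = "ecoeff_domain_error")
  }
  if (model == "pooled") {
    fix$mu <- 0; fix$eta <- 0
  }
  if (!is.null(fix$gamma)) {
    # gamma = 0: the model is plain OLS with normal errors
    ll <- sum(dnorm(yv, Xd %*% b0, sqrt(s2_0), log = TRUE))
    te <- tibble(region = reg, year = data[[year]], te = rep(1, length(yv)))
    return(new_sfa_fit(b0, mu = 0, eta = 0, sigma2 = s2_0, gamma = 0,
                       loglik = ll, te = te, convergence = 0L,
                       boundary_gamma = TRUE, model = model,
                       colnames = colnames(Xd), n = length(yv)))
  }
  free_mu <- is.null(fix$mu)
  free_eta <- is.null(fix$eta) && model == "bc92"
  # parameter vector: beta, log sigma2, logit gamma, [mu], [eta]
  unpack <- function(th) {
    th <- unname(th)
    beta <- th[seq_len(kb)]
    s2 <- exp(th[kb + 1])
    g <- stats::plogis(th[kb + 2])
    i <- kb + 2
    mu <- if (free_mu) th[(i <- i + 1)] else fix$mu
    eta <- if (free_eta) th[(i <- i + 1)] else (fix$eta %||% 0)
    list(beta = beta, sigma2 = s2, gamma = g, mu = mu, eta = eta)
  }
  negll <- function(th) {
    p <- unpack(th)
    eps <- yv - drop(Xd %*% p$beta)
    ll <- if (model == "bc92") {
      bc92_loglik(eps, groups, yr, p$mu, p$eta, p$sigma2, p$gamma)
    } else {
      halfnormal_loglik(eps, p$sigma2, p$gamma)
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  # box bounds on transformed parameters keep the search away from the
  # degenerate sigma_v -> 0 region where the likelihood surface collapses
  npar <- kb + 2 + free_mu + free_eta
  lower <- c(rep(-Inf, kb), log(s2_0) - 12, -12,
             if (free_mu) -10, if (free_eta) -2)
  upper <- c(rep(Inf, kb), log(s2_0) + 12, 12,
             if (free_mu) 10, if (free_eta) 2)
  grid <- data.frame(g = c(0.7, 0.3, 0.95, 0.3, 0.7, 0.95),
                     e = c(0.2, 0, 0.2, 0.2, 0, 0))
  n_grid <- min(starts, nrow(grid))
  starts_list <- purrr::map(seq_len(n_grid), function(i) {
    c(b0, log(s2_0), stats::qlogis(grid$g[i]),
      if (free_mu) 0.1, if (free_eta) grid$e[i])
  })
  if (starts > nrow(grid)) {
    extra <- withr::with_seed(seed, {
      purrr::map(seq_len(starts - nrow(grid)), function(i) {
        starts_list[[1]] + rnorm(npar, 0, 0.3)
      })
    })
    starts_list <- c(starts_list, extra)
  }
  fits <- purrr::map(starts_list, function(st) {
    tryCatch(optim(st, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    abort("frontier optimization failed from every start", class = "ecoeff_convergence_error")
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  p <- unpack(best$par)
  eps <- yv - drop(Xd %*% p$beta)
  te_vals <- if (model == "bc92") {
    bc92_te(eps, groups, yr, p$mu, p$eta, p$sigma2, p$gamma)
  } else {
    halfnormal_te(eps, p$sigma2, p$gamma)
  }
  new_sfa_fit(setNames(p$beta, colnames(Xd)), mu = p$mu, eta = p$eta,
              sigma2 = p$sigma2, gamma = p$gamma, loglik = -best$value,
              te = tibble(region = reg, year = data[[year]], te = te_vals),
              convergence = best$convergence,
              boundary_gamma = p$gamma < 1e-4 || p$gamma > 1 - 1e-4,
              model = model, colnames = colnames(Xd), n = length(yv))
}

new_sfa_fit <- function(beta, mu, eta, sigma2, gamma, loglik, te, convergence,
                        boundary_gamma, model, colnames, n) {
  structure(list(beta = beta, mu = mu, eta = eta, sigma2 = sigma2,
                 gamma = gamma, loglik = loglik, te = te,
                 convergence = convergence, boundary_gamma = boundary_gamma,
                 model = model, nobs = n), class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf("<sfa_fit %s> logLik = %.3f, sigma2 = %.4f, gamma = %.4f, mu = %.4f, eta = %.4f\n",
              x$model, x$loglik, x$sigma2, x$gamma, x$mu, x$eta))
  if (x$boundary_gamma) cat("  note: gamma at boundary\n")
  invisible(x)
}

# Battese-Coelli time-decay panel log-likelihood in (sigma2, gamma).
# For each region i with residual vector eps_i and decay weights
# h_it = exp(-eta (t - T_i)):
#   mu*_i = (mu sv2 - h'eps su2) / (sv2 + h'h su2)
#   s*2_i = su2 sv2 / (sv2 + h'h su2)
# ll_i = -T/2 log(2 pi) - T/2 log sv2 + (1/2)log(s*2/su2)
#        + log Phi(mu*/s*) - log Phi(mu/su)
#        - (1/2)(eps'eps/sv2 + mu^2/su2 - mu*^2/s*2)
bc92_loglik <- function(eps, groups, yr, mu, eta, sigma2, gamma) {
  su2 <- gamma * sigma2
  sv2 <- (1 - gamma) * sigma2
  if (su2 <= 0 || sv2 <= 0) return(-Inf)
  su <- sqrt(su2)
  parts <- bc92_region_parts(eps, groups, yr, mu, eta, su2, sv2)
  sum(-parts$Ti / 2 * log(2 * pi) - parts$Ti / 2 * log(sv2) +
        0.5 * (log(parts$ss2) - log(su2)) +
        pnorm(parts$mus / sqrt(parts$ss2), log.p = TRUE) -
        pnorm(mu / su, log.p = TRUE) -
        0.5 * (parts$sse / sv2 + mu^2 / su2 - parts$mus^2 / parts$ss2))
}

# per-region sufficient statistics, vectorized over regions
bc92_region_parts <- function(eps, groups, yr, mu, eta, su2, sv2) {
  Ti <- lengths(groups)
  hh <- he <- sse <- numeric(length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    h <- exp(-eta * (yr[idx] - max(yr[idx])))
    hh[i] <- sum(h^2)
    he[i] <- sum(h * eps[idx])
    sse[i] <- sum(eps[idx]^2)
  }
  den <- sv2 + hh * su2
  list(Ti = Ti, mus = (mu * sv2 - he * su2) / den,
       ss2 = su2 * sv2 / den, sse = sse)
}

# E[exp(-h_it u_i) | eps_i] for each observation
bc92_te <- function(eps, groups, yr, mu, eta, sigma2, gamma) {
  su2 <- gamma * sigma2
  sv2 <- (1 - gamma) * sigma2
  out <- numeric(length(eps))
  for (idx in groups) {
    e <- eps[idx]
    Tl <- max(yr[idx])
    h <- exp(-eta * (yr[idx] - Tl))
    den <- sv2 + sum(h^2) * su2
    mus <- (mu * sv2 - sum(h * e) * su2) / den
    ss <- sqrt(su2 * sv2 / den)
    out[idx] <- exp(-h * mus + 0.5 * h^2 * ss^2) *
      pnorm(mus / ss - h * ss) / pnorm(mus / ss)
  }
  pmin(out, 1)
}

# cross-sectional normal/half-normal frontier (ALS77)
halfnormal_loglik <- function(eps, sigma2, gamma) {
  if (gamma <= 0 || gamma >= 1) return(-Inf)
  s <- sqrt(sigma2)
  lambda <- sqrt(gamma / (1 - gamma))
  sum(log(2 / s) + dnorm(eps / s, log = TRUE) +
        pnorm(-eps * lambda / s, log.p = TRUE))
}

halfnormal_te <- function(eps, sigma2, gamma) {
  su2 <- gamma * sigma2; sv2 <- (1 - gamma) * sigma2
  ss <- sqrt(su2 * sv2 / sigma2)
  mus <- -eps * su2 / sigma2
  pmin(exp(-mus + ss^2 / 2) * pnorm(mus / ss - ss) / pnorm(mus / ss), 1)
}

#' Likelihood-ratio test between nested frontier models
#'
#' Computes \eqn{LR = 2(\ell_{full} - \ell_{restricted})}.  For null
#' hypotheses that pin variance parameters at a boundary (e.g. no
#' inefficiency), the statistic follows the mixed chi-squared distribution
#' \eqn{\tfrac12\chi^2_{df-1} + \tfrac12\chi^2_{df}} rather than plain
#' chi-squared; set `boundary = TRUE` for those.
#'
#' @param full,restricted `sfa_fit` objects, restricted nested in full.
#' @param df degrees of freedom; defaults to the difference in free
#'   parameter counts implied by the restriction list is not tracked, so
#'   give it explicitly for restricted designs.
#' @param boundary use the mixed chi-squared reference.
#' @param alpha significance level for the reported decision.
#' @return One-row tibble: `statistic`, `df`, `p`, `boundary`, `decision`.
#' @export
lr_test <- function(full, restricted, df, boundary = FALSE, alpha = 0.05) {
  stopifnot(inherits(full, "sfa_fit"), inherits(restricted, "sfa_fit"))
  stat <- 2 * (full$loglik - restricted$loglik)
  if (stat < -1e-6) {
    abort(sprintf("restricted log-likelihood exceeds the full model's (LR = %.4g); models are not nested or optimization failed", stat),
          class = "ecoeff_nesting_error")
  }
  stat <- max(stat, 0)
  p <- if (boundary) {
    0.5 * (if (df > 1) pchisq(stat, df - 1, lower.tail = FALSE) else as.numeric(stat <= 0)) +
      0.5 * pchisq(stat, df, lower.tail = FALSE)
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  tibble(statistic = stat, df = df, p = p, boundary = boundary,
         decision = ifelse(p < alpha, "reject", "fail"))
}
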