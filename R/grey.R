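#' Fit a GM(1,1) grey model
#'
#' Classic single-variable first-order grey model.  The series is
#' accumulated once (AGO), the parameters \eqn{(a, u)} are the least-squares
#' solution of the grey differential equation built from consecutive means
#' of the accumulated series, and fitted values are restored by inverse
#' accumulation of the time-response function:
#' \deqn{\hat x^{(1)}(t+1) = (x^{(0)}(1) - u/a) e^{-a t} + u/a.}
#' The fitted base-period value is set to the observed one (zero base-year
#' error by convention), and for \eqn{t \ge 2} fitted values are geometric
#' with ratio \eqn{e^{-a}}.  A (near-)constant series makes the grey
#' equation degenerate; that branch fits the constant mean with a warning.
#'
#' @param x positive numeric series (length >= 4), or a data frame with
#'   columns `year` and `value`.
#' @param t0 label of the first period (e.g. first year).
#' @return A `gm11` object: `a`, `u`, `x1`, `fitted`, `residuals`,
#'   `rel_errors` (%, zero for the base period), `data`, `t0`.
#' @export
fit_gm11 <- function(x, t0 = 1L) {
  if (is.data.frame(x)) {
    t0 <- x$year[1]
    x <- x$value
  }
  n <- length(x)
  if (n < 4) abort("GM(1,1) needs at least 4 observations", class = "ecoeff_domain_error")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("GM(1,1) needs strictly positive values", class = "ecoeff_domain_error")
  }
  x1 <- cumsum(x)
  z <- -(x1[-n] + x1[-1]) / 2
  B <- cbind(z, 1)
  Y <- x[-1]
  au <- drop(solve(crossprod(B), crossprod(B, Y)))
  a <- unname(au[1]); u <- unname(au[2])
  if (abs(a) < 1e-12) {
    warn("development coefficient ~ 0 (constant series); fitting the mean")
    fitted <- c(x[1], rep(mean(Y), n - 1))
  } else {
    tt <- seq_len(n - 1)
    x1hat <- (x[1] - u / a) * exp(-a * tt) + u / a
    fitted <- c(x[1], diff(c(x[1], x1hat)))
  }
  residuals <- x - fitted
  structure(list(a = a, u = u, x1 = x[1], fitted = fitted,
                 residuals = residuals,
                 rel_errors = 100 * residuals / x,
                 data = x, t0 = t0), class = "gm11")
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("<gm11> a = %.6f, u = %.4f, ratio exp(-a) = %.6f, n = %d\n",
              x$a, x$u, exp(-x$a), length(x$data)))
  diag <- posterior_diagnostics(x)
  cat(sprintf("  C = %.4f, P = %.4f -> grade %d (%s)\n",
              diag$C, diag$P, diag$grade, diag$label))
  invisible(x)
}

#' Per-period relative errors between actual and simulated series
#'
#' \eqn{e(t) = 100\,(actual_t - simulated_t)/actual_t}, rounded to two
#' decimals for reporting, with the mean absolute error taken over
#' \eqn{t \ge 2} (the base period is zero by construction in grey modelling
#' and would dilute the average).
#'
#' @param actual,simulated equal-length numeric series.
#' @return Tibble `period`, `actual`, `simulated`, `error_pct` (2 dp), with
#'   the mean absolute percentage error over `t >= 2` in attribute
#'   `"mean_abs_pct"` (also returned by [mean_abs_error()]).
#' @export
relative_errors <- function(actual, simulated) {
  if (length(actual) != length(simulated)) {
    abort("actual and simulated must have equal length", class = "ecoeff_format_error")
  }
  if (any(actual == 0)) {
    abort("relative errors undefined where actual = 0", class = "ecoeff_domain_error")
  }
  err <- round(100 * (actual - simulated) / actual, 2)
  out <- tibble(period = seq_along(actual), actual = actual,
                simulated = simulated, error_pct = err)
  attr(out, "mean_abs_pct") <- mean_abs_error(err[-1])
  out
}

#' Mean absolute percentage error of a reported error column
#'
#' The average of absolute per-period percentage errors, the figure quoted
#' when comparing grey and grey-neural simulated series.  Pass errors
#' already excluding the base period, or the full column minus its first
#' entry.
#'
#' @param errors_pct numeric vector of percentage errors.
#' @return Scalar mean absolute value, rounded to 2 decimals.
#' @export
mean_abs_error <- function(errors_pct) {
  round(mean(abs(errors_pct)), 2)
}

#' Posterior-variance diagnostics and accuracy grade of a grey model
#'
#' Classic posterior-difference test.  `s1` is the standard deviation of
#' the observed series about its mean; `s2` that of the residuals (base
#' period excluded, where the error is zero by convention).  The posterior
#' variance ratio is `C = s2/s1` and the small-error probability `P` is the
#' share of residuals within `0.6745 * s1` of the mean residual.  The grade
#' is the best band whose *both* bounds hold (C strictly below, P strictly
#' above), else 4:
#'
#' | grade | C      | P      | label           |
#' |-------|--------|--------|-----------------|
#' | 1     | < 0.35 | > 0.95 | Good            |
#' | 2     | < 0.50 | > 0.80 | Qualified       |
#' | 3     | < 0.65 | > 0.70 | Barely qualified|
#' | 4     | else   | else   | Unqualified     |
#'
#' @param model a `gm11` object, or a list with elements `data` and
#'   `residuals`.
#' @return One-row tibble: `s1`, `s2`, `C`, `P`, `grade`, `label`.
#' @export
posterior_diagnostics <- function(model) {
  x <- model$data
  q <- model$residuals[-1]  # base period is exact by convention
  if (length(q) < 3) {
    abort("need at least 3 residuals for the posterior test", class = "ecoeff_domain_error")
  }
  s1 <- sqrt(mean((x - mean(x))^2))
  if (s1 == 0) {
    abort("constant observed series; posterior ratio undefined",
          class = "ecoeff_degenerate_error")
  }
  s2 <- sqrt(mean((q - mean(q))^2))
  C <- s2 / s1
  P <- mean(abs(q - mean(q)) < 0.6745 * s1)
  grade <- grade_cp(C, P)
  labels <- c("Good", "Qualified", "Barely qualified", "Unqualified")
  tibble(s1 = s1, s2 = s2, C = C, P = P, grade = grade, label = labels[grade])
}

#' Accuracy grade for a (C, P) diagnostic pair
#'
#' The band logic of [posterior_diagnostics()] exposed directly: every
#' (C, P) pair maps to exactly one grade in 1..4.
#'
#' @param C posterior variance ratio (>= 0).
#' @param P small-error probability in `[0, 1]`.
#' @return Integer grade 1..4.
#' @export
grey_grade <- function(C, P) {
  stopifnot(C >= 0, P >= 0, P <= 1)
  grade_cp(C, P)
}

grade_cp <- function(C, P) {
  if (C < 0.35 && P > 0.95) 1L
  else if (C < 0.50 && P > 0.80) 2L
  else if (C < 0.65 && P > 0.70) 3L
  else 4L
}

#' Forecast from a grey or grey-neural model
#'
#' Extrapolates the fitted model `h` periods past the end of the sample.
#' For a hybrid model the back-propagation residual corrector is rolled
#' forward on its own predictions; the reported forecast decomposes into
#' the GM(1,1) component and the correction.
#'
#' @param object a `gm11` or `grey_hybrid` fit.
#' @param h forecast horizon (>= 1 periods past the sample).
#' @param ... unused.
#' @return Tibble `period` (t0-based), `gm`, `correction`, `combined`.
#' @export
forecast <- function(object, h, ...) UseMethod("forecast")

#' @rdname forecast
#' @export
forecast.gm11 <- function(object, h, ...) {
  if (h <= 0) abort("forecast horizon must be >= 1", class = "ecoeff_domain_error")
  n <- length(object$data)
  gm <- gm11_extrapolate(object, n + seq_len(h))
  tibble(period = object$t0 + n - 1 + seq_len(h),
         gm = gm, correction = 0, combined = gm)
}

gm11_extrapolate <- function(m, t_idx) {
  if (abs(m$a) < 1e-12) return(rep(mean(m$data[-1]), length(t_idx)))
  (m$x1 - m$u / m$a) * exp(-m$a * (t_idx - 1)) * (1 - exp(m$a))
}
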