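#' Train a back-propagation neural network
#'
#' A deliberately classical multilayer perceptron: one sigmoid hidden layer,
#' linear output, full-batch gradient descent on mean squared error.
#' Inputs and targets are min-max normalized to \eqn{[-1, 1]} (each
#' feature's observed min maps to -1 and max to +1); predictions are
#' denormalized on the way out.  Weights and biases initialize uniform on
#' \eqn{(-0.5, 0.5)} under the given seed, so training is bit-reproducible.
#' Training stops at `epochs` or when the (normalized-scale) MSE reaches
#' `target_mse`.
#'
#' @param x numeric matrix of input rows (or vector for one feature).
#' @param y numeric matrix of target rows (or vector for one output).
#' @param hidden hidden-layer width.
#' @param lr learning rate in (0, 1).
#' @param epochs maximum training epochs.
#' @param target_mse early-stopping MSE on the normalized scale.
#' @param seed integer seed for the weight initialization.
#' @return A `bp_net` object; use [predict.bp_net()].
#' @export
train_bp <- function(x, y, hidden = 5, lr = 0.05, epochs = 10000,
                     target_mse = 1e-5, seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 2) {
    abort("need at least 2 training samples", class = "ecoeff_domain_error")
  }
  if (nrow(x) != nrow(y)) {
    abort("x and y must have the same number of rows", class = "ecoeff_format_error")
  }
  rng_x <- apply(x, 2, range)
  rng_y <- apply(y, 2, range)
  if (any(rng_x[1, ] == rng_x[2, ])) {
    abort("constant input feature cannot be min-max normalized",
          class = "ecoeff_degenerate_error")
  }
  const_y <- rng_y[1, ] == rng_y[2, ]
  rng_y[2, const_y] <- rng_y[1, const_y] + 1  # constant target: trivially learnable
  Xn <- norm_pm1(x, rng_x)
  Yn <- norm_pm1(y, rng_y)
  n_in <- ncol(x); n_out <- ncol(y); n <- nrow(x)
  withr::local_seed(seed)
  W1 <- matrix(runif(hidden * n_in, -0.5, 0.5), hidden, n_in)
  b1 <- runif(hidden, -0.5, 0.5)
  W2 <- matrix(runif(n_out * hidden, -0.5, 0.5), n_out, hidden)
  b2 <- runif(n_out, -0.5, 0.5)
  mse <- NA_real_
  for (ep in seq_len(epochs)) {
    H <- 1 / (1 + exp(-(Xn %*% t(W1) + matrix(b1, n, hidden, byrow = TRUE))))
    Out <- H %*% t(W2) + matrix(b2, n, n_out, byrow = TRUE)
    E <- Out - Yn
    mse <- mean(E^2)
    if (!is.finite(mse)) {
      abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
            class = "ecoeff_divergence_error")
    }
    if (mse <= target_mse) break
    dOut <- 2 * E / (n * n_out)
    gW2 <- t(dOut) %*% H
    gb2 <- colSums(dOut)
    dH <- (dOut %*% W2) * H * (1 - H)
    gW1 <- t(dH) %*% Xn
    gb1 <- colSums(dH)
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 rng_x = rng_x, rng_y = rng_y,
                 mse = mse, epochs_run = ep, hidden = hidden, lr = lr,
                 seed = seed), class = "bp_net")
}

norm_pm1 <- function(m, rng) {
  sweep(sweep(m, 2, rng[1, ]), 2, (rng[2, ] - rng[1, ]) / 2, `/`) - 1
}

denorm_pm1 <- function(m, rng) {
  sweep(sweep(m + 1, 2, (rng[2, ] - rng[1, ]) / 2, `*`), 2, rng[1, ], `+`)
}

#' @export
print.bp_net <- function(x, ...) {
  cat(sprintf("<bp_net> %d-%d-%d, trained %d epochs, mse = %.3g\n",
              ncol(x$W1), x$hidden, nrow(x$W2), x$epochs_run, x$mse))
  invisible(x)
}

#' Predict from a trained back-propagation network
#'
#' @param object a `bp_net`.
#' @param newdata matrix (or vector) of input rows on the original scale.
#' @param ... unused.
#' @return Matrix of denormalized predictions.
#' @export
predict.bp_net <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object$W1)) x <- matrix(x, ncol = ncol(object$W1))
  Xn <- norm_pm1(x, object$rng_x)
  H <- 1 / (1 + exp(-(Xn %*% t(object$W1) +
                        matrix(object$b1, nrow(x), object$hidden, byrow = TRUE))))
  Out <- H %*% t(object$W2) +
    matrix(object$b2, nrow(x), nrow(object$W2), byrow = TRUE)
  denorm_pm1(Out, object$rng_y)
}

#' Grey-neural hybrid: GM(1,1) with BP residual correction
#'
#' Couples the grey model with the neural corrector: a GM(1,1) model is
#' fitted first; a BP network is then trained on sliding windows of past
#' GM residuals to predict the next residual; the combined value is the GM
#' fit/forecast plus the predicted residual, elementwise
#' (`combined - gm = correction`).  If the grey fit is already exact
#' (residuals numerically zero) the corrector is the zero function.
#'
#' @param x positive series or `year`/`value` data frame (see [fit_gm11()]).
#' @param window number of past residuals fed to the network.
#' @param hidden,lr,epochs,target_mse,seed passed to [train_bp()].
#' @param t0 label of the first period.
#' @return A `grey_hybrid` object: elements `gm` (the `gm11`), `bp` (the
#'   `bp_net` or NULL), `window`, and a `fitted` tibble with `period`,
#'   `actual`, `gm`, `correction`, `combined` (correction is zero where no
#'   residual window exists yet).
#' @export
grey_bp_hybrid <- function(x, window = 3, hidden = 5, lr = 0.05,
                           epochs = 10000, target_mse = 1e-5, seed = 1,
                           t0 = 1L) {
  gm <- fit_gm11(x, t0 = t0)
  n <- length(gm$data)
  if (n < window + 2) {
    abort(sprintf("series length %d too short for residual window %d (need >= window + 2)",
                  n, window), class = "ecoeff_domain_error")
  }
  q <- gm$residuals[-1]  # residuals for t = 2..n
  m <- length(q)
  samples <- m - window
  correction <- numeric(n)
  bp <- NULL
  if (max(abs(q)) > 1e-10 && samples >= 2) {
    Xtr <- t(vapply(seq_len(samples), function(i) q[i:(i + window - 1)],
                    numeric(window)))
    Ytr <- q[window + seq_len(samples)]
    bp <- train_bp(Xtr, Ytr, hidden = hidden, lr = lr, epochs = epochs,
                   target_mse = target_mse, seed = seed)
    pred <- drop(predict(bp, Xtr))
    # residual index window+1..m corresponds to period window+2..n
    correction[window + 1 + seq_len(samples)] <- pred
  }
  combined <- gm$fitted + correction
  structure(list(
    gm = gm, bp = bp, window = window,
    fitted = tibble(period = gm$t0 + seq_len(n) - 1, actual = gm$data,
                    gm = gm$fitted, correction = correction,
                    combined = combined)), class = "grey_hybrid")
}

#' @export
print.grey_hybrid <- function(x, ...) {
  err_gm <- mean_abs_error(100 * (x$fitted$actual - x$fitted$gm)[-1] / x$fitted$actual[-1])
  err_hy <- mean_abs_error(100 * (x$fitted$actual - x$fitted$combined)[-1] / x$fitted$actual[-1])
  cat(sprintf("<grey_hybrid> window %d; mean abs error %%: GM %.2f, hybrid %.2f\n",
              x$window, err_gm, err_hy))
  invisible(x)
}

#' @rdname forecast
#' @export
forecast.grey_hybrid <- function(object, h, ...) {
  if (h <= 0) abort("forecast horizon must be >= 1", class = "ecoeff_domain_error")
  gm <- object$gm
  n <- length(gm$data)
  gm_fc <- gm11_extrapolate(gm, n + seq_len(h))
  corr <- numeric(h)
  if (!is.null(object$bp)) {
    # roll the residual window forward on predicted residuals
    q <- gm$residuals[-1]
    buf <- tail(q, object$window)
    for (i in seq_len(h)) {
      corr[i] <- drop(predict(object$bp, matrix(buf, 1)))
      buf <- c(buf[-1], corr[i])
    }
  }
  tibble(period = gm$t0 + n - 1 + seq_len(h),
         gm = gm_fc, correction = corr, combined = gm_fc + corr)
}
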