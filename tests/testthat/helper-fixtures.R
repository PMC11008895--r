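# Shared fixtures and independent oracles, built in code.

# small well-formed panel for IO tests
toy_panel <- function() {
  tidyr::expand_grid(region = c("R1", "R2"), year = 2012:2014) |>
    dplyr::mutate(capital = c(10, 11, 12, 20, 21, 22),
                  labour = c(5, 5, 6, 7, 8, 8),
                  energy = c(3, 3, 4, 6, 6, 7),
                  gdp = c(8, 9, 10, 15, 16, 18),
                  carbon = c(2, 2, 3, 4, 4, 5))
}

ring4 <- function() make_lattice_weights(4, "ring")

path4 <- function() {
  w <- matrix(0, 4, 4)
  w[cbind(1:3, 2:4)] <- 1
  eco_weights(w + t(w))
}

# Independent DEA oracle: optimize the fractional SBM program directly over
# the lambda simplex (softmax parametrization, multi-start local search).
# Given lambda, slacks/projections are closed-form, so this touches none of
# the package's Charnes-Cooper/simplex machinery.
oracle_sbm <- function(X, Yg, Yb, eval, ref, n_starts = 40, seed = 1) {
  m <- nrow(X); s1 <- nrow(Yg); s2 <- if (is.null(Yb)) 0 else nrow(Yb)
  x0 <- X[, eval]; g0 <- Yg[, eval]
  b0 <- if (s2) Yb[, eval] else NULL
  K <- length(ref)
  score_of <- function(lam) {
    xl <- drop(X[, ref, drop = FALSE] %*% lam)
    gl <- drop(Yg[, ref, drop = FALSE] %*% lam)
    sx <- x0 - xl
    sg <- gl - g0
    viol <- sum(pmax(-sx / x0, 0)) + sum(pmax(-sg / g0, 0))
    if (s2) {
      bl <- drop(Yb[, ref, drop = FALSE] %*% lam)
      sb <- b0 - bl
      viol <- viol + sum(pmax(-sb / b0, 0))
      den <- 1 + (sum(pmax(sg, 0) / g0) + sum(pmax(sb, 0) / b0)) / (s1 + s2)
    } else {
      den <- 1 + sum(pmax(sg, 0) / g0) / s1
    }
    num <- 1 - mean(pmax(sx, 0) / x0)
    if (viol > 1e-9) return(2 + 100 * viol)  # graded infeasibility penalty
    num / den
  }
  best_over_starts(score_of, K, n_starts, seed)
}

oracle_super_sbm <- function(X, Yg, Yb, eval, ref, n_starts = 40, seed = 1) {
  m <- nrow(X); s1 <- nrow(Yg); s2 <- if (is.null(Yb)) 0 else nrow(Yb)
  x0 <- X[, eval]; g0 <- Yg[, eval]
  b0 <- if (s2) Yb[, eval] else NULL
  score_of <- function(lam) {
    xl <- drop(X[, ref, drop = FALSE] %*% lam)
    gl <- drop(Yg[, ref, drop = FALSE] %*% lam)
    xbar <- pmax(xl, x0)
    gbar <- pmin(gl, g0)
    if (any(gbar <= 0)) return(Inf)
    num <- sum(xbar / x0)
    if (s2) {
      bl <- drop(Yb[, ref, drop = FALSE] %*% lam)
      bbar <- pmax(bl, b0)
      num <- (num + sum(bbar / b0)) / (m + s2)
    } else {
      num <- num / m
    }
    num / (mean(gbar / g0))
  }
  best_over_starts(score_of, length(ref), n_starts, seed)
}

best_over_starts <- function(score_of, K, n_starts, seed) {
  if (K == 1) return(score_of(1))
  if (K == 2) {
    # one-dimensional simplex: dense grid plus local refinement
    f1 <- function(t) score_of(c(t, 1 - t))
    ts <- seq(0, 1, length.out = 20001)
    vals <- vapply(ts, f1, numeric(1))
    i <- which.min(vals)
    lo <- ts[max(1, i - 2)]; hi <- ts[min(length(ts), i + 2)]
    return(min(vals[i], optimize(f1, c(lo, hi), tol = 1e-12)$objective))
  }
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  obj <- function(z) score_of(softmax(c(0, z)))
  run_from <- function(st) {
    o <- tryCatch(optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15)),
                  error = function(e) list(par = st, value = Inf))
    # Nelder-Mead restarts from its own optimum recover lost digits
    for (k in 1:3) {
      o2 <- tryCatch(optim(o$par, obj, method = "Nelder-Mead",
                           control = list(maxit = 5000, reltol = 1e-15)),
                     error = function(e) o)
      if (o2$value < o$value) o <- o2 else break
    }
    o$value
  }
  withr::with_seed(seed, {
    starts <- c(list(numeric(K - 1)),
                lapply(seq_len(K), function(i) {
                  z <- rep(-8, K - 1); if (i > 1) z[i - 1] <- 8; z
                }),
                # sparse random supports reach low-dimensional faces
                lapply(seq_len(n_starts), function(i) {
                  z <- rnorm(K - 1, 0, 3)
                  drop_k <- sample(K - 1, sample(0:(K - 2), 1))
                  z[drop_k] <- -12
                  z
                }))
    min(vapply(starts, run_from, numeric(1)))
  })
}

# random positive DEA instance
random_dmus <- function(n, m, s1, s2, seed) {
  withr::with_seed(seed, {
    list(X = matrix(runif(m * n, 1, 10), m, n),
         Yg = matrix(runif(s1 * n, 1, 10), s1, n),
         Yb = if (s2) matrix(runif(s2 * n, 1, 10), s2, n) else NULL)
  })
}

dmu_df <- function(inst) {
  d <- as.data.frame(t(rbind(inst$X, inst$Yg, inst$Yb)))
  m <- nrow(inst$X); s1 <- nrow(inst$Yg)
  s2 <- if (is.null(inst$Yb)) 0 else nrow(inst$Yb)
  names(d) <- c(paste0("x", 1:m), paste0("g", 1:s1),
                if (s2) paste0("b", 1:s2))
  d$id <- paste0("D", seq_len(nrow(d)))
  d
}
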