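# Internal linear-programming backend.
#
# The DEA programs are small (tens of variables, ~a dozen rows), so they are
# solved with a dense two-phase primal simplex using Bland's anti-cycling
# rule: slower than a production LP code but immune to the degeneracy that
# SBM programs produce in quantity (many zero right-hand sides and ties).
#
# lp_solve(): min/max c'z  s.t.  A z (dir) b, z >= 0, with dir in
# {"=", "<=", ">="}.  Inequalities get explicit slack/surplus columns and
# rows are flipped so b >= 0 before the tableau is built.
lp_solve <- function(obj, A, dir, b, maximize = FALSE) {
  stopifnot(length(dir) == nrow(A), length(b) == nrow(A))
  n0 <- length(obj)
  extra <- sum(dir != "=")
  Afull <- cbind(A, matrix(0, nrow(A), extra))
  j <- n0
  for (i in seq_len(nrow(A))) {
    if (dir[i] == "<=") {
      j <- j + 1L
      Afull[i, j] <- 1
    } else if (dir[i] == ">=") {
      j <- j + 1L
      Afull[i, j] <- -1
    }
  }
  flip <- b < 0
  Afull[flip, ] <- -Afull[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  cc <- c(obj, numeric(extra))
  if (maximize) cc <- -cc
  res <- simplex_two_phase(cc, Afull, b)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_,
                solution = rep(NA_real_, n0)))
  }
  val <- sum(cc * res$x)
  list(status = "optimal", value = if (maximize) -val else val,
       solution = res$x[seq_len(n0)])
}

# min c'x s.t. Ax = b, x >= 0, b >= 0
simplex_two_phase <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificials form the starting basis
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(numeric(n), rep(1, m))
  r <- simplex_iterate(Tab, basis, cost1, ncol = n + m, tol = tol)
  Tab <- r$Tab; basis <- r$basis
  if (sum(cost1[basis] * Tab[, n + m + 1]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  # drive leftover artificials out of the basis (degenerate rows)
  drop_rows <- integer()
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(Tab[i, seq_len(n)]) > tol)[1]
      if (is.na(piv)) {
        drop_rows <- c(drop_rows, i)  # redundant constraint
      } else {
        Tab <- pivot_tableau(Tab, i, piv)
        basis[i] <- piv
      }
    }
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on original columns only
  Tab2 <- Tab[, c(seq_len(n), n + m + 1), drop = FALSE]
  r2 <- simplex_iterate(Tab2, basis, cc, ncol = n, tol = tol)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  x[r2$basis] <- r2$Tab[, n + 1]
  list(status = "optimal", x = x)
}

# Bland's rule iterations on a tableau whose last column is the rhs
simplex_iterate <- function(Tab, basis, cost, ncol, tol = 1e-9,
                            max_iter = 100000L) {
  rhs_col <- ncol(Tab)
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    # reduced costs over eligible columns
    red <- cost[seq_len(ncol)] - drop(crossprod(Tab[, seq_len(ncol), drop = FALSE], cb))
    enter <- which(red < -tol)
    if (!length(enter)) {
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    }
    e <- enter[1L]  # Bland: smallest index
    col <- Tab[, e]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(Tab = Tab, basis = basis, status = "unbounded"))
    }
    ratios <- Tab[pos, rhs_col] / col[pos]
    best <- min(ratios)
    cand <- pos[ratios <= best + tol]
    l <- cand[which.min(basis[cand])]  # Bland: smallest basis index on ties
    Tab <- pivot_tableau(Tab, l, e)
    basis[l] <- e
  }
  list(Tab = Tab, basis = basis, status = "maxiter")
}

pivot_tableau <- function(Tab, row, col) {
  Tab[row, ] <- Tab[row, ] / Tab[row, col]
  other <- setdiff(seq_len(nrow(Tab)), row)
  Tab[other, ] <- Tab[other, , drop = FALSE] -
    outer(Tab[other, col], Tab[row, ])
  Tab
}
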