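#' Slack-based-measure (SBM) efficiency with an undesirable output
#'
#' Solves, for every decision-making unit (DMU; here a region-year), the
#' non-radial SBM program via the Charnes-Cooper linearization.  The score is
#' \deqn{\rho = \frac{1 - \frac1m \sum_i s^-_i/x_{i0}}
#'                   {1 + \frac1s \left(\sum_r s^g_r/y^g_{r0} +
#'                    \sum_r s^b_r/y^b_{r0}\right)} \in (0, 1],}
#' equal to 1 iff every slack is zero.  Undesirable outputs (carbon) enter as
#' reduction slacks by default (`bad_mode = "output"`); `bad_mode = "input"`
#' treats them as inputs instead, since their accounting treatment is a
#' modelling choice.  Returns to scale default to VRS (the convexity
#' constraint \eqn{\sum_k \lambda_k = 1}).
#'
#' Alternate optima are resolved by a lexicographic second stage that fixes
#' the optimal score and maximizes total normalized slack, so reported slacks
#' are the maximal ones supporting the score.
#'
#' @param data data frame of DMUs, one row each.
#' @param inputs,good,bad character vectors of column names for inputs,
#'   desirable outputs, undesirable outputs (`bad = NULL` for none). All must
#'   be strictly positive.
#' @param id columns identifying the DMU (defaults to all columns not used
#'   as data).
#' @param returns `"vrs"` or `"crs"`.
#' @param bad_mode `"output"` (reduction slacks) or `"input"`.
#' @return A tibble: id columns, `score`, `status`, one `slack_*` column per
#'   input/output, and a `lambda` list column of named peer weights.
#' @export
sbm_efficiency <- function(data, inputs, good, bad = NULL, id = NULL,
                           returns = c("vrs", "crs"),
                           bad_mode = c("output", "input")) {
  returns <- match.arg(returns)
  bad_mode <- match.arg(bad_mode)
  tech <- dea_technology(data, inputs, good, bad, id, bad_mode)
  res <- purrr::map(seq_len(tech$n), function(j) {
    sbm_one(tech, eval = j, ref = seq_len(tech$n), returns = returns)
  })
  dea_bind(tech, res, super = FALSE)
}

#' Super-efficiency SBM
#'
#' Plain SBM scores for inefficient units; for units scoring exactly 1 the
#' evaluated DMU is removed from its own reference set and the
#' super-efficiency program is solved, giving a score >= 1 that ranks
#' efficient units by their distance to the frontier of the remaining DMUs.
#' Undesirable outputs behave like inputs on the super side (the projection
#' may raise them toward the peers' levels), the reading under which
#' super-efficiency scores exceed 1 exactly for frontier units.
#'
#' @inheritParams sbm_efficiency
#' @return As [sbm_efficiency()], plus a logical `super` column flagging
#'   units scored by the super-efficiency program.
#' @export
super_sbm_efficiency <- function(data, inputs, good, bad = NULL, id = NULL,
                                 returns = c("vrs", "crs"),
                                 bad_mode = c("output", "input")) {
  returns <- match.arg(returns)
  bad_mode <- match.arg(bad_mode)
  tech <- dea_technology(data, inputs, good, bad, id, bad_mode)
  if (tech$n < 2) {
    abort("super-efficiency needs at least 2 DMUs", class = "ecoeff_domain_error")
  }
  res <- purrr::map(seq_len(tech$n), function(j) {
    plain <- sbm_one(tech, eval = j, ref = seq_len(tech$n), returns = returns)
    if (plain$status == "optimal" && plain$score >= 1 - 1e-9) {
      sup <- super_sbm_one(tech, eval = j, ref = setdiff(seq_len(tech$n), j),
                           returns = returns)
      sup$super <- TRUE
      sup
    } else {
      plain$super <- FALSE
      plain
    }
  })
  dea_bind(tech, res, super = TRUE)
}

#' Mean efficiency against contemporaneous, sequential and global frontiers
#'
#' For each year reports three mean SBM scores: `Dt` against the same-year
#' frontier, `Do` against the cumulative frontier of all years up to and
#' including the current one (sequential technology), and `Dg` against the
#' pooled all-year (global) frontier.  Because the reference sets are nested,
#' `Dg <= Do <= Dt` holds for every DMU before averaging.  Years with fewer
#' than 2 DMUs are flagged and skipped.
#'
#' @inheritParams sbm_efficiency
#' @param year name of the year column.
#' @return Tibble `year`, `n`, `Dt`, `Do`, `Dg`, `skipped`.
#' @export
frontier_distances <- function(data, inputs, good, bad = NULL, year = "year",
                               returns = c("vrs", "crs"),
                               bad_mode = c("output", "input")) {
  returns <- match.arg(returns)
  bad_mode <- match.arg(bad_mode)
  years <- sort(unique(data[[year]]))
  if (length(years) < 2) {
    abort("frontier_distances needs at least 2 years", class = "ecoeff_domain_error")
  }
  tech <- dea_technology(data, inputs, good, bad, id = NULL, bad_mode)
  yr <- data[[year]]
  purrr::map_dfr(years, function(yy) {
    here <- which(yr == yy)
    if (length(here) < 2) {
      return(tibble(year = yy, n = length(here), Dt = NA_real_, Do = NA_real_,
                    Dg = NA_real_, skipped = TRUE))
    }
    score_vs <- function(ref) {
      vapply(here, function(j) {
        sbm_one(tech, eval = j, ref = union(ref, j), returns = returns,
                second_stage = FALSE)$score
      }, numeric(1))
    }
    tibble(year = yy, n = length(here),
           Dt = mean(score_vs(here)),
           Do = mean(score_vs(which(yr <= yy))),
           Dg = mean(score_vs(seq_len(tech$n))),
           skipped = FALSE)
  })
}

# ---- internals -------------------------------------------------------------

# assemble the production technology; bad_mode "input" folds bads into X
dea_technology <- function(data, inputs, good, bad, id, bad_mode) {
  cols <- c(inputs, good, bad)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("column(s) not in data: %s", paste(missing, collapse = ", ")),
          class = "ecoeff_lookup_error")
  }
  M <- as.matrix(data[, cols, drop = FALSE])
  if (any(!is.finite(M)) || any(M <= 0)) {
    abort("DEA requires strictly positive, finite inputs and outputs",
          class = "ecoeff_domain_error")
  }
  if (nrow(M) < 2) {
    abort("need at least 2 DMUs", class = "ecoeff_domain_error")
  }
  if (bad_mode == "input") {
    x_cols <- c(inputs, bad); b_cols <- character()
  } else {
    x_cols <- inputs; b_cols <- bad %||% character()
  }
  id <- id %||% setdiff(names(data), cols)
  list(n = nrow(M),
       X = t(M[, x_cols, drop = FALSE]),
       Yg = t(M[, good, drop = FALSE]),
       Yb = t(M[, b_cols, drop = FALSE]),
       ids = data[, id, drop = FALSE],
       x_cols = x_cols, g_cols = good, b_cols = b_cols)
}

# plain SBM for one DMU. Variables: t, Lambda[ref], S-[m], Sg[s1], Sb[s2].
sbm_one <- function(tech, eval, ref, returns, second_stage = TRUE) {
  X <- tech$X; Yg <- tech$Yg; Yb <- tech$Yb
  m <- nrow(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  s <- s1 + s2
  K <- length(ref)
  x0 <- X[, eval]; g0 <- Yg[, eval, drop = TRUE]
  b0 <- if (s2) Yb[, eval, drop = TRUE] else numeric()
  nv <- 1 + K + m + s1 + s2
  iT <- 1; iL <- 1 + seq_len(K); iSx <- 1 + K + seq_len(m)
  iSg <- 1 + K + m + seq_len(s1); iSb <- 1 + K + m + s1 + seq_len(s2)
  obj <- numeric(nv); obj[iT] <- 1; obj[iSx] <- -1 / (m * x0)
  rows <- list(); dir <- character(); b <- numeric()
  add <- function(r, d, rhs) {
    rows[[length(rows) + 1]] <<- r; dir <<- c(dir, d); b <<- c(b, rhs)
  }
  r1 <- numeric(nv); r1[iT] <- 1
  r1[iSg] <- 1 / (s * g0)
  if (s2) r1[iSb] <- 1 / (s * b0)
  add(r1, "=", 1)
  for (i in seq_len(m)) {
    r <- numeric(nv); r[iT] <- x0[i]; r[iL] <- -X[i, ref]; r[iSx[i]] <- -1
    add(r, "=", 0)
  }
  for (rr in seq_len(s1)) {
    r <- numeric(nv); r[iT] <- g0[rr]; r[iL] <- -Yg[rr, ref]; r[iSg[rr]] <- 1
    add(r, "=", 0)
  }
  for (rr in seq_len(s2)) {
    r <- numeric(nv); r[iT] <- b0[rr]; r[iL] <- -Yb[rr, ref]; r[iSb[rr]] <- -1
    add(r, "=", 0)
  }
  if (returns == "vrs") {
    r <- numeric(nv); r[iL] <- 1; r[iT] <- -1
    add(r, "=", 0)
  }
  A <- do.call(rbind, rows)
  sol1 <- lp_solve(obj, A, dir, b)
  if (sol1$status != "optimal") {
    return(list(score = NA_real_, status = sol1$status,
                slack_x = rep(NA_real_, m), slack_g = rep(NA_real_, s1),
                slack_b = rep(NA_real_, s2), lambda = numeric()))
  }
  z <- sol1$solution
  if (second_stage) {
    # fix the optimal score, maximize total normalized slack
    A2 <- rbind(A, obj)
    sol2 <- lp_solve(obj2_weights(x0, g0, b0, iSx, iSg, iSb, nv),
                     A2, c(dir, "="), c(b, sol1$value), maximize = TRUE)
    if (sol2$status == "optimal") z <- sol2$solution
  }
  tt <- z[iT]
  lam <- z[iL] / tt
  names(lam) <- as.character(ref)
  list(score = sol1$value, status = "optimal",
       slack_x = z[iSx] / tt,
       slack_g = if (s1) z[iSg] / tt else numeric(),
       slack_b = if (s2) z[iSb] / tt else numeric(),
       lambda = lam[lam > 1e-9])
}

obj2_weights <- function(x0, g0, b0, iSx, iSg, iSb, nv) {
  w <- numeric(nv)
  w[iSx] <- 1 / x0
  if (length(g0)) w[iSg] <- 1 / g0
  if (length(b0)) w[iSb] <- 1 / b0
  w
}

# super-SBM for one (efficient) DMU evaluated against ref (eval excluded).
# Variables: t, Lambda[ref], Xbar[m], Ygbar[s1], Ybbar[s2]; all scaled by t.
super_sbm_one <- function(tech, eval, ref, returns) {
  X <- tech$X; Yg <- tech$Yg; Yb <- tech$Yb
  m <- nrow(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  K <- length(ref)
  if (K == 0) {
    abort("empty reference set after excluding the evaluated DMU",
          class = "ecoeff_domain_error")
  }
  x0 <- X[, eval]; g0 <- Yg[, eval, drop = TRUE]
  b0 <- if (s2) Yb[, eval, drop = TRUE] else numeric()
  nv <- 1 + K + m + s1 + s2
  iT <- 1; iL <- 1 + seq_len(K); iX <- 1 + K + seq_len(m)
  iG <- 1 + K + m + seq_len(s1); iB <- 1 + K + m + s1 + seq_len(s2)
  obj <- numeric(nv); obj[iX] <- 1 / ((m + s2) * x0)
  if (s2) obj[iB] <- 1 / ((m + s2) * b0)
  rows <- list(); dir <- character(); b <- numeric()
  add <- function(r, d, rhs) {
    rows[[length(rows) + 1]] <<- r; dir <<- c(dir, d); b <<- c(b, rhs)
  }
  r1 <- numeric(nv); r1[iG] <- 1 / (s1 * g0)
  add(r1, "=", 1)
  for (i in seq_len(m)) {
    r <- numeric(nv); r[iX[i]] <- 1; r[iL] <- -X[i, ref]; add(r, ">=", 0)
    r <- numeric(nv); r[iX[i]] <- 1; r[iT] <- -x0[i]; add(r, ">=", 0)
  }
  for (rr in seq_len(s1)) {
    r <- numeric(nv); r[iL] <- Yg[rr, ref]; r[iG[rr]] <- -1; add(r, ">=", 0)
    r <- numeric(nv); r[iT] <- g0[rr]; r[iG[rr]] <- -1; add(r, ">=", 0)
  }
  for (rr in seq_len(s2)) {
    r <- numeric(nv); r[iB[rr]] <- 1; r[iL] <- -Yb[rr, ref]; add(r, ">=", 0)
    r <- numeric(nv); r[iB[rr]] <- 1; r[iT] <- -b0[rr]; add(r, ">=", 0)
  }
  if (returns == "vrs") {
    r <- numeric(nv); r[iL] <- 1; r[iT] <- -1; add(r, "=", 0)
  } else {
    # CRS still needs t tied to the scale of the program
    r <- numeric(nv); r[iT] <- 1; add(r, ">=", 1e-9)
  }
  sol <- lp_solve(obj, do.call(rbind, rows), dir, b)
  if (sol$status != "optimal") {
    return(list(score = NA_real_, status = sol$status,
                slack_x = rep(NA_real_, m), slack_g = rep(NA_real_, s1),
                slack_b = rep(NA_real_, s2), lambda = numeric()))
  }
  z <- sol$solution
  tt <- z[iT]
  lam <- z[iL] / tt
  names(lam) <- as.character(ref)
  # super "slacks" reported as the projection excesses/shortfalls
  list(score = sol$value, status = "optimal",
       slack_x = z[iX] / tt - x0,
       slack_g = if (s1) g0 - z[iG] / tt else numeric(),
       slack_b = if (s2) z[iB] / tt - b0 else numeric(),
       lambda = lam[lam > 1e-9])
}

dea_bind <- function(tech, res, super) {
  slack_names <- c(paste0("slack_", tech$x_cols),
                   paste0("slack_", tech$g_cols),
                   if (length(tech$b_cols)) paste0("slack_", tech$b_cols))
  slacks <- purrr::map(res, function(r) {
    setNames(c(r$slack_x, r$slack_g, r$slack_b), slack_names)
  })
  out <- dplyr::bind_cols(
    as_tibble(tech$ids),
    tibble(score = purrr::map_dbl(res, "score"),
           status = purrr::map_chr(res, "status")))
  if (super) out$super <- purrr::map_lgl(res, "super")
  out <- dplyr::bind_cols(out, dplyr::bind_rows(slacks))
  lam_ids <- if (ncol(tech$ids)) {
    do.call(paste, c(as.list(tech$ids), sep = "/"))
  } else {
    as.character(seq_len(tech$n))
  }
  out$lambda <- purrr::map(res, function(r) {
    setNames(as.numeric(r$lambda), lam_ids[as.integer(names(r$lambda))])
  })
  out
}
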