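#' Discretize a panel variable into efficiency states
#'
#' Assigns each region-year value to one of `k` quantile states (state 1 =
#' lowest).  `mode = "pooled"` (default) computes the quantile breaks from
#' all region-years jointly; `mode = "per-year"` recomputes them within each
#' year so states are relative positions in that year's cross-section.
#' Boundary values go to the lower state.  Precomputed breaks may be passed
#' so that, e.g., spatial-lag values are classified on the same bins as the
#' originals.
#'
#' @param data long panel.
#' @param value name of the value column.
#' @param k number of states (default 4, quartiles).
#' @param mode `"pooled"` or `"per-year"`.
#' @param breaks optional numeric vector of breaks (overrides `k`/`mode`).
#' @param region,year key column names.
#' @return Tibble `region`, `year`, `state` (integer 1..k), with the pooled
#'   breaks in attribute `"breaks"` when `mode = "pooled"`.
#' @export
discretize_states <- function(data, value, k = 4,
                              mode = c("pooled", "per-year"),
                              breaks = NULL, region = "region", year = "year") {
  mode <- match.arg(mode)
  if (is.null(breaks) && k < 2) {
    abort("k must be >= 2", class = "ecoeff_domain_error")
  }
  x <- data[[value]]
  if (anyNA(x)) abort("value column contains NA", class = "ecoeff_domain_error")
  cut_states <- function(v, brk) {
    brk[1] <- -Inf; brk[length(brk)] <- Inf
    as.integer(cut(v, breaks = brk, labels = FALSE, right = TRUE))
  }
  out <- tibble(region = data[[region]], year = data[[year]])
  if (!is.null(breaks)) {
    out$state <- cut_states(x, breaks)
  } else if (mode == "pooled") {
    brk <- quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE)
    if (anyDuplicated(brk)) {
      abort("values too degenerate for k quantile bins", class = "ecoeff_degenerate_error")
    }
    out$state <- cut_states(x, brk)
    attr(out, "breaks") <- brk
  } else {
    out$state <- NA_integer_
    for (yy in unique(out$year)) {
      sel <- out$year == yy
      brk <- quantile(x[sel], probs = seq(0, 1, length.out = k + 1), names = FALSE)
      if (anyDuplicated(brk)) {
        abort(sprintf("values in year %s too degenerate for k quantile bins", yy),
              class = "ecoeff_degenerate_error")
      }
      out$state[sel] <- cut_states(x[sel], brk)
    }
  }
  out
}

#' Markov transition-probability matrix of efficiency states
#'
#' Counts transitions over all consecutive (t, t+1) year pairs within each
#' region and converts rows to probabilities.  Rows with no observed
#' origin are reported as `NA` (undefined) rather than zero-filled, so every
#' observed row sums to exactly one.
#'
#' @param states a tibble from [discretize_states()] (columns `region`,
#'   `year`, `state`).
#' @param k number of states; defaults to `max(states$state)`.
#' @return An `eco_transition` object: list with `k`, integer `counts`
#'   (k x k), `probs` (k x k, rows summing to 1 or NA), and per-state origin
#'   counts `n_row`.
#' @export
transition_matrix <- function(states, k = max(states$state)) {
  pairs <- transition_pairs(states)
  if (!nrow(pairs)) {
    abort("no consecutive-year transitions in the state panel",
          class = "ecoeff_domain_error")
  }
  counts <- matrix(0L, k, k, dimnames = list(from = 1:k, to = 1:k))
  for (i in seq_len(nrow(pairs))) {
    counts[pairs$from[i], pairs$to[i]] <- counts[pairs$from[i], pairs$to[i]] + 1L
  }
  new_transition(counts)
}

new_transition <- function(counts) {
  n_row <- rowSums(counts)
  probs <- counts / ifelse(n_row > 0, n_row, NA_real_)
  structure(list(k = nrow(counts), counts = counts, probs = probs,
                 n_row = n_row), class = "eco_transition")
}

#' @export
print.eco_transition <- function(x, digits = 4, ...) {
  cat(sprintf("<eco_transition> %d states, %d transitions\n", x$k, sum(x$counts)))
  print(round(x$probs, digits))
  invisible(x)
}

transition_pairs <- function(states) {
  states |>
    dplyr::arrange(.data$region, .data$year) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(to = dplyr::lead(.data$state),
                  next_year = dplyr::lead(.data$year)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to), .data$next_year == .data$year + 1) |>
    dplyr::transmute(region = .data$region, year = .data$year,
                     from = .data$state, to = .data$to)
}

#' Spatial Markov transition matrices conditioned on the neighbourhood state
#'
#' Stratifies the ordinary transition counts by the spatial-lag state of the
#' origin year: one transition matrix per neighbourhood class, answering
#' whether a region's mobility depends on how well its neighbours are doing.
#' Lag states should be the spatial lag of the same underlying values,
#' discretized on the same bins (see [discretize_states()]'s `breaks`).
#' Summed over classes, the stratified counts reproduce the ordinary counts.
#'
#' @param states state panel for the regions.
#' @param lag_states state panel for the spatially lagged values; must have
#'   exactly the same (region, year) keys.
#' @param k number of states.
#' @return An `eco_spatial_transition` object: list of `eco_transition`
#'   objects, one per lag class `1..k`.
#' @export
spatial_transition_matrices <- function(states, lag_states,
                                        k = max(states$state)) {
  key <- function(d) paste(d$region, d$year, sep = "\r")
  if (!setequal(key(states), key(lag_states)) ||
      nrow(states) != nrow(lag_states)) {
    abort("states and lag_states must share exactly the same (region, year) keys",
          class = "ecoeff_integrity_error")
  }
  lag_lookup <- setNames(lag_states$state, key(lag_states))
  pairs <- transition_pairs(states)
  pairs$lag <- lag_lookup[paste(pairs$region, pairs$year, sep = "\r")]
  k_lag <- max(k, max(lag_states$state))
  mats <- purrr::map(seq_len(k_lag), function(cls) {
    counts <- matrix(0L, k, k, dimnames = list(from = 1:k, to = 1:k))
    sub <- pairs[pairs$lag == cls, ]
    for (i in seq_len(nrow(sub))) {
      counts[sub$from[i], sub$to[i]] <- counts[sub$from[i], sub$to[i]] + 1L
    }
    new_transition(counts)
  })
  structure(list(k = k, classes = mats), class = "eco_spatial_transition")
}

#' @export
print.eco_spatial_transition <- function(x, digits = 4, ...) {
  for (cls in seq_along(x$classes)) {
    cat(sprintf("-- neighbourhood state %d --\n", cls))
    print(x$classes[[cls]], digits = digits)
  }
  invisible(x)
}
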