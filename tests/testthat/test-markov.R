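test_that("quantile discretization assigns states by quartile with ties downward", {
  d <- tibble::tibble(region = paste0("R", 1:8), year = 1, v = 1:8)
  s <- discretize_states(d, "v", k = 4)
  expect_equal(s$state, c(1, 1, 2, 2, 3, 3, 4, 4))

  dd <- tibble::tibble(region = paste0("R", 1:4), year = 1, v = rep(3, 4))
  expect_error(discretize_states(dd, "v", k = 4), class = "ecoeff_degenerate_error")

  # boundary value goes to the lower state (median of 1..5 is the value 3)
  d2 <- tibble::tibble(region = paste0("R", 1:5), year = 1, v = 1:5)
  brk <- attr(discretize_states(d2, "v", k = 2), "breaks")
  expect_equal(brk[2], 3)
  s2 <- discretize_states(d2, "v", breaks = brk)
  expect_equal(s2$state, c(1, 1, 1, 2, 2))
})

test_that("per-year discretization depends only on within-year ranks", {
  d <- tidyr::expand_grid(region = paste0("R", 1:8), year = 1:2) |>
    dplyr::mutate(v = withr::with_seed(2, rnorm(16)))
  s <- discretize_states(d, "v", k = 4, mode = "per-year")
  d2 <- d
  d2$v <- d2$v * 100 + 5  # monotone transform preserves ranks
  s2 <- discretize_states(d2, "v", k = 4, mode = "per-year")
  expect_equal(s$state, s2$state)
  for (yy in 1:2) expect_setequal(s$state[s$year == yy], rep(1:4, 2))
})

test_that("transition matrices count consecutive-year moves and are row-stochastic", {
  s1 <- tibble::tibble(region = "A", year = 1:3, state = c(1, 1, 1))
  t1 <- transition_matrix(s1, k = 4)
  expect_equal(t1$probs[1, 1], 1)
  expect_true(all(is.na(t1$probs[2:4, ])))

  s2 <- tibble::tibble(region = "A", year = 1:4, state = c(1, 2, 1, 2))
  t2 <- transition_matrix(s2, k = 2)
  expect_equal(t2$probs, matrix(c(0, 1, 1, 0), 2, byrow = TRUE,
                                dimnames = list(from = 1:2, to = 1:2)))
  observed <- t2$n_row > 0
  expect_equal(rowSums(t2$probs)[observed], c(`1` = 1, `2` = 1), tolerance = 1e-12)

  expect_error(transition_matrix(tibble::tibble(region = "A", year = 1, state = 1)),
               class = "ecoeff_domain_error")
})

test_that("transition probabilities are invariant to region relabelling", {
  d <- tidyr::expand_grid(region = paste0("R", 1:6), year = 1:5) |>
    dplyr::mutate(v = withr::with_seed(7, rnorm(30)))
  s <- discretize_states(d, "v", k = 3)
  t1 <- transition_matrix(s)
  s2 <- s
  s2$region <- factor(s2$region, labels = rev(LETTERS[1:6]))
  expect_equal(transition_matrix(s2)$probs, t1$probs)
})

test_that("spatial stratification conserves counts and matches enumeration", {
  # two regions, 3 years, hand-enumerable
  s <- tibble::tibble(region = rep(c("A", "B"), each = 3), year = rep(1:3, 2),
                      state = c(1, 2, 2, 2, 2, 1))
  lag <- tibble::tibble(region = s$region, year = s$year,
                        state = c(2, 2, 1, 1, 2, 2))
  sp <- spatial_transition_matrices(s, lag, k = 2)
  # transitions: A 1->2 (lag 2), A 2->2 (lag 2), B 2->2 (lag 1), B 2->1 (lag 2)
  expect_equal(sp$classes[[1]]$counts[2, 2], 1L)
  expect_equal(sum(sp$classes[[1]]$counts), 1L)
  expect_equal(sp$classes[[2]]$counts[1, 2], 1L)
  expect_equal(sp$classes[[2]]$counts[2, 2], 1L)
  expect_equal(sp$classes[[2]]$counts[2, 1], 1L)
  # conservation against the ordinary matrix
  tot <- transition_matrix(s, k = 2)
  expect_equal(Reduce(`+`, lapply(sp$classes, function(m) m$counts)), tot$counts)

  # constant lag state: single class equals the ordinary matrix
  lag1 <- dplyr::mutate(lag, state = 1L)
  sp1 <- spatial_transition_matrices(s, lag1, k = 2)
  expect_equal(sp1$classes[[1]]$counts, tot$counts)

  expect_error(spatial_transition_matrices(s, lag[-1, ]),
               class = "ecoeff_integrity_error")
})
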