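test_that("SBM scores match single-slack closed forms", {
  d <- tibble::tibble(id = c("A", "B"), x = c(1, 2), y = c(1, 1))
  r <- sbm_efficiency(d, inputs = "x", good = "y", id = "id")
  expect_equal(r$score, c(1, 0.5))      # B: 1 - s/x = 1 - 1/2
  expect_equal(r$slack_x, c(0, 1))
  expect_equal(r$status, rep("optimal", 2))

  # identical DMUs leave no slack anywhere
  d2 <- tibble::tibble(id = c("A", "B"), x = c(3, 3), y = c(2, 2))
  expect_equal(sbm_efficiency(d2, inputs = "x", good = "y", id = "id")$score,
               c(1, 1))
})

test_that("reported score is self-consistent with reported slacks", {
  inst <- random_dmus(6, m = 2, s1 = 1, s2 = 1, seed = 21)
  d <- dmu_df(inst)
  r <- sbm_efficiency(d, inputs = c("x1", "x2"), good = "g1", bad = "b1", id = "id")
  for (j in seq_len(nrow(d))) {
    num <- 1 - mean(c(r$slack_x1[j] / d$x1[j], r$slack_x2[j] / d$x2[j]))
    den <- 1 + (r$slack_g1[j] / d$g1[j] + r$slack_b1[j] / d$b1[j]) / 2
    expect_equal(r$score[j], num / den, tolerance = 1e-9)
  }
})

test_that("super-efficiency ranks efficient units above 1 and keeps plain scores below", {
  d <- tibble::tibble(id = c("A", "B"), x = c(1, 2), y = c(1, 1))
  r <- super_sbm_efficiency(d, inputs = "x", good = "y", id = "id")
  expect_equal(r$score[r$id == "A"], 2)  # A must double x to reach B's frontier
  expect_equal(r$score[r$id == "B"], 0.5)
  expect_true(r$super[r$id == "A"])
  expect_false(r$super[r$id == "B"])

  # two identical DMUs each lie on the other's frontier
  d2 <- tibble::tibble(id = c("A", "B"), x = c(1, 1), y = c(1, 1))
  expect_equal(super_sbm_efficiency(d2, inputs = "x", good = "y", id = "id")$score,
               c(1, 1))
  expect_error(super_sbm_efficiency(d2[1, ], inputs = "x", good = "y", id = "id"),
               class = "ecoeff_domain_error")
})

test_that("scores are invariant to rescaling any input or output column", {
  inst <- random_dmus(5, m = 2, s1 = 1, s2 = 1, seed = 31)
  d <- dmu_df(inst)
  base <- super_sbm_efficiency(d, inputs = c("x1", "x2"), good = "g1",
                               bad = "b1", id = "id")$score
  d2 <- dplyr::mutate(d, x2 = x2 * 1000, g1 = g1 / 250, b1 = b1 * 3)
  scaled <- super_sbm_efficiency(d2, inputs = c("x1", "x2"), good = "g1",
                                 bad = "b1", id = "id")$score
  expect_equal(base, scaled, tolerance = 1e-9)
})

test_that("weak dominance never lowers an SBM score", {
  inst <- random_dmus(5, m = 2, s1 = 1, s2 = 0, seed = 41)
  d <- dmu_df(inst)
  base <- sbm_efficiency(d, inputs = c("x1", "x2"), good = "g1", id = "id")$score
  d2 <- d
  d2$x1[3] <- d2$x1[3] * 0.8   # strictly better inputs for DMU 3
  d2$g1[3] <- d2$g1[3] * 1.2   # strictly better output
  better <- sbm_efficiency(d2, inputs = c("x1", "x2"), good = "g1", id = "id")$score
  expect_gte(better[3], base[3] - 1e-9)
})

test_that("plain and super SBM agree with the direct fractional-program oracle", {
  cases <- list(list(n = 4, m = 2, s1 = 1, s2 = 0, seed = 51),
                list(n = 5, m = 2, s1 = 1, s2 = 1, seed = 52),
                list(n = 6, m = 3, s1 = 1, s2 = 1, seed = 53))
  for (cs in cases) {
    inst <- random_dmus(cs$n, cs$m, cs$s1, cs$s2, cs$seed)
    d <- dmu_df(inst)
    inputs <- paste0("x", seq_len(cs$m))
    bad <- if (cs$s2) "b1" else NULL
    r <- super_sbm_efficiency(d, inputs = inputs, good = "g1", bad = bad, id = "id")
    for (j in seq_len(cs$n)) {
      ref_all <- seq_len(cs$n)
      o_plain <- oracle_sbm(inst$X, inst$Yg, inst$Yb, j, ref_all)
      if (o_plain >= 1 - 1e-6) {
        o <- oracle_super_sbm(inst$X, inst$Yg, inst$Yb, j, setdiff(ref_all, j))
      } else {
        o <- o_plain
      }
      expect_equal(r$score[j], o, tolerance = 1e-6,
                   label = sprintf("seed %d DMU %d", cs$seed, j))
    }
  }
})

test_that("frontier comparison is nested and degenerate years are skipped", {
  # identical technology in both years: all three frontiers coincide
  d <- tibble::tibble(region = rep(c("A", "B"), 2),
                      year = rep(1:2, each = 2),
                      x = c(1, 2, 1, 2), g = c(1, 1, 1, 1))
  fd <- frontier_distances(d, inputs = "x", good = "g", year = "year")
  expect_equal(fd$Dt, fd$Do)
  expect_equal(fd$Do, fd$Dg)

  # expanding frontier: last year's contemporaneous mean exceeds global
  d2 <- tibble::tibble(region = rep(c("A", "B"), 3),
                       year = rep(1:3, each = 2),
                       x = c(1, 2, 1, 2, 1, 2),
                       g = c(1, 1, 2, 2, 4, 4))
  fd2 <- frontier_distances(d2, inputs = "x", good = "g", year = "year")
  expect_true(all(fd2$Dg <= fd2$Do + 1e-9))
  expect_true(all(fd2$Do <= fd2$Dt + 1e-9))
  expect_lt(fd2$Dg[1], fd2$Dt[1])

  # a single-DMU year is flagged, others still computed
  d3 <- dplyr::bind_rows(d2, tibble::tibble(region = "A", year = 4, x = 1, g = 8))
  fd3 <- frontier_distances(d3, inputs = "x", good = "g", year = "year")
  expect_true(fd3$skipped[fd3$year == 4])
  expect_false(any(fd3$skipped[fd3$year != 4]))
})

test_that("nonpositive data are a domain error", {
  d <- tibble::tibble(id = c("A", "B"), x = c(1, 0), y = c(1, 1))
  expect_error(sbm_efficiency(d, inputs = "x", good = "y", id = "id"),
               class = "ecoeff_domain_error")
})
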