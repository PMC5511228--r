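pair_matrix <- function(s_i, s_j, s_ij) {
  # build an explicit two-island matrix with the requested overlap structure
  n <- s_i + s_j - s_ij
  m <- matrix(0L, n, 2, dimnames = list(sprintf("sp%02d", seq_len(n)),
                                        c("i1", "i2")))
  if (s_i > 0) m[seq_len(s_i), 1] <- 1L
  if (s_j > 0) m[seq(s_i - s_ij + 1, length.out = s_j), 2] <- 1L
  m
}

test_that("hand-computed SDR triples are reproduced", {
  tri <- sdr_pair(pair_matrix(5, 3, 2), "i1", "i2")
  expect_equal(unname(tri[c("S", "D", "R")]), c(1/3, 1/3, 1/3))

  # disjoint islands with 3 and 5 species
  tri <- sdr_pair(pair_matrix(3, 5, 0), "i1", "i2")
  expect_equal(unname(tri[c("S", "D", "R")]), c(0, 0.25, 0.75))

  # identical nonempty islands
  tri <- sdr_pair(pair_matrix(4, 4, 4), "i1", "i2")
  expect_equal(unname(tri[c("S", "D", "R")]), c(1, 0, 0))
})

test_that("S + D + R = 1, components non-negative, pairs symmetric", {
  set.seed(19)
  for (i in 1:200) {
    m <- random_incidence(sample(3:15, 1), sample(2:6, 1), runif(1, .1, .9))
    cols <- colnames(m)[colSums(m) > 0]
    if (length(cols) < 2) next
    ab <- sample(cols, 2)
    t1 <- sdr_pair(m, ab[1], ab[2])
    t2 <- sdr_pair(m, ab[2], ab[1])
    expect_equal(sum(t1), 1, tolerance = 1e-12)
    expect_true(all(t1 >= 0))
    expect_equal(as.numeric(t1), as.numeric(t2))
    # the replacement numerator doubles exactly: S_t * R is an even integer
    counts <- attr(t1, "counts")
    half <- t1[["R"]] * counts[["S_t"]] / 2
    expect_equal(half, round(half), tolerance = 1e-9)
  }
})

test_that("simplex table means equal brute-force per-pair means", {
  set.seed(23)
  m <- random_incidence(6, 4, 0.6)
  sx <- sdr_simplex(m)
  expect_equal(sx$summary$n_pairs, choose(4, 2))
  manual <- t(apply(sx$pairs[, c("island_a", "island_b")], 1, function(p) {
    sdr_pair(m, p[1], p[2])
  }))
  expect_equal(sx$summary$mean_S, 100 * mean(manual[, 1]))
  expect_equal(sx$summary$mean_D, 100 * mean(manual[, 2]))
  expect_equal(sx$summary$mean_R, 100 * mean(manual[, 3]))
  expect_equal(sx$summary$mean_S + sx$summary$mean_D + sx$summary$mean_R, 100,
               tolerance = 1e-9)
  expect_equal(sx$summary$matrix_fill, 100 * mean(m))
})

test_that("two identical islands summarize to (100, 0, 0)", {
  m <- pair_matrix(5, 5, 5)
  sx <- sdr_simplex(m)
  expect_equal(c(sx$summary$mean_S, sx$summary$mean_D, sx$summary$mean_R),
               c(100, 0, 0))
})

test_that("empty pairs are undefined and excluded with a warning", {
  m <- matrix(c(1, 1, 0, 0, 0, 0), 2, 3,
              dimnames = list(c("a", "b"), c("i1", "i2", "i3")))
  expect_error(sdr_pair(m, "i2", "i3"), "undefined")
  expect_warning(sx <- sdr_simplex(m), "zero pooled richness")
  expect_equal(sx$summary$n_pairs, 2)   # (i1,i2) and (i1,i3) survive
})

test_that("cross-temporal decomposition follows the same formulas", {
  m1 <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "i1"))
  m2 <- matrix(1L, 2, 1, dimnames = list(c("a", "d"), "i1"))
  tri <- sdr_cross_temporal(m1, m2, "i1")
  expect_equal(unname(tri[c("S", "D", "R")]), c(0.25, 0.25, 0.5))

  same <- sdr_cross_temporal(m1, m1, "i1")
  expect_equal(unname(same[c("S", "D", "R")]), c(1, 0, 0))

  empty1 <- m1; empty1[] <- 0L
  empty2 <- m2; empty2[] <- 0L
  expect_error(sdr_cross_temporal(empty1, empty2, "i1"), "undefined")
})

test_that("turnover counts are consistent with the cross-temporal Jaccard", {
  m1 <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), "i1"))
  m2 <- matrix(1L, 2, 1, dimnames = list(c("b", "c"), "i1"))
  tc <- turnover_counts(m1, m2, "i1")
  expect_equal(unname(tc), c(1L, 1L, 1L))
  expect_equal(unname(turnover_counts(m1, m1, "i1")), c(2L, 0L, 0L))

  set.seed(29)
  arch <- generate_archipelago(small_config(seed = 29))
  p <- c("1830-1950", "1951-2015")
  m1 <- build_incidence(arch$occurrences, arch$islands, p[1])
  m2 <- build_incidence(arch$occurrences, arch$islands, p[2])
  for (isl in sample(arch$islands$island, 5)) {
    tc <- turnover_counts(m1, m2, isl)
    tri <- sdr_cross_temporal(m1, m2, isl)
    expect_equal(tri[["S"]], tc[["stable"]] / sum(tc))
  }
  # archipelago-level counts use the union over islands
  tc_all <- turnover_counts(m1, m2)
  cmp <- compare_periods(arch$occurrences, periods = p)
  expect_equal(unname(tc_all), c(cmp$shared, cmp$gained, cmp$lost))
})
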