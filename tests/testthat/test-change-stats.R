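test_that("the G-test reproduces the origin-composition shift from raw counts", {
  gt <- g_test(matrix(c(1523, 78, 1360, 181), 2, 2, byrow = TRUE))
  expect_equal(gt$G, 50.191, tolerance = 0.001)
  expect_equal(gt$df, 1L)
  expect_lt(gt$p, 1e-4)
})

test_that("G = 0 under perfect independence; zero cells contribute zero", {
  expect_equal(g_test(matrix(10, 2, 2))$G, 0)
  gt <- g_test(matrix(c(5, 0, 3, 7), 2, 2))
  expect_true(is.finite(gt$G) && gt$G > 0)
  expect_error(g_test(matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE)), "marginal")
})

test_that("G matches the direct log-likelihood-ratio formula and is permutation invariant", {
  set.seed(131)
  for (i in 1:20) {
    O <- matrix(rpois(6, 40) + 1, 2, 3)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    G_direct <- 2 * sum(O * log(O / E))
    gt <- g_test(O)
    expect_equal(gt$G, G_direct, tolerance = 1e-12)
    expect_equal(gt$df, 2L)
    expect_equal(g_test(O[2:1, c(2, 3, 1)])$G, gt$G)
  }
})

test_that("period comparison pools species over islands and decomposes by origin", {
  occ <- make_occ(list("a", "i1", "P1"), list("a", "i2", "P1"),
                  list("b", "i1", "P1"), list("x", "i1", "P1"),
                  list("a", "i1", "P2"), list("c", "i2", "P2"),
                  list("x", "i1", "P2"), list("y", "i2", "P2"))
  traits <- data.frame(species = c("a", "b", "c", "x", "y"),
                       origin = c("native", "native", "native", "alien", "alien"),
                       functional_type = "AH")
  total <- compare_periods(occ, periods = c("P1", "P2"))
  expect_equal(total$richness_p1, 3)
  expect_equal(total$richness_p2, 4)
  expect_equal(total$shared, 2)
  expect_equal(total$jaccard, 2 / 5)
  expect_equal(total$gained + total$shared, total$richness_p2)
  expect_equal(total$lost + total$shared, total$richness_p1)

  nat <- compare_periods(occ, traits, origin = "native", periods = c("P1", "P2"))
  ali <- compare_periods(occ, traits, origin = "alien", periods = c("P1", "P2"))
  expect_equal(total$gained, nat$gained + ali$gained)
  expect_equal(total$lost, nat$lost + ali$lost)

  same <- compare_periods(make_occ(list("a", "i1", "P1"), list("a", "i1", "P2")),
                          periods = c("P1", "P2"))
  expect_equal(same$jaccard, 1)
  expect_equal(same$pct_change, 0)
})

test_that("inter-period OLS recovers exact and noisy linear relations", {
  x <- c(3, 8, 20, 50, 120)
  fit <- suppressWarnings(interperiod_regression(x, x))  # exact fit warns in summary.lm
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_true(all(abs(fit$relative_residuals) < 1e-10))

  set.seed(137)
  y <- 5 + 0.8 * x + rnorm(5, sd = 2)
  fit <- interperiod_regression(x, y)
  expect_equal(fit$slope, cov(x, y) / var(x))          # closed form
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-10)

  expect_error(interperiod_regression(c(5, 5, 5), c(1, 2, 3)), "variance")
})

test_that("OLS standard errors have near-nominal coverage", {
  set.seed(139)
  hits <- replicate(200, {
    x <- runif(16, 10, 400)
    y <- 10 + 0.8 * x + rnorm(16, sd = 15)
    fit <- lm(y ~ x)
    se <- coef(summary(fit))[, 2]
    ours <- interperiod_regression(x, y)
    abs(ours$intercept - 10) <= 2 * se[1] & abs(ours$slope - 0.8) <= 2 * se[2]
  })
  expect_gte(mean(hits), 0.90)
})

test_that("relative change joins areas and flags empty baselines", {
  occ <- make_occ(list("a", "i1", "P1"), list("b", "i1", "P1"),
                  list("a", "i1", "P2"), list("b", "i1", "P2"),
                  list("a", "i2", "P1"),
                  list("a", "i2", "P2"), list("b", "i2", "P2"),
                  list("c", "i2", "P2"), list("d", "i2", "P2"),
                  list("e", "i2", "P2"),
                  list("z", "i3", "P2"))
  islands <- data.frame(island = c("i1", "i2", "i3"), area_km2 = c(1, 5, 0.1))
  rc <- relative_change_by_area(occ, islands, periods = c("P1", "P2"))
  expect_equal(rc$rel_change_pct[rc$island == "i1"], 0)
  expect_equal(rc$rel_change_pct[rc$island == "i2"], 400)  # 1 -> 5 species
  expect_true(rc$undefined[rc$island == "i3"])
  expect_true(is.na(rc$rel_change_pct[rc$island == "i3"]))
})

test_that("small islands show more variable relative change than large ones", {
  # occurrence-level turnover: each occurrence is an independent coin, so
  # islands with few occurrences fluctuate more in relative terms
  sds <- sapply(1:5, function(s) {
    arch <- generate_archipelago(small_config(seed = 500 + s))
    rc <- relative_change_by_area(arch$occurrences, arch$islands, arch$traits,
                                  origin = "native")
    ok <- !rc$undefined
    half <- median(rc$area_km2)
    c(small = sd(rc$rel_change_pct[ok & rc$area_km2 < half]),
      large = sd(rc$rel_change_pct[ok & rc$area_km2 >= half]))
  })
  expect_gt(mean(sds["small", ] > sds["large", ]), 0.5)
})

test_that("composition shares normalize to 100% at both levels", {
  arch <- generate_archipelago(small_config(seed = 43))
  sh <- composition_shares(arch$occurrences, arch$traits, "1830-1950",
                           by = "functional_type")
  expect_equal(sum(sh$archipelago$share_pct), 100)
  expect_true(all(abs(rowSums(sh$by_island) - 100) < 1e-9))
  expect_equal(sum(attr(sh$by_island, "mean_share_pct")), 100, tolerance = 1e-9)

  mono <- make_occ(list("a", "i1", "P1"), list("b", "i1", "P1"))
  tr <- data.frame(species = c("a", "b"), origin = "native",
                   functional_type = c("AH", "AH"))
  sh1 <- composition_shares(mono, tr, "P1", by = "origin")
  expect_equal(sh1$archipelago$share_pct[sh1$archipelago$class == "native"], 100)
})
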