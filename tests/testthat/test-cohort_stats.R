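test_that("Mann-Whitney exact branch matches exhaustive enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")

  or <- oracle_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, or$U)
  expect_equal(mw$p_value, or$p)

  a <- c(1, 3, 5, 7)
  b <- c(2, 4, 6, 8)
  mw2 <- mann_whitney(a, b)
  or2 <- oracle_mann_whitney(a, b)
  expect_equal(mw2$U, or2$U)
  expect_equal(mw2$p_value, or2$p)

  set.seed(3)
  for (i in 1:10) {
    a <- sample(100, 4)
    b <- setdiff(sample(100, 8), a)[1:4]
    expect_equal(mann_whitney(a, b)$p_value, oracle_mann_whitney(a, b)$p,
                 tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and degenerate data is handled", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "perfvec_insufficient_data")
})

test_that("exact and approximate Mann-Whitney branches agree closely without ties", {
  # Exhaustive over all tie-free 6 + 6 configurations (U determines p): the
  # continuity-corrected normal approximation stays within 0.016 of the exact
  # two-sided p, the worst case sitting at mid-range U.
  set.seed(19)
  worst <- 0
  for (i in 1:50) {
    a <- sample(1000, 6)
    b <- setdiff(sample(1000, 12), a)[1:6]
    p_exact <- mann_whitney(a, b)$p_value
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    worst <- max(worst, abs(p_exact - ht$p.value))
  }
  expect_lte(worst, 0.02)
})

test_that("Kruskal-Wallis matches the hand-evaluated rank formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # ranks 1..9, group mean ranks 2, 5, 8:
  # H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(rep(1, 4), rep(1, 5)))$H, 0)
  expect_equal(kruskal_wallis(list(rep(1, 4), rep(1, 5)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "perfvec_insufficient_data")
})

test_that("two-group Kruskal-Wallis agrees with Mann-Whitney on significance", {
  set.seed(23)
  agree <- vapply(1:100, function(i) {
    a <- rnorm(8, mean = sample(c(0, 1.5), 1))
    b <- rnorm(9)
    (kruskal_wallis(list(a, b))$p_value < 0.05) ==
      (mann_whitney(a, b)$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.97)
})

test_that("Spearman correlation matches hand rank computation", {
  expect_equal(spearman_correlation(1:10, 2 * (1:10) + 3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1)
  sp <- spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(sp$rho, 0.8)          # 1 - 6*2/(4*15)
  expect_equal(sp$method, "exact")
  expect_error(spearman_correlation(1:3, 1:4),
               class = "perfvec_insufficient_data")
  expect_error(spearman_correlation(1:2, 1:2),
               class = "perfvec_insufficient_data")
})

make_cohort <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, stress_mag = groups[[g]])
  }))
}

test_that("compare_groups applies the Bonferroni thresholds of the design", {
  set.seed(31)
  co4 <- make_cohort(list(normal = rnorm(20),
                          apical = rnorm(10, 5), inferior = rnorm(10, 5),
                          anterior = rnorm(10, 5), lateral = rnorm(10, 5)))
  rep4 <- compare_groups(co4, "stress_mag")
  expect_equal(rep4$bonferroni_threshold, 0.0125)
  expect_equal(rep4$n_comparisons, 4L)
  expect_true(all(rep4$pairwise$significant))

  co2 <- make_cohort(list(normal = rnorm(20), ischemia = rnorm(10, 5),
                          infarction = rnorm(10)))
  rep2 <- compare_groups(co2, "stress_mag")
  expect_equal(rep2$bonferroni_threshold, 0.025)
  expect_equal(rep2$n_comparisons, 2L)
})

test_that("a non-significant omnibus gates off the pairwise tests", {
  set.seed(77)
  repeat {
    co <- make_cohort(list(normal = rnorm(10), apical = rnorm(10),
                           lateral = rnorm(10)))
    rep0 <- compare_groups(co, "stress_mag")
    if (!rep0$omnibus_significant) break
  }
  expect_equal(nrow(rep0$pairwise), 0L)
})

test_that("compare_groups is invariant to row order and validates its inputs", {
  set.seed(41)
  co <- make_cohort(list(normal = rnorm(12), apical = rnorm(12, 2),
                         lateral = rnorm(12, 2)))
  r1 <- compare_groups(co, "stress_mag")
  r2 <- compare_groups(co[sample(nrow(co)), ], "stress_mag")
  expect_equal(r1$kruskal$H, r2$kruskal$H)
  expect_equal(r1$pairwise, r2$pairwise)

  expect_error(compare_groups(co, "nope"), class = "perfvec_schema_error")
  expect_error(compare_groups(co, "stress_mag", reference = "none"),
               class = "perfvec_schema_error")
})

test_that("null simulation keeps the pairwise type-I error controlled", {
  set.seed(53)
  n_rep <- 1000L
  hits <- 0L
  total <- 0L
  for (i in seq_len(n_rep)) {
    co <- make_cohort(list(normal = rnorm(10), g1 = rnorm(10), g2 = rnorm(10),
                           g3 = rnorm(10), g4 = rnorm(10)))
    rep0 <- compare_groups(co, "stress_mag")
    total <- total + rep0$n_comparisons
    if (nrow(rep0$pairwise)) hits <- hits + sum(rep0$pairwise$significant)
  }
  expect_lte(hits / total, 0.06)
})
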