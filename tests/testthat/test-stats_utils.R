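test_that("2x2 Fisher matches stats::fisher.test and the enumeration oracle", {
  tab <- matrix(c(15, 3, 45, 39), 2)   # validation-cohort response table
  got <- fisher_exact_2x2(tab)
  expect_lt(got$p_greater, 0.05)       # one-sided enrichment of responses
  ref <- stats::fisher.test(tab)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  expect_equal(got$p_greater,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(got$p_less,
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_two_sided, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)),
               class = "icb_validation_error")
})

test_that("2x2 Fisher agrees with full enumeration for all small tables", {
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, c, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, oracle_fisher2x2(tab),
                 tolerance = 1e-10)
  }
})

test_that("Freeman-Halton: 2x2 reduction, enumeration oracle, Monte-Carlo", {
  tab22 <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(freeman_halton(tab22)$p, fisher_exact_2x2(tab22)$p_two_sided)
  tab23 <- matrix(c(3, 1, 4, 6, 2, 5), 2, 3)
  got <- freeman_halton(tab23)
  expect_equal(got$method, "exact")
  expect_equal(got$p, oracle_freeman_halton(tab23), tolerance = 1e-8)
  # a second shape against the oracle
  tab33 <- matrix(c(2, 1, 0, 1, 3, 1, 0, 1, 3), 3, 3)
  expect_equal(freeman_halton(tab33)$p, oracle_freeman_halton(tab33),
               tolerance = 1e-8)
  # Monte-Carlo route vs exact within 3 standard errors at a n=100 table
  tabmc <- matrix(c(20, 10, 5, 15, 30, 20), 2, 3)
  set.seed(7)
  mc <- freeman_halton(tabmc, exact_max_n = 0, n_mc = 2e4)
  exact <- stats::fisher.test(tabmc)$p.value
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p - exact), 3 * mc$mc_se + 1e-4)
})

test_that("Woolf odds ratio with the printed validation-cohort numbers", {
  got <- odds_ratio_woolf(matrix(c(15, 3, 45, 39), 2), confidence = 0.90)
  expect_equal(round(got$or, 2), 4.33)
  # the printed interval [1.44, 13.02] exponentiates around the OR rounded
  # to 4.33; from full counts the upper bound lands at 13.03
  expect_equal(got$ci, c(1.44, 13.02), tolerance = 0.002)
  se <- sqrt(1 / 15 + 1 / 45 + 1 / 3 + 1 / 39)
  printed <- exp(log(4.33) + c(-1, 1) * qnorm(0.95) * se)
  expect_equal(round(printed, 2), c(1.44, 13.02))
  expect_equal(odds_ratio_woolf(matrix(c(6, 6, 11, 11), 2))$or, 1)
  # CI narrows as all cells scale up
  small <- odds_ratio_woolf(matrix(c(4, 2, 3, 6), 2))
  big <- odds_ratio_woolf(10 * matrix(c(4, 2, 3, 6), 2))
  expect_lt(diff(log(big$ci)), diff(log(small$ci)))
  expect_true(suppressMessages(
    odds_ratio_woolf(matrix(c(0, 3, 5, 7), 2)))$corrected)
})

test_that("rank tests dispatch and match enumeration on a tiny fixture", {
  a <- c(1.1, 2.3, 3.1)
  b <- c(0.5, 1.8, 2.9, 4.0)
  got <- rank_tests(c(a, b), rep(c("A", "B"), c(3, 4)), exact = TRUE)
  expect_equal(got$method, "wilcoxon_rank_sum")
  # rank-sum of A in the pooled sample: ranks 2,4,6 -> W = 12 - 3*4/2 = 6
  expect_equal(got$statistic, 6)
  # exact p by enumeration over all 35 assignments
  pooled <- c(a, b)
  stats_all <- apply(utils::combn(7, 3), 2, function(ix) sum(rank(pooled)[ix]))
  obs <- sum(rank(pooled)[1:3])
  p_enum <- mean(abs(stats_all - mean(stats_all)) >= abs(obs - mean(stats_all)))
  expect_equal(got$p, p_enum, tolerance = 1e-10)
  # identical groups -> p near 1
  same <- rep(1:6, 2)
  expect_gt(rank_tests(same, rep(c("A", "B"), each = 6))$p, 0.9)
  # >2 groups dispatches to Kruskal-Wallis and matches stats::
  set.seed(2)
  v <- rnorm(30); g <- rep(1:3, 10)
  expect_equal(rank_tests(v, g)$p, stats::kruskal.test(v, g)$p.value)
})

test_that("Kruskal-Wallis rejects a 3-group shift alternative at n=600", {
  set.seed(11)
  hits <- 0
  for (r in 1:40) {
    g <- rep(1:3, each = 200)
    v <- rnorm(600) + c(0, 0.25, 0.5)[g]
    hits <- hits + (rank_tests(v, g)$p < 0.05)
  }
  expect_gte(hits, 38)
})
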