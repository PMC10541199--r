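test_that("Kaplan-Meier: hand examples and the no-event flat curve", {
  fit <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0))
  flat <- kaplan_meier(c(4, 6, 9), c(0, 0, 0))
  expect_equal(nrow(flat), 0)
  expect_equal(km_survival_at(flat, c(1, 100)), c(1, 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), class = "icb_validation_error")
})

test_that("Kaplan-Meier matches survfit (estimate and log-log CI) to 1e-10", {
  d <- make_surv_fixture(50, seed = 202, ties = TRUE)
  fit <- kaplan_meier(d$time, d$event)
  ref <- survival::survfit(survival::Surv(d$time, d$event) ~ 1,
                           conf.type = "log-log")
  at_events <- ref$n.event > 0
  expect_equal(fit$time, ref$time[at_events], tolerance = 1e-12)
  expect_equal(fit$surv, ref$surv[at_events], tolerance = 1e-10)
  expect_equal(fit$lower, ref$lower[at_events], tolerance = 1e-10)
  expect_equal(fit$upper, ref$upper[at_events], tolerance = 1e-10)
})

test_that("KM equals the empirical survival function without censoring", {
  for (s in 1:5) {
    set.seed(s)
    t <- sample(rexp(40))
    fit <- kaplan_meier(t, rep(1, 40))
    emp <- vapply(fit$time, function(u) mean(t > u), 0)
    expect_equal(fit$surv, emp, tolerance = 1e-12)
  }
})

test_that("log-rank matches survdiff for 2 and 3 groups", {
  for (k in 2:3) {
    d <- make_surv_fixture(60, seed = 300 + k, ties = TRUE)
    g <- rep_len(seq_len(k), 60)
    got <- logrank_test(d$time, d$event, g)
    ref <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
    expect_equal(got$statistic, ref$chisq, tolerance = 1e-8)
    expect_equal(got$df, k - 1L)
    expect_equal(got$p, stats::pchisq(ref$chisq, k - 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("log-rank on identical groups is null", {
  d <- make_surv_fixture(20, seed = 5)
  dup <- rbind(d, d)
  got <- logrank_test(dup$time, dup$event, rep(c("a", "b"), each = 20))
  expect_lt(got$statistic, 1e-10)
  expect_equal(got$p, 1, tolerance = 1e-8)
})

test_that("Cox: parameter recovery, CI coverage and degenerate input", {
  d <- make_surv_fixture(2000, seed = 77, beta = log(2))
  fit <- cox_univariable(d$time, d$event, d$x)
  expect_true(fit$converged)
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
  # null coverage: CI covers 1 in about 95% of replicates
  hits <- 0
  for (r in 1:150) {
    d0 <- make_surv_fixture(300, seed = 1000 + r, beta = 0)
    f0 <- cox_univariable(d0$time, d0$event, d0$x)
    hits <- hits + (f0$ci[1] <= 1 && 1 <= f0$ci[2])
  }
  expect_gt(hits / 150, 0.90)
  expect_lt(hits / 150, 0.99)
  # 2-sample separation is flagged, not silent
  expect_warning(
    bad <- cox_univariable(c(1, 5), c(1, 1), c(1, 0)),
    "convergence")
  expect_false(bad$converged)
})

test_that("Cox matches a numeric partial-likelihood oracle on tie-free data", {
  d <- make_surv_fixture(40, seed = 9, beta = 0.7)  # continuous times
  fit <- cox_univariable(d$time, d$event, d$x)
  expect_equal(fit$hr, oracle_cox_hr(d$time, d$event, d$x), tolerance = 1e-4)
})

test_that("concordance index: exact cases, brute-force oracle, invariance", {
  t <- c(5, 3, 9, 1, 7)
  expect_equal(concordance_index(t, rep(1, 5), -t), 1)
  d <- make_surv_fixture(30, seed = 41, beta = 0.5)
  risk <- d$x + rnorm(30, sd = 0.3)
  got <- concordance_index(d$time, d$event, risk)
  expect_equal(got, oracle_cindex(d$time, d$event, risk), tolerance = 1e-12)
  expect_equal(concordance_index(d$time, d$event, exp(3 * risk)), got)
  set.seed(4)
  big <- make_surv_fixture(2000, seed = 4)
  expect_lt(abs(concordance_index(big$time, big$event, rnorm(2000)) - 0.5), 0.04)
})

test_that("time-dependent ROC: exact limits and the frozen reference value", {
  # perfect separation, no censoring
  t <- c(1, 2, 3, 10, 11, 12)
  expect_equal(time_dependent_roc(t, rep(1, 6), -t, horizon = 5)$auc, 1)
  # no censoring before the horizon reduces to the binary ROC
  d <- make_surv_fixture(80, seed = 15, beta = 0.6)
  d$event[d$time <= 4] <- 1  # force completeness before the horizon
  sc <- -d$x
  got <- time_dependent_roc(d$time, d$event, sc, horizon = 4)
  expect_equal(got$auc, binary_auc(d$time <= 4, sc), tolerance = 1e-12)
  # frozen oracle: scikit-survival cumulative_dynamic_auc on this exact
  # fixture gives 0.8220118710965132 (t=6) and 0.8683635310340035 (t=12)
  set.seed(424242)
  n <- 120
  score <- rnorm(n)
  lat <- rexp(n, rate = exp(0.8 * score) / 10)
  cens <- runif(n, 0, 25)
  time <- pmin(lat, cens); event <- as.integer(lat <= cens)
  expect_equal(time_dependent_roc(time, event, score, 6)$auc,
               0.8220118710965132, tolerance = 1e-6)
  expect_equal(time_dependent_roc(time, event, score, 12)$auc,
               0.8683635310340035, tolerance = 1e-6)
  expect_error(time_dependent_roc(c(1, 2), c(1, 1), c(1, 2), horizon = 5),
               class = "icb_domain_error")
})
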