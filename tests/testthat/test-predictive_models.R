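test_that("balanced_split: single candidate, zero-score case, invariants", {
  co <- generate_cohort(cohort_spec(n_patients = 60, seed = 2))
  one <- suppressWarnings(balanced_split(co, n_candidates = 1, seed = 9))
  expect_length(one$train_ids, 42)
  expect_setequal(c(one$train_ids, one$test_ids), seq_len(60))
  expect_equal(one$n_candidates_tried, 1)
  expect_true(is.finite(one$imbalance_score))
  # identical rows: categorical frequencies match on any split -> score 0
  flat <- data.frame(a = rep("x", 40), b = rep(c("u", "v"), 20))
  flat_split <- balanced_split(flat, balance_vars = "a", n_candidates = 3, seed = 1)
  expect_equal(flat_split$imbalance_score, 0)
  # zero-IQR continuous variable excluded with a warning
  co$zero_iqr <- c(rep(0, 58), 5, 9)
  expect_warning(
    balanced_split(co, balance_vars = c("tmb", "zero_iqr"), n_candidates = 2, seed = 1),
    "zero-IQR")
})

test_that("balanced_split score improves (in expectation) with candidates", {
  co <- generate_cohort(cohort_spec(n_patients = 100, seed = 13))
  s1 <- s2 <- numeric(10)
  for (r in 1:10) {
    s1[r] <- suppressWarnings(balanced_split(co, n_candidates = 1, seed = r))$imbalance_score
    s2[r] <- suppressWarnings(balanced_split(co, n_candidates = 50, seed = r))$imbalance_score
  }
  expect_true(all(s2 <= s1 + 1e-12))
  expect_lt(mean(s2), mean(s1))
})

test_that("screen_candidates drops missing-value features and appends clinical", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 19))
  co$with_na <- co$tmb
  co$with_na[7] <- NA
  expect_message(
    got <- screen_candidates(co, c("siri", "with_na"), "pfs",
                             clinical_features = "age"),
    "missing values")
  expect_false("with_na" %in% got)
  expect_true("age" %in% got)
  got2 <- suppressMessages(screen_candidates(co, c("siri", "sbs4"), "pfs"))
  expect_true(all(got2 %in% c("siri", "sbs4")))
})

test_that("train_forest is deterministic, refuses too few events, prunes", {
  co <- generate_cohort(cohort_spec(n_patients = 90, seed = 29))
  feats <- c("siri", "tmb", "sbs4", "tp53_mut", "age")
  m1 <- train_forest(co, feats, "pfs", n_trees = 30, n_repeats = 2, seed = 11)
  m2 <- train_forest(co, feats, "pfs", n_trees = 30, n_repeats = 2, seed = 11)
  expect_identical(m1$importance_table, m2$importance_table)
  expect_identical(predict(m1, co), predict(m2, co))
  few <- co[1:12, ]
  few$pfs_event <- c(rep(TRUE, 3), rep(FALSE, 9))
  expect_error(train_forest(few, feats, "pfs", n_repeats = 1),
               class = "icb_domain_error")
  # pruning keeps strictly positive features and renames the model
  pm <- prune_to_positive_importance(m1)
  pos <- m1$importance_table$feature[m1$importance_table$mean_importance > 0]
  expect_setequal(pm$features, pos)
  expect_equal(pm$name, paste0("RF", length(pos)))
  # all-nonpositive importance is refused
  m_bad <- m1
  m_bad$importance_table$mean_importance <- -abs(m_bad$importance_table$mean_importance)
  expect_error(prune_to_positive_importance(m_bad), class = "icb_domain_error")
  expect_error(train_forest(co, c("siri", "best_response"), "pfs", n_repeats = 1),
               class = "icb_validation_error")
})

test_that("survival-group assignment: tie rule and monotone invariance", {
  expect_equal(as.character(assign_survival_groups(c(1, 2))),
               c("low_survival", "high_survival"))
  expect_warning(all_hi <- assign_survival_groups(rep(3, 5)), "identical")
  expect_true(all(all_hi == "high_survival"))
  for (s in 1:5) {
    set.seed(s)
    sc <- rnorm(21)
    expect_identical(assign_survival_groups(sc),
                     assign_survival_groups(exp(sc)))
  }
})

test_that("imputation: identity, median fallback, mask-and-recover", {
  co <- generate_cohort(cohort_spec(n_patients = 120, seed = 37))
  co$proxy <- co$siri + rnorm(120, sd = 0.1 * sd(co$siri))
  feats <- c("siri", "tmb", "proxy", "sbs4")
  m <- train_forest(co, feats, "pfs", n_trees = 50, n_repeats = 2, seed = 3)
  same <- impute_missing_features(co, m)
  expect_equal(same$proxy, co$proxy)
  expect_false(any(attr(same, "imputed")))
  # fully missing feature falls back to the training median
  blank <- co
  blank$proxy <- NA_real_
  filled <- impute_missing_features(blank, m)
  expect_true(all(filled$proxy == median(co$proxy)))
  # masked cells recover better than the marginal spread
  masked <- co
  set.seed(8)
  holes <- sample(120, 30)
  masked$proxy[holes] <- NA
  rec <- impute_missing_features(masked, m)
  rmse <- sqrt(mean((rec$proxy[holes] - co$proxy[holes])^2))
  expect_lt(rmse, sd(co$proxy))
  expect_true(all(attr(rec, "imputed")[holes, "proxy"]))
})

test_that("evaluate_survival_model returns coherent discrimination metrics", {
  co <- generate_cohort(cohort_spec(n_patients = 150, seed = 53))
  scores <- -co$siri  # higher SIRI = worse survival in the generator
  ev <- evaluate_survival_model(scores, co, "pfs", horizons = c(pfs = 6, os = 12))
  expect_gt(ev$c_index, 0.5)
  expect_true(all(ev$td_auc > 0.4, na.rm = TRUE))
  expect_gte(ev$response_auc, 0); expect_lte(ev$response_auc, 1)
})
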