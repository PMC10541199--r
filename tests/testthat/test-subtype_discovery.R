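test_that("screening: empty input, planted signal retained, noise excluded", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 17))
  empty <- screen_features(co, character(0))
  expect_equal(nrow(empty), 0)
  expect_length(attr(empty, "retained"), 0)
  # a strongly prognostic feature is retained
  scr <- screen_features(co, c("siri", "sbs4"))
  expect_true(all(c("siri", "sbs4") %in% attr(scr, "retained")))
  # pure noise columns are usually dropped (calibration tested in acceptance)
  set.seed(1)
  co$noise1 <- rnorm(300); co$noise2 <- rnorm(300)
  scr2 <- screen_features(co, c("noise1", "noise2"))
  expect_true(all(scr2$p_combined > 0.001, na.rm = TRUE))
})

test_that("dichotomization: binary feature, degenerate input, tie-breaking", {
  co <- generate_cohort(cohort_spec(n_patients = 120, seed = 21))
  co$bin <- as.numeric(co$virus_positive)
  d <- dichotomize_by_pfs(co, "bin", lower_q = 0, upper_q = 1)
  expect_equal(d$threshold, 0.5)   # unique midpoint of a 0/1 feature
  co$flat <- 1
  expect_error(dichotomize_by_pfs(co, "flat"), class = "icb_no_threshold_error")
  expect_error(dichotomize_by_pfs(co[1:10, ], "siri"), class = "icb_domain_error")
})

test_that("dichotomization partition is invariant to monotone transforms", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 33))
  d1 <- dichotomize_by_pfs(co, "siri")
  co$siri_t <- log(co$siri)
  d2 <- dichotomize_by_pfs(co, "siri_t")
  expect_identical(dichotomize_apply(d1, co$siri),
                   dichotomize_apply(d2, co$siri_t))
  expect_equal(d1$logrank_stat, d2$logrank_stat, tolerance = 1e-9)
  expect_equal(d2$threshold, log(d1$threshold), tolerance = 0.2)
})

test_that("clustering: singletons, duplicates, row-order determinism, k guard", {
  ortho <- diag(6)
  colnames(ortho) <- c("tp53_mut", "tmb_high", "del_9p24_1", "purity_high",
                       "smoking_sig", "virus_positive")
  sm <- cluster_subtypes(ortho)
  expect_equal(sort(tabulate(sm$assignments, 6)), rep(1L, 6))
  dup <- ortho[c(1, 1, 2, 2, 3, 3, 4, 5, 6), ]
  smd <- cluster_subtypes(dup)
  expect_equal(smd$assignments[1], smd$assignments[2])
  expect_equal(smd$assignments[3], smd$assignments[4])
  arc <- make_archetype_matrix(n_per = 25, noise = 0.04, seed = 2)
  base <- cluster_subtypes(arc$matrix)$assignments
  set.seed(10)
  perm <- sample(nrow(arc$matrix))
  permuted <- cluster_subtypes(arc$matrix[perm, ])$assignments
  expect_identical(permuted, base[perm])
  expect_error(cluster_subtypes(ortho[1:4, ]), class = "icb_domain_error")
  expect_error(cluster_subtypes(matrix(c(0, 2), 3, 4)), class = "icb_validation_error")
})

test_that("canonical numbering matches the archetype semantics", {
  arc <- make_archetype_matrix(n_per = 40, noise = 0.03, seed = 5)
  sm <- cluster_subtypes(arc$matrix)
  # majority mapping: each planted archetype should map to its own label
  map <- vapply(1:6, function(s) {
    as.integer(names(which.max(table(sm$assignments[arc$labels == s]))))
  }, 0L)
  expect_equal(map, 1:6)
  pr <- sm$cluster_profiles
  expect_gt(pr["subtype_2", "del_9p24_1"], 0.5)
  expect_gt(pr["subtype_4", "tmb_high"], 0.5)
  expect_gt(pr["subtype_6", "purity_high"], 0.5)
  expect_lt(max(pr[4:6, "tp53_mut"]), min(pr[1:3, "tp53_mut"]))
})

test_that("risk-group ORR ordering holds with planted parameters", {
  wins <- 0
  for (s in 1:5) {
    co <- generate_cohort(cohort_spec(n_patients = 300, seed = 400 + s))
    rg <- subtype_risk_group(co$subtype_true)
    wins <- wins + (mean(co$response[rg == "low_risk"]) >
                      mean(co$response[rg == "high_risk"]))
  }
  expect_gte(wins, 4)
})

test_that("radar profile: all-favorable, empty group, hand counts", {
  fav <- data.frame(cd8_per_roi = c(300, 400), cps = c(5, 10), tmb = c(5, 6),
                    virus_positive = TRUE, del_9p24_1 = FALSE,
                    sbs4 = 0.01, sbs2 = 0.2, sbs13 = 0.1)
  expect_equal(unname(radar_profile(fav, cd8_cutoff = 200)), rep(1, 7))
  expect_error(radar_profile(fav[0, ], cd8_cutoff = 200), class = "icb_domain_error")
  mixed <- data.frame(
    cd8_per_roi = c(300, 100, 250, 50),
    cps = c(0, 1, 5, 0.5),
    tmb = c(4, 2, 3.34, 1),
    virus_positive = c(TRUE, FALSE, TRUE, FALSE),
    del_9p24_1 = c(FALSE, TRUE, FALSE, FALSE),
    sbs4 = c(0.01, 0.3, 0.06, 0.02),
    sbs2 = c(0.3, 0.01, 0.2, 0.02),
    sbs13 = c(0.1, 0.01, 0.1, 0.02))
  got <- radar_profile(mixed, cd8_cutoff = 200)
  expect_equal(unname(got),
               c(2 / 4, 2 / 4, 2 / 4, 2 / 4, 3 / 4, 2 / 4, 2 / 4))
})

test_that("fit_subtypes assembles a coherent model", {
  co <- generate_cohort(cohort_spec(n_patients = 150, seed = 61))
  fs <- suppressWarnings(fit_subtypes(co))
  expect_s3_class(fs$model, "subtype_model")
  expect_equal(length(fs$model$assignments), 150)
  expect_true(all(fs$model$assignments %in% 1:6))
  expect_true(all(vapply(fs$thresholds, function(d)
    d$threshold > min(co[[d$name]]) && d$threshold < max(co[[d$name]]),
    logical(1))))
})
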