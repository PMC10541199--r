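test_that("filter_snvs applies all six criteria, preserves order, is idempotent", {
  mut <- make_mutation_fixture()
  kept <- filter_snvs(mut)
  expect_equal(kept$gene, c("G2", "G6", "G8"))
  expect_identical(filter_snvs(kept), kept)
  # boundary examples (vaf_normal = 0 so only the VAF criterion moves)
  one <- mut[2, ]
  one$vaf_normal <- 0
  one$vaf_tumor <- 0.04
  expect_equal(nrow(filter_snvs(one)), 0)
  one$vaf_tumor <- 0.05
  expect_equal(nrow(filter_snvs(one)), 1)
})

test_that("filter_snvs flags missing required fields by name", {
  mut <- make_mutation_fixture()
  mut$vaf_normal[3] <- NA
  mut$depth_tumor[5] <- NA
  err <- tryCatch(filter_snvs(mut), error = function(e) e)
  expect_s3_class(err, "icb_validation_error")
  expect_match(conditionMessage(err), "vaf_normal")
  expect_match(conditionMessage(err), "depth_tumor")
})

test_that("compute_tmb divides, errors on bad coverage, and is additive", {
  expect_equal(compute_tmb(0, 30), 0)
  expect_equal(compute_tmb(100, 30), 100 / 30)
  expect_equal(round(compute_tmb(1045, 20), 2), 52.25)
  expect_error(compute_tmb(10, 0), class = "icb_domain_error")
  for (ab in list(c(3, 9), c(120, 7), c(0, 55))) {
    expect_equal(compute_tmb(ab[1] + ab[2], 17.3),
                 compute_tmb(ab[1], 17.3) + compute_tmb(ab[2], 17.3))
  }
})

test_that("clonal load counts strictly above 0.5 and reports missingness", {
  expect_equal(as.integer(compute_clonal_load(rep(0.5, 5))), 0L)
  got <- suppressMessages(compute_clonal_load(c(0.9, 0.51, 0.2, NA)))
  expect_equal(as.integer(got), 2L)
  expect_equal(attr(got, "n_missing_ccf"), 1L)
  set.seed(31)
  u <- runif(200)
  expect_lt(abs(as.integer(compute_clonal_load(u)) - 100), 4 * sqrt(200 * 0.25))
})

test_that("SIRI formula, symmetry and domain errors", {
  expect_equal(compute_siri(4, 0.5, 1), 2)
  expect_equal(compute_siri(2, 0.3, 0.6), 1)
  expect_equal(compute_siri(2.3, 0.7, 1.1), compute_siri(0.7, 2.3, 1.1))
  expect_error(compute_siri(4, 0.5, 0), class = "icb_domain_error")
  expect_error(compute_siri(4, -1, 1), class = "icb_domain_error")
})

test_that("CPS ratio with capping", {
  expect_equal(compute_cps(0, 500), 0)
  expect_equal(compute_cps(50, 500), 10)
  expect_message(got <- compute_cps(600, 500), "capped")
  expect_equal(got, 100)
  expect_equal(compute_cps(600, 500, cap = Inf), 120)
})

test_that("arm events use a strict 20% rule and ploidy bands are honored", {
  expect_false(call_arm_event(0.20))
  expect_true(call_arm_event(0.21))
  expect_true(call_arm_event(7 / 30))
  expect_equal(classify_ploidy(2.0), "diploid")
  expect_equal(classify_ploidy(2.5), "diploid")
  expect_equal(classify_ploidy(2.51), "hyperploid")
  expect_warning(out <- classify_ploidy(c(1.2, 3)), "out-of-range")
  expect_identical(out, c(NA_character_, "hyperploid"))
})

test_that("HPV integration: stated examples and the zero-assay error", {
  expect_equal(integrate_hpv_status(p16_ihc = "pos"), "HPV_positive")
  expect_equal(integrate_hpv_status(p16_ihc = "pos", dna_ish = "neg"), "HPV_positive")
  expect_equal(integrate_hpv_status(p16_ihc = "pos", pcr = "neg"), "HPV_negative")
  expect_equal(integrate_hpv_status(dna_ish = "neg"), "HPV_negative")
  expect_error(integrate_hpv_status(), class = "icb_validation_error")
})

test_that("endpoints: response and clinical benefit", {
  got <- derive_endpoints(c("PR", "SD", "SD", "PD", "CR", "NE"),
                          c(NA, 7, 3, NA, NA, NA))
  expect_equal(got$response, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(got$clinical_benefit, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  # boundary: exactly 6 months counts ("lasting at least 6 months")
  expect_true(derive_endpoints("SD", 6)$clinical_benefit)
  expect_error(derive_endpoints("XX"), class = "icb_validation_error")
})

test_that("cohort TSV round-trip is bit-exact for doubles", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   x = c(pi, exp(1), 1 / 3),
                   t = c(0.1 + 0.2, 1e-17, 123456.789),
                   flag = c(TRUE, FALSE, NA),
                   lab = c("x", NA, "z"),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_cohort(df, path)
  back <- read_cohort(path)
  expect_identical(back$x, df$x)
  expect_identical(back$t, df$t)
  expect_identical(back$flag, df$flag)
  expect_identical(back$lab, df$lab)
})

test_that("build_cohort reproduces the generator's derived features", {
  tabs <- generate_cohort_tables(cohort_spec(n_patients = 25, seed = 5))
  built <- suppressWarnings(suppressMessages(
    build_cohort(tabs$clinical, tabs$mutations, tabs$cna, tabs$signatures)))
  expect_equal(built$tmb, tabs$cohort$tmb)
  expect_equal(built$clonal_load, tabs$cohort$clonal_load)
  expect_equal(built$tp53_mut, tabs$cohort$tp53_mut)
  expect_equal(built$del_9p24_1, tabs$cohort$del_9p24_1)
  expect_equal(built$siri, tabs$cohort$siri)
  expect_equal(built$response, tabs$cohort$response)
})

test_that("validation-sample accounting excludes QC, purity and TMB outliers", {
  samples <- data.frame(sample_id = sprintf("K%03d", 1:20),
                        qc_pass = c(FALSE, rep(TRUE, 19)),
                        purity = c(0.5, NA, NA, rep(0.5, 17)),
                        tmb = c(rep(3, 19), 300))
  got <- suppressMessages(filter_validation_samples(samples))
  expect_equal(got$n_kept, 16)
  expect_setequal(got$exclusions$reason,
                  c("failed_qc", "purity_undetermined", "tmb_outlier"))
})
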