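# Shared fixtures built in code at test time.

# small censored survival sample with reproducible draws
make_surv_fixture <- function(n, seed, beta = 0, ties = FALSE) {
  set.seed(seed)
  x <- rnorm(n)
  lat <- rexp(n, rate = exp(beta * x) / 8)
  if (ties) lat <- round(lat, 1)
  cens <- runif(n, 0, 20)
  data.frame(time = pmin(lat, cens), event = as.integer(lat <= cens), x = x)
}

# planted three-tier RPA cohort: high tier by SIRI, intermediate by low TMB
# or smoking signature, low otherwise; viral status orthogonal to hazard
make_tier_cohort <- function(n, seed, hr = c(1, 2.8, 9)) {
  set.seed(seed)
  siri <- runif(n, 0, 8)
  tmb <- rlnorm(n, log(3), 0.6)
  sbs4 <- runif(n)
  tier <- ifelse(siri > 4, 3, ifelse(tmb <= 2 | sbs4 > 0.6, 2, 1))
  lat <- 10 * (-log(runif(n)) / (log(2) * hr[tier]))
  cens <- runif(n, 0, 2.5 * stats::quantile(lat, 0.8))
  data.frame(siri = siri, tmb = tmb, sbs4 = sbs4,
             virus_positive = runif(n) < 0.5,
             pfs_time = pmin(lat, cens), pfs_event = lat <= cens, tier = tier)
}

# six binary feature archetypes over the canonical matrix columns; `noise`
# is label noise: that fraction of patients carries the feature pattern of
# a different (random) archetype than their nominal label
make_archetype_matrix <- function(n_per = 50, noise = 0.05, seed = 1) {
  arch <- rbind(
    c(1, 0, 0, 0, 1, 0, 1, 0, 0, 1, 0, 0),  # TP53-mut, low TMB, smoking
    c(1, 1, 1, 1, 1, 0, 1, 1, 0, 1, 0, 0),  # TP53-mut, TMB-high, 9p24.1 del
    c(1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 0),  # TP53-mut, TMB-high, APOBEC
    c(0, 1, 1, 1, 0, 1, 1, 0, 1, 0, 1, 1),  # WT, TMB-high, APOBEC, viral
    c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 1),  # WT, low TMB, mixed, viral
    c(0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 1, 1)   # WT, low TMB, high purity, viral
  )
  colnames(arch) <- c("tp53_mut", "tmb_high", "clonal_high", "indel_high",
                      "smoking_sig", "apobec_sig", "aging_sig", "del_9p24_1",
                      "hla_loh", "hyperploid", "purity_high", "virus_positive")
  set.seed(seed)
  lab <- rep(1:6, each = n_per)
  pattern_of <- lab
  scramble <- runif(length(lab)) < noise
  pattern_of[scramble] <- sample(1:6, sum(scramble), replace = TRUE)
  mat <- arch[pattern_of, ]
  rownames(mat) <- NULL
  list(matrix = mat, labels = lab)
}

# minimal mutation table that passes/fails the SNV filter as marked
make_mutation_fixture <- function() {
  data.frame(
    sample_id = "S1",
    gene = paste0("G", 1:10),
    variant_class = "missense",
    vaf_tumor   = c(0.04, 0.30, 0.20, 0.10, 0.25, 0.30, 0.05, 0.50, 0.12, 0.40),
    vaf_normal  = c(0.00, 0.05, 0.00, 0.00, 0.06, 0.00, 0.00, 0.00, 0.00, 0.30),
    depth_tumor = c(100L,  60L,  49L, 100L, 100L, 100L,  80L, 200L, 100L,  90L),
    depth_normal= c( 50L,  25L,  30L,  19L,  40L,  40L,  30L,  60L,  50L,  45L),
    alt_reads_tumor = c(8L, 18L, 10L, 10L, 25L, 30L, 4L, 100L, 12L, 36L),
    strand_both = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    ccf = c(0.9, 0.51, 0.2, NA, 0.6, 0.7, 0.3, 0.95, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
  # passing rows: 2, 6, 8 (three in total); the others each violate one
  # criterion: 1 VAF, 3 DP.tumor, 4 DP.normal, 5 VAF ratio (0.24), 7
  # AD.tumor, 9 strand, 10 VAF ratio (0.75)
}
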