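# Synthetic two-etiology immunotherapy cohorts with the statistical
# structure the downstream analyses assume: subtype-dependent hazards and
# response rates, TP53-viral-status anti-correlation, viral-status-specific
# TMB log-normals, signature Dirichlets and copy-number prevalences.
# Defaults are anchored to the printed summaries of a 133-patient cohort;
# see the methods vignette for the anchor of every number.

#' Specification for a synthetic ICB cohort
#'
#' Returns a validated parameter list consumed by [generate_cohort()].
#' Defaults encode the stated world: 52% virus-positive tumors, six
#' molecular subtypes with objective response rates from 7% to 48%,
#' progression-free-survival hazard multipliers of 4.42 and 3.76 for the
#' two worst subtypes relative to the best (median PFS 9.1 months), TP53
#' mutation prevalence 67% in virus-negative versus 10% in virus-positive
#' disease, and viral-status-specific TMB log-normal parameters fitted to
#' printed medians and interquartile ranges.
#'
#' @param n_patients cohort size (>= 20).
#' @param seed integer seed stored with the spec.
#' @param subtype_mixture 6 mixture weights (normalized to sum to 1).
#' @param virus_assoc_prob per-subtype probability of a virus-associated
#'   tumor.
#' @param response_prob per-subtype objective response probability.
#' @param pfs_hazard_mult,os_hazard_mult per-subtype hazard multipliers
#'   relative to subtype 4.
#' @param pfs_baseline_median,os_baseline_median subtype-4 median survival
#'   (months) under the exponential baseline.
#' @param weibull_shape shape of the baseline hazard family; 1 (default)
#'   gives the exponential baseline.
#' @param censoring_rate target fraction of censored PFS observations; the
#'   uniform administrative horizon is tuned to achieve it.
#' @param tp53_prob_subtype per-subtype TP53 mutation probability. The
#'   default (0.80 for the three mutant-block subtypes, 0.10 otherwise)
#'   reproduces, through the subtype-viral coupling, the printed marginal
#'   prevalences: about 67% in virus-negative and low in virus-positive
#'   tumors (the anti-correlation is emergent, not imposed).
#' @param tmb_meanlog,tmb_sdlog named (`v_negative`, `hpv`, `ebv`)
#'   log-normal parameters for the etiology-level TMB base.
#' @param tmb_subtype_mult per-subtype multiplicative shift of the TMB
#'   median (subtype 1 low, subtypes 2-4 high, 5-6 low, per the printed
#'   subtype profiles).
#' @param del9p_prob per-subtype probability of 9p24.1 deletion.
#' @param hyperploid_prob,hla_loh_prob per-subtype event probabilities,
#'   chosen so the viral-status marginals match the printed prevalences
#'   (hyperploidy about 59%/27%/23% and HLA-LOH about 27%/41%/8% in
#'   virus-negative/HPV/EBV tumors).
#' @param purity_shape named list of `c(alpha, beta)` Beta parameters per
#'   viral status; subtype 6 (defined by high purity) overrides with
#'   `purity_shape_subtype6`.
#' @param purity_shape_subtype6 Beta parameters for subtype 6.
#' @param sig_alpha list of 6 Dirichlet alphas over
#'   (SBS1, SBS2, SBS4, SBS13), one per subtype: smoking-dominated for the
#'   virus-negative subtypes 1-2 and 6, smoking+APOBEC for 3,
#'   APOBEC-dominated smoking-free for 4, mixed for 5.
#' @param lab_meanlog,lab_sdlog named (`neutrophils`, `monocytes`,
#'   `lymphocytes`) log-normal parameters (10^9 cells/L).
#' @param siri_log_hr log-hazard slope per unit log-SIRI applied to both
#'   endpoints (default 0.5). The systemic inflammatory response index is
#'   strongly prognostic in the reference analysis (top recursive-
#'   partitioning feature), so the generator gives it a direct
#'   proportional-hazards effect on top of the subtype hazards.
#' @param irae_prob_responder,irae_prob_nonresponder any-grade irAE rates.
#' @return Object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_patients = 133,
                        seed = 1L,
                        subtype_mixture = c(0.18, 0.10, 0.13, 0.16, 0.28, 0.15),
                        virus_assoc_prob = c(0.13, 0.07, 0.04, 1.00, 0.69, 0.91),
                        response_prob = c(0.13, 0.07, 0.32, 0.48, 0.20, 0.18),
                        pfs_hazard_mult = c(4.42, 3.76, 1.50, 1.00, 1.80, 2.80),
                        os_hazard_mult = c(3.50, 3.00, 1.40, 1.00, 1.60, 2.40),
                        pfs_baseline_median = 9.1,
                        os_baseline_median = 20,
                        weibull_shape = 1,
                        censoring_rate = 0.25,
                        tp53_prob_subtype = c(0.90, 0.90, 0.88, 0.05, 0.20, 0.06),
                        tmb_meanlog = c(v_negative = log(3.72), hpv = log(2.66), ebv = log(1.70)),
                        tmb_sdlog = c(v_negative = 0.810, hpv = 0.651, ebv = 0.920),
                        tmb_subtype_mult = c(0.45, 1.80, 1.90, 2.20, 0.65, 0.50),
                        del9p_prob = c(0.30, 0.86, 0.08, 0.04, 0.10, 0.08),
                        hyperploid_prob = c(0.65, 0.70, 0.55, 0.20, 0.40, 0.30),
                        hla_loh_prob = c(0.25, 0.22, 0.30, 0.45, 0.35, 0.28),
                        purity_shape = list(v_negative = c(4, 5), hpv = c(7, 3), ebv = c(5, 4)),
                        purity_shape_subtype6 = c(9, 2),
                        sig_alpha = list(c(2.0, 1.0, 7.0, 1.0),    # 1: smoking
                                         c(2.0, 1.5, 6.0, 1.5),    # 2: smoking
                                         c(2.0, 4.0, 3.0, 3.0),    # 3: smoking + APOBEC
                                         c(2.0, 5.0, 0.3, 4.0),    # 4: APOBEC, no smoking
                                         c(3.0, 2.0, 3.0, 1.5),    # 5: mixed
                                         c(2.0, 1.0, 6.0, 1.0)),   # 6: smoking, weak APOBEC
                        lab_meanlog = c(neutrophils = log(4.5), monocytes = log(0.6), lymphocytes = log(1.2)),
                        lab_sdlog = c(neutrophils = 0.35, monocytes = 0.40, lymphocytes = 0.40),
                        siri_log_hr = 0.5,
                        irae_prob_responder = 0.47,
                        irae_prob_nonresponder = 0.16) {
  spec <- as.list(environment())
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 20)
    .icb_stop("cohort_spec: n_patients must be at least 20", "icb_validation_error")
  for (f in c("subtype_mixture", "virus_assoc_prob", "response_prob",
              "pfs_hazard_mult", "os_hazard_mult", "del9p_prob",
              "tp53_prob_subtype", "tmb_subtype_mult", "sig_alpha",
              "hyperploid_prob", "hla_loh_prob"))
    if (length(spec[[f]]) != 6)
      .icb_stop(sprintf("cohort_spec: %s must have 6 entries", f), "icb_validation_error")
  if (any(spec$subtype_mixture < 0) || sum(spec$subtype_mixture) <= 0)
    .icb_stop("cohort_spec: degenerate subtype mixture", "icb_validation_error")
  probs <- c(spec$virus_assoc_prob, spec$response_prob, spec$censoring_rate,
             spec$tp53_prob_subtype, spec$del9p_prob,
             spec$hyperploid_prob, spec$hla_loh_prob,
             spec$irae_prob_responder, spec$irae_prob_nonresponder)
  if (any(probs < 0 | probs > 1))
    .icb_stop("cohort_spec: probabilities must lie in [0, 1]", "icb_validation_error")
  if (any(c(spec$pfs_hazard_mult, spec$os_hazard_mult) <= 0))
    .icb_stop("cohort_spec: hazard multipliers must be positive", "icb_validation_error")
  invisible(spec)
}

#' Generate a synthetic ICB cohort table
#'
#' Draws one cohort from a [cohort_spec()]: subtype from the mixture, viral
#' status conditional on subtype, genomic and laboratory features
#' conditional on viral status and subtype, and PFS/OS from per-subtype
#' proportional hazards (Weibull with the spec's shape; exponential by
#' default) under independent uniform administrative censoring whose
#' horizon is tuned to the spec's censoring rate. Reproducible given the
#' spec's seed. The true generative subtype is kept in `subtype_true`.
#'
#' @param spec a `cohort_spec`.
#' @return Data frame, one row per patient, with attribute `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  w <- spec$subtype_mixture / sum(spec$subtype_mixture)
  subtype <- sample.int(6, n, replace = TRUE, prob = w)
  virus_pos <- runif(n) < spec$virus_assoc_prob[subtype]
  # among virus-positive tumors, ~81% HPV / 19% EBV (56:13 split)
  etiology <- ifelse(!virus_pos, "v_negative",
                     ifelse(runif(n) < 56 / 69, "hpv", "ebv"))
  viral_status <- c(v_negative = "V_negative", hpv = "HPV_positive",
                    ebv = "EBV_positive")[etiology]
  tp53_mut <- runif(n) < spec$tp53_prob_subtype[subtype]

  tmb <- rlnorm(n, spec$tmb_meanlog[etiology] + log(spec$tmb_subtype_mult[subtype]),
                spec$tmb_sdlog[etiology])
  n_mut <- pmax(1L, rpois(n, tmb * 30))
  tmb <- n_mut / 30                     # keep TMB consistent with counts
  clonal_frac <- rbeta(n, 6, 4)
  clonal_load <- vapply(seq_len(n), function(i) rbinom(1, n_mut[i], clonal_frac[i]), 0L)
  indel_load <- rpois(n, pmax(0.5, 0.08 * n_mut))

  sig <- t(vapply(subtype, function(s) .rdirichlet1(spec$sig_alpha[[s]]), numeric(4)))
  colnames(sig) <- c("sbs1", "sbs2", "sbs4", "sbs13")

  del_9p24_1 <- runif(n) < spec$del9p_prob[subtype]
  hyperploid <- runif(n) < spec$hyperploid_prob[subtype]
  mean_cn <- ifelse(hyperploid, runif(n, 2.6, 4.2), runif(n, 1.6, 2.45))
  purity <- vapply(seq_len(n), function(i) {
    ab <- if (subtype[i] == 6) spec$purity_shape_subtype6
          else spec$purity_shape[[etiology[i]]]
    rbeta(1, ab[1], ab[2])
  }, 0)
  purity <- pmin(pmax(purity, 0.05), 0.99)
  hla_loh <- runif(n) < spec$hla_loh_prob[subtype]

  labs <- vapply(c("neutrophils", "monocytes", "lymphocytes"), function(l)
    rlnorm(n, spec$lab_meanlog[[l]], spec$lab_sdlog[[l]]), numeric(n))
  siri <- compute_siri(labs[, 1], labs[, 2], labs[, 3])

  # smoking history rank-correlated with the SBS4 signature fraction
  pack_years <- round(pmax(0, 60 * sig[, "sbs4"] + rnorm(n, 0, 6)), 1)
  cd8 <- rlnorm(n, log(ifelse(subtype %in% c(3, 4, 5), 260, 120)), 0.9)
  cd3 <- cd8 * rlnorm(n, log(3), 0.4)
  cps <- pmin(100, rlnorm(n, log(ifelse(del_9p24_1, 1.2, 5)), 1.2))

  response <- runif(n) < spec$response_prob[subtype]
  best_response <- ifelse(response,
                          ifelse(runif(n) < 0.2, "CR", "PR"),
                          ifelse(runif(n) < 0.25, "SD", "PD"))
  irae <- runif(n) < ifelse(response, spec$irae_prob_responder,
                            spec$irae_prob_nonresponder)

  # SIRI acts directly on the hazard (centered at its design median)
  siri_mult <- exp(spec$siri_log_hr *
                     (log(siri) - sum(spec$lab_meanlog * c(1, 1, -1))))
  pfs_lat <- .rweib_ph(n, spec$pfs_baseline_median, spec$weibull_shape,
                       spec$pfs_hazard_mult[subtype] * siri_mult)
  os_lat <- pmax(pfs_lat * runif(n, 1.0, 1.3),
                 .rweib_ph(n, spec$os_baseline_median, spec$weibull_shape,
                           spec$os_hazard_mult[subtype] * siri_mult))
  cens <- .tuned_uniform_censoring(pfs_lat, spec$censoring_rate)
  pfs_time <- pmin(pfs_lat, cens$time)
  pfs_event <- pfs_lat <= cens$time
  os_cens <- pmax(cens$time, runif(n, 0, 2) + cens$time)  # later admin cutoff for OS
  os_time <- pmin(os_lat, os_cens)
  os_event <- os_lat <= os_cens
  sd_dur <- ifelse(best_response == "SD", round(pfs_time, 2), NA_real_)

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    viral_status = viral_status,
    virus_positive = virus_pos,
    subtype_true = subtype,
    tp53_mut = tp53_mut,
    tmb = tmb,
    n_mutations = n_mut,
    clonal_load = clonal_load,
    indel_load = indel_load,
    sbs1 = sig[, "sbs1"], sbs2 = sig[, "sbs2"],
    sbs4 = sig[, "sbs4"], sbs13 = sig[, "sbs13"],
    del_9p24_1 = del_9p24_1,
    mean_copy_number = mean_cn,
    purity = purity,
    hla_loh = hla_loh,
    neutrophils = labs[, 1], monocytes = labs[, 2], lymphocytes = labs[, 3],
    siri = siri,
    cps = cps,
    cd3_per_roi = cd3,
    cd8_per_roi = cd8,
    age = round(pmin(92, pmax(28, rnorm(n, 62, 9)))),
    ecog = sample(0:2, n, replace = TRUE, prob = c(0.30, 0.55, 0.15)),
    stage = sample(c("III", "IVA", "IVB", "IVC"), n, replace = TRUE,
                   prob = c(0.10, 0.30, 0.25, 0.35)),
    smoking_pack_years = pack_years,
    antibiotics = runif(n) < 0.20,
    infection = runif(n) < 0.15,
    autoimmune = runif(n) < 0.08,
    best_response = best_response,
    sd_duration_months = sd_dur,
    response = response,
    irae_any_grade = irae,
    pfs_time = pfs_time, pfs_event = pfs_event,
    os_time = os_time, os_event = os_event,
    stringsAsFactors = FALSE
  )
  ep <- derive_endpoints(out$best_response, out$sd_duration_months)
  out$clinical_benefit <- ep$clinical_benefit
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

# Weibull proportional-hazards draw: S(t) = exp(-m * (log 2) (t/med)^shape)
.rweib_ph <- function(n, baseline_median, shape, mult) {
  u <- runif(n)
  baseline_median * (-log(u) / (log(2) * mult))^(1 / shape)
}

# Tune a Uniform(0, horizon) censoring horizon so the expected censored
# fraction matches `rate` for the realized latent times, then draw.
.tuned_uniform_censoring <- function(latent, rate) {
  if (rate <= 0) return(list(time = rep(Inf, length(latent)), horizon = Inf))
  p_cens <- function(h) mean(pmin(latent, h)) / h - rate
  hi <- max(latent) * 2
  horizon <- if (p_cens(hi) > 0) hi else uniroot(p_cens, c(1e-6, hi))$root
  list(time = runif(length(latent), 0, horizon), horizon = horizon)
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

#' Planted-threshold survival feature
#'
#' Generates a continuous feature (Uniform on `feature_range`) where
#' crossing `true_threshold` multiplies an exponential hazard by
#' `hazard_ratio`, under independent uniform censoring. The fixture for
#' threshold-recovery experiments.
#'
#' @param n sample size.
#' @param true_threshold planted cutpoint.
#' @param hazard_ratio hazard multiplier above the threshold (1 = null).
#' @param seed RNG seed.
#' @param baseline_median median survival below the threshold (months).
#' @param censoring_rate target censored fraction.
#' @param feature_range range of the uniform feature.
#' @return Data frame with `feature`, `time`, `event`.
#' @export
generate_planted_threshold_feature <- function(n, true_threshold, hazard_ratio,
                                               seed = 1L, baseline_median = 6,
                                               censoring_rate = 0.2,
                                               feature_range = c(0, 10)) {
  stopifnot(n >= 10, hazard_ratio > 0,
            true_threshold > feature_range[1], true_threshold < feature_range[2])
  set.seed(seed)
  feature <- runif(n, feature_range[1], feature_range[2])
  mult <- ifelse(feature > true_threshold, hazard_ratio, 1)
  latent <- .rweib_ph(n, baseline_median, 1, mult)
  cens <- .tuned_uniform_censoring(latent, censoring_rate)
  data.frame(feature = feature,
             time = pmin(latent, cens$time),
             event = latent <= cens$time)
}

#' Emit synthetic component tables in the cohort I/O dialect
#'
#' Decomposes a generated cohort into the four tables [build_cohort()]
#' consumes (clinical, mutation, copy-number, signature), with mutation
#' rows that all pass the SNV confidence filter and reproduce the cohort's
#' TMB, clonal load, indel load and TP53 status exactly.
#'
#' @param spec a `cohort_spec`.
#' @param exonic_coverage_mbp coverage used to size mutation lists.
#' @return List of data frames: `clinical`, `mutations`, `cna`,
#'   `signatures`, plus the merged `cohort`.
#' @export
generate_cohort_tables <- function(spec = cohort_spec(), exonic_coverage_mbp = 30) {
  cohort <- generate_cohort(spec)
  n <- nrow(cohort)
  set.seed(spec$seed + 104729L)  # independent stream for per-mutation noise
  mut_list <- lapply(seq_len(n), function(i) {
    k <- cohort$n_mutations[i]
    n_indel <- min(cohort$indel_load[i], k)
    n_clonal <- min(cohort$clonal_load[i], k)
    classes <- c(rep("frameshift_indel", n_indel),
                 sample(c("missense", "nonsense", "splice", "promoter"),
                        k - n_indel, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)))
    genes <- sprintf("GENE%03d", sample.int(400, k, replace = TRUE))
    if (cohort$tp53_mut[i]) genes[1] <- "TP53" else genes[genes == "TP53"] <- "GENE401"
    ccf <- numeric(k)
    idx_cl <- seq_len(n_clonal)
    ccf[idx_cl] <- runif(n_clonal, 0.51, 1)
    if (n_clonal < k) ccf[(n_clonal + 1):k] <- runif(k - n_clonal, 0.05, 0.5)
    depth_t <- 50L + rpois(k, 400)
    vaf_t <- pmax(0.05, round(ccf * cohort$purity[i] / 2, 3))
    data.frame(sample_id = cohort$patient_id[i],
               gene = genes, variant_class = classes,
               vaf_tumor = vaf_t, vaf_normal = 0,
               depth_tumor = depth_t, depth_normal = 20L + rpois(k, 180),
               alt_reads_tumor = pmax(5L, as.integer(round(vaf_t * depth_t))),
               strand_both = TRUE, ccf = ccf,
               stringsAsFactors = FALSE)
  })
  mutations <- do.call(rbind, mut_list)
  cna <- data.frame(sample_id = cohort$patient_id,
                    frac_9p_deleted = ifelse(cohort$del_9p24_1,
                                             runif(n, 0.25, 0.9), runif(n, 0, 0.18)),
                    locus_9p24_1_deleted = cohort$del_9p24_1,
                    mean_copy_number = cohort$mean_copy_number,
                    purity = cohort$purity,
                    hla_loh = cohort$hla_loh)
  signatures <- cohort[, c("patient_id", "sbs1", "sbs2", "sbs4", "sbs13")]
  names(signatures)[1] <- "sample_id"
  clinical_cols <- setdiff(names(cohort),
                           c("tmb", "n_mutations", "clonal_load", "indel_load", "tp53_mut",
                             "del_9p24_1", "mean_copy_number", "purity", "hla_loh",
                             "sbs1", "sbs2", "sbs4", "sbs13", "siri",
                             "response", "clinical_benefit"))
  list(clinical = cohort[, clinical_cols], mutations = mutations, cna = cna,
       signatures = signatures, cohort = cohort)
}
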