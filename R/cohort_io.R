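# Cohort, mutation, copy-number and signature table I/O plus all
# per-patient feature derivation. Tables are tab-separated UTF-8 with a
# header row; missing values are empty strings; numerics round-trip at full
# precision (written with 17 significant digits).

#' Filter somatic SNV calls to high confidence
#'
#' Applies the six-criterion confidence filter to a mutation table: tumor
#' VAF >= 0.05, tumor depth >= 50, normal depth >= 20, tumor alt reads >= 5,
#' VAF(normal)/VAF(tumor) < 0.2, and support on both strands. The same
#' filter is applied to indels (the calling pipeline does not distinguish;
#' see the methods vignette). Row order is preserved and the filter is
#' idempotent.
#'
#' @param records data frame with columns `vaf_tumor`, `vaf_normal`,
#'   `depth_tumor`, `depth_normal`, `alt_reads_tumor`, `strand_both`.
#' @return The subset of rows passing all criteria.
#' @export
filter_snvs <- function(records) {
  req <- c("vaf_tumor", "vaf_normal", "depth_tumor", "depth_normal",
           "alt_reads_tumor", "strand_both")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    .icb_stop(paste0("filter_snvs: missing columns: ",
                     paste(missing_cols, collapse = ", ")), "icb_validation_error")
  na_fields <- req[vapply(req, function(f) anyNA(records[[f]]), logical(1))]
  if (length(na_fields))
    .icb_stop(paste0("filter_snvs: missing values in required fields: ",
                     paste(na_fields, collapse = ", ")), "icb_validation_error")
  if (any(records$alt_reads_tumor > records$depth_tumor))
    .icb_stop("filter_snvs: alt_reads_tumor exceeds depth_tumor", "icb_validation_error")
  keep <- records$vaf_tumor >= 0.05 &
    records$depth_tumor >= 50 &
    records$depth_normal >= 20 &
    records$alt_reads_tumor >= 5 &
    (records$vaf_normal / records$vaf_tumor) < 0.2 &
    as.logical(records$strand_both)
  records[keep, , drop = FALSE]
}

#' Tumor mutational burden
#'
#' Somatic mutation count normalized to the exonic coverage in megabases.
#' Full precision is kept internally; round only for display.
#'
#' @param n_filtered_mutations mutation count(s) after filtering.
#' @param exonic_coverage_mbp covered exonic megabases, > 0.
#' @return TMB in mutations per megabase.
#' @examples
#' compute_tmb(1045, 20)  # 52.25, the microsatellite-unstable extreme
#' @export
compute_tmb <- function(n_filtered_mutations, exonic_coverage_mbp) {
  if (any(!is.finite(exonic_coverage_mbp)) || any(exonic_coverage_mbp <= 0))
    .icb_stop("compute_tmb: exonic coverage must be positive", "icb_domain_error")
  if (any(n_filtered_mutations < 0))
    .icb_stop("compute_tmb: negative mutation count", "icb_domain_error")
  n_filtered_mutations / exonic_coverage_mbp
}

#' Clonal mutational load
#'
#' Number of mutations with cancer cell fraction strictly above 0.5.
#' Missing CCFs are excluded from the count and reported via the
#' `n_missing_ccf` attribute (a per-sample missingness metric).
#'
#' @param ccf numeric vector of cancer cell fractions (NA allowed), or a
#'   data frame with a `ccf` column.
#' @return Integer count with attribute `n_missing_ccf`.
#' @export
compute_clonal_load <- function(ccf) {
  if (is.data.frame(ccf)) ccf <- ccf$ccf
  n_miss <- sum(is.na(ccf))
  if (n_miss > 0)
    message(sprintf("compute_clonal_load: %d mutation(s) without CCF excluded", n_miss))
  structure(sum(ccf > 0.5, na.rm = TRUE), n_missing_ccf = n_miss)
}

#' Systemic inflammatory response index (SIRI)
#'
#' `(neutrophils x monocytes) / lymphocytes`, all in 10^9 cells/L.
#' Non-positive lymphocyte counts are a data-entry problem, not a value to
#' coerce: they raise a domain error for clinical review.
#'
#' @param neutrophils,monocytes,lymphocytes absolute counts, > 0.
#' @return SIRI value(s).
#' @export
compute_siri <- function(neutrophils, monocytes, lymphocytes) {
  vals <- cbind(neutrophils, monocytes, lymphocytes)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .icb_stop("compute_siri: lab values must be positive and finite (flag for clinical-data review)",
              "icb_domain_error")
  neutrophils * monocytes / lymphocytes
}

#' PD-L1 combined positive score (CPS)
#'
#' `(PD-L1-positive tumor and immune cells) / (total tumor cells) x 100`.
#' Because the numerator includes immune cells the raw ratio can exceed
#' 100; by clinical convention the score is capped at 100 (capping is
#' reported via a message).
#'
#' @param pdl1_positive_cells non-negative integer count(s).
#' @param total_tumor_cells positive integer count(s).
#' @param cap cap value, default 100; `Inf` disables capping.
#' @return CPS value(s).
#' @export
compute_cps <- function(pdl1_positive_cells, total_tumor_cells, cap = 100) {
  if (any(total_tumor_cells <= 0))
    .icb_stop("compute_cps: total tumor cells must be positive", "icb_domain_error")
  if (any(pdl1_positive_cells < 0))
    .icb_stop("compute_cps: negative cell count", "icb_domain_error")
  cps <- 100 * pdl1_positive_cells / total_tumor_cells
  if (any(cps > cap)) {
    message(sprintf("compute_cps: %d value(s) above %s capped", sum(cps > cap), format(cap)))
    cps <- pmin(cps, cap)
  }
  cps
}

#' Call an arm-level copy-number event
#'
#' An arm counts as deleted (or amplified) when the fraction of its genes
#' with the event strictly exceeds 0.20.
#'
#' @param arm_fraction fraction(s) of genes on the arm carrying the event.
#' @return Logical vector.
#' @export
call_arm_event <- function(arm_fraction) {
  if (any(arm_fraction < 0 | arm_fraction > 1, na.rm = TRUE))
    .icb_stop("call_arm_event: fractions must lie in [0, 1]", "icb_validation_error")
  arm_fraction > 0.20
}

#' Classify ploidy from mean copy number
#'
#' Diploid for mean copy number in `[1.5, 2.5]`, hyperploid above 2.5.
#' Values below 1.5 fall outside the defined bands: they are flagged as
#' `NA` with a warning and should be excluded from ploidy-based
#' comparisons.
#'
#' @param mean_copy_number positive mean copy number(s).
#' @return Character vector `"diploid"`/`"hyperploid"` with `NA` for
#'   out-of-range samples.
#' @export
classify_ploidy <- function(mean_copy_number) {
  if (any(mean_copy_number <= 0, na.rm = TRUE))
    .icb_stop("classify_ploidy: mean copy number must be positive", "icb_validation_error")
  out <- ifelse(mean_copy_number > 2.5, "hyperploid",
                ifelse(mean_copy_number >= 1.5, "diploid", NA_character_))
  n_low <- sum(is.na(out) & !is.na(mean_copy_number))
  if (n_low > 0)
    warning(sprintf("classify_ploidy: %d sample(s) with mean CN < 1.5 flagged out-of-range and excluded from ploidy comparisons", n_low))
  out
}

#' Integrate multi-assay HPV testing into a single status
#'
#' Single performed test: its result stands. Multiple tests: positive only
#' if all performed tests are positive, with one exception — a negative DNA
#' ISH is overridden when p16 IHC or RNA ISH is positive (DNA ISH has
#' limited sensitivity).
#'
#' @param p16_ihc,pcr,dna_ish,rna_ish each `"pos"`, `"neg"` or
#'   `"not_done"`. Vectorized over tumors.
#' @return `"HPV_positive"` or `"HPV_negative"` per tumor.
#' @export
integrate_hpv_status <- function(p16_ihc = "not_done", pcr = "not_done",
                                 dna_ish = "not_done", rna_ish = "not_done") {
  assays <- cbind(p16_ihc = p16_ihc, pcr = pcr, dna_ish = dna_ish, rna_ish = rna_ish)
  ok <- assays %in% c("pos", "neg", "not_done")
  if (!all(ok)) .icb_stop("assay results must be pos/neg/not_done", "icb_validation_error")
  apply(assays, 1, function(a) {
    performed <- a != "not_done"
    if (!any(performed))
      .icb_stop("integrate_hpv_status: no assay performed", "icb_validation_error")
    others <- a[performed & names(a) != "dna_ish"]
    all_pos <- all(a[performed] == "pos")
    exception <- !is.na(a["dna_ish"]) && a["dna_ish"] == "neg" &&
      (a["p16_ihc"] == "pos" || a["rna_ish"] == "pos") &&
      (length(others) == 0 || all(others == "pos"))
    if (all_pos || exception) "HPV_positive" else "HPV_negative"
  })
}

#' Derive response endpoints
#'
#' Objective response: best RECIST response of CR or PR. Clinical benefit:
#' objective response, or stable disease lasting at least 6 months
#' (duration measured from the first infusion to progression or censoring).
#'
#' @param best_response character vector in `{CR, PR, SD, PD, NE}`.
#' @param sd_duration_months duration of stable disease in months (only
#'   used for `SD` rows; NA elsewhere is fine).
#' @return Data frame with logical columns `response`, `clinical_benefit`.
#' @export
derive_endpoints <- function(best_response, sd_duration_months = NA_real_) {
  if (!all(best_response %in% c("CR", "PR", "SD", "PD", "NE")))
    .icb_stop("best_response must be one of CR/PR/SD/PD/NE", "icb_validation_error")
  sd_duration_months <- rep_len(sd_duration_months, length(best_response))
  response <- best_response %in% c("CR", "PR")
  benefit <- response | (best_response == "SD" &
                           !is.na(sd_duration_months) & sd_duration_months >= 6)
  data.frame(response = response, clinical_benefit = benefit)
}

#' Account for validation-cohort sample exclusions
#'
#' Applies the external-cohort quality filter: samples failing sequencing
#' QC are dropped, samples without a purity estimate cannot be subtyped and
#' are dropped, and hypermutated outliers (TMB above `outlier_factor` times
#' the cohort median, e.g. POLE-driven) are excluded because no comparably
#' hypermutated tumors exist in the reference cohort.
#'
#' @param samples data frame with columns `sample_id`, `qc_pass` (logical),
#'   `purity` (NA when undetermined), `tmb`.
#' @param outlier_factor multiple of the cohort median TMB beyond which a
#'   sample is excluded (default 10).
#' @return List with `kept` (data frame), `n_kept`, and `exclusions`
#'   (data frame of sample_id + reason).
#' @export
filter_validation_samples <- function(samples, outlier_factor = 10) {
  stopifnot(all(c("sample_id", "qc_pass", "purity", "tmb") %in% names(samples)))
  reason <- rep(NA_character_, nrow(samples))
  reason[!samples$qc_pass] <- "failed_qc"
  reason[is.na(reason) & is.na(samples$purity)] <- "purity_undetermined"
  med <- median(samples$tmb[is.na(reason)], na.rm = TRUE)
  out <- flag_tmb_outliers(samples$tmb, factor = outlier_factor, reference_median = med)
  reason[is.na(reason) & out] <- "tmb_outlier"
  kept <- samples[is.na(reason), , drop = FALSE]
  excl <- data.frame(sample_id = samples$sample_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  if (nrow(excl)) message(sprintf("filter_validation_samples: excluded %d of %d sample(s)",
                                  nrow(excl), nrow(samples)))
  list(kept = kept, n_kept = nrow(kept), exclusions = excl)
}

# ---------------------------------------------------------------------------
# Table I/O: tab-separated, UTF-8, header row, NA as empty string, numerics
# at 17 significant digits so a write/read round-trip is bit-exact.

#' Read a cohort-style TSV table
#' @param path file path.
#' @return data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          check.names = FALSE)
  # logical columns serialize as TRUE/FALSE strings
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) && all(v %in% c("TRUE", "FALSE", NA)))
      df[[nm]] <- as.logical(v)
  }
  df
}

#' Write a cohort-style TSV table
#' @param df data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.double(v)) {
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[nm]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_mutations <- read_cohort

#' @rdname read_cohort
#' @export
read_copy_number <- read_cohort

#' @rdname read_cohort
#' @export
read_signatures <- read_cohort

#' Build an analysis-ready cohort table from component tables
#'
#' Merges a clinical table with per-sample mutation, copy-number and
#' mutational-signature tables, applying the SNV confidence filter and
#' deriving TMB, clonal load, indel load, SIRI, CPS-derived flags,
#' arm-level events, ploidy class and response endpoints.
#'
#' @param clinical data frame keyed by `patient_id` with labs, endpoints and
#'   covariates (see the synthetic generator for the full column set).
#' @param mutations mutation table keyed by `sample_id` (same ids) with the
#'   columns required by [filter_snvs()] plus `gene`, `variant_class`, `ccf`.
#' @param cna copy-number table keyed by `sample_id` with
#'   `frac_9p_deleted` (arm fraction), `locus_9p24_1_deleted`,
#'   `mean_copy_number`, `purity`, `hla_loh`.
#' @param signatures signature table keyed by `sample_id` with columns
#'   `sbs1`, `sbs2`, `sbs4`, `sbs13` (contribution fractions).
#' @param exonic_coverage_mbp covered megabases used for TMB (default 30).
#' @return Analysis-ready data frame, one row per patient.
#' @export
build_cohort <- function(clinical, mutations, cna, signatures,
                         exonic_coverage_mbp = 30) {
  stopifnot("patient_id" %in% names(clinical))
  flt <- filter_snvs(mutations)
  ids <- clinical$patient_id
  n_mut <- vapply(ids, function(i) sum(flt$sample_id == i), integer(1))
  clonal <- vapply(ids, function(i) {
    as.integer(compute_clonal_load(suppressMessages(flt$ccf[flt$sample_id == i])))
  }, integer(1))
  indel <- vapply(ids, function(i) {
    sum(flt$sample_id == i &
          flt$variant_class %in% c("frameshift_indel", "inframe_indel"))
  }, integer(1))
  tp53 <- vapply(ids, function(i) any(flt$sample_id == i & flt$gene == "TP53"), logical(1))
  out <- clinical
  out$tmb <- compute_tmb(n_mut, exonic_coverage_mbp)
  out$clonal_load <- clonal
  out$indel_load <- indel
  out$tp53_mut <- tp53
  m <- match(ids, cna$sample_id)
  out$del_9p_arm <- call_arm_event(cna$frac_9p_deleted[m])
  out$del_9p24_1 <- as.logical(cna$locus_9p24_1_deleted[m])
  out$mean_copy_number <- cna$mean_copy_number[m]
  out$ploidy_class <- classify_ploidy(cna$mean_copy_number[m])
  out$purity <- cna$purity[m]
  out$hla_loh <- as.logical(cna$hla_loh[m])
  ms <- match(ids, signatures$sample_id)
  for (s in c("sbs1", "sbs2", "sbs4", "sbs13")) out[[s]] <- signatures[[s]][ms]
  if (all(c("neutrophils", "monocytes", "lymphocytes") %in% names(clinical)))
    out$siri <- compute_siri(clinical$neutrophils, clinical$monocytes,
                             clinical$lymphocytes)
  if ("best_response" %in% names(clinical)) {
    ep <- derive_endpoints(clinical$best_response,
                           if ("sd_duration_months" %in% names(clinical))
                             clinical$sd_duration_months else NA_real_)
    out$response <- ep$response
    out$clinical_benefit <- ep$clinical_benefit
  }
  out
}
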