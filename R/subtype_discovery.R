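# Feature screening, survival-guided dichotomization, hierarchical
# molecular subtyping and radar profiling.

#' Screen candidate features by univariable survival association
#'
#' Fits a univariable Cox model for each candidate feature in three strata
#' (virus-positive, virus-negative, combined) and retains features with a
#' Wald p-value at or below `alpha` in any stratum. Features failing to
#' converge in a stratum contribute no evidence from it.
#'
#' @param cohort data frame with `virus_positive`, `<endpoint>_time`,
#'   `<endpoint>_event` and the candidate columns.
#' @param candidate_features character vector of column names.
#' @param endpoint `"pfs"` (default) or `"os"`.
#' @param alpha retention threshold on the p-value (default 0.1).
#' @return Data frame with one row per candidate (`feature`, `p_combined`,
#'   `p_vpos`, `p_vneg`, `retained`); attribute `retained` holds the
#'   retained names. Empty input gives an empty result, no error.
#' @export
screen_features <- function(cohort, candidate_features, endpoint = c("pfs", "os"),
                            alpha = 0.1) {
  endpoint <- match.arg(endpoint)
  tm <- cohort[[paste0(endpoint, "_time")]]
  ev <- cohort[[paste0(endpoint, "_event")]]
  strata <- list(combined = rep(TRUE, nrow(cohort)),
                 vpos = cohort$virus_positive,
                 vneg = !cohort$virus_positive)
  one_p <- function(feature, idx) {
    x <- cohort[[feature]][idx]
    if (length(unique(x[!is.na(x)])) < 2) return(NA_real_)
    fit <- tryCatch(
      suppressWarnings(cox_univariable(tm[idx], ev[idx], x)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) NA_real_ else fit$p
  }
  res <- data.frame(
    feature = candidate_features,
    p_combined = vapply(candidate_features, one_p, 0, idx = strata$combined),
    p_vpos = vapply(candidate_features, one_p, 0, idx = strata$vpos),
    p_vneg = vapply(candidate_features, one_p, 0, idx = strata$vneg),
    stringsAsFactors = FALSE
  )
  pm <- as.matrix(res[, c("p_combined", "p_vpos", "p_vneg")])
  res$retained <- apply(pm, 1, function(p) any(p <= alpha, na.rm = TRUE))
  rownames(res) <- NULL
  structure(res, retained = res$feature[res$retained])
}

#' Dichotomize a feature at the best PFS-separating threshold
#'
#' Evaluates the two-group log-rank statistic at every candidate threshold
#' (midpoints of consecutive sorted unique values, restricted to the
#' 10th-90th percentile window to forbid degenerate one-versus-rest splits)
#' and returns the maximizing threshold. Ties are broken toward the more
#' balanced split, then toward the smaller threshold. The continuous-
#' covariate Cox p-value (`screen_p`) is carried along; callers should gate
#' on it (the maximally selected statistic itself is anti-conservative).
#'
#' @param cohort data frame with the feature and endpoint columns.
#' @param feature column name of the continuous feature.
#' @param endpoint `"pfs"` or `"os"`.
#' @param lower_q,upper_q percentile window for candidate thresholds.
#' @param min_n,min_events preconditions (defaults 20 patients, 5 events).
#' @return Object of class `dichotomized_feature`: list with `name`,
#'   `threshold`, `direction` (`"high_above"` if the above-threshold group
#'   carries the higher hazard, `"high_below"` otherwise), `logrank_stat`,
#'   `screen_p`, `n_above`, `n_below`.
#' @export
dichotomize_by_pfs <- function(cohort, feature, endpoint = "pfs",
                               lower_q = 0.1, upper_q = 0.9,
                               min_n = 20, min_events = 5) {
  x <- cohort[[feature]]
  tm <- cohort[[paste0(endpoint, "_time")]]
  ev <- as.integer(cohort[[paste0(endpoint, "_event")]])
  keep <- complete.cases(x, tm, ev)
  x <- x[keep]; tm <- tm[keep]; ev <- ev[keep]
  if (length(x) < min_n)
    .icb_stop(sprintf("dichotomize: need >= %d patients", min_n), "icb_domain_error")
  if (sum(ev) < min_events)
    .icb_stop(sprintf("dichotomize: need >= %d events", min_events), "icb_domain_error")
  ux <- sort(unique(x))
  if (length(ux) < 2)
    .icb_stop("dichotomize: all feature values identical", "icb_no_threshold_error")
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  qs <- quantile(x, c(lower_q, upper_q), type = 7)
  cand <- mids[mids >= qs[1] & mids <= qs[2]]
  if (length(cand) == 0) cand <- mids[which.min(abs(mids - median(x)))]
  ord <- order(tm)
  t_s <- tm[ord]; e_s <- ev[ord]; x_s <- x[ord]
  n <- length(x)
  stats_ <- vapply(cand, function(thr) .logrank2_stat(t_s, e_s, x_s > thr), numeric(2))
  stat <- stats_["stat", ]
  best_stat <- max(stat)
  at_max <- which(stat >= best_stat - 1e-9)
  if (length(at_max) > 1) {
    balance <- abs(vapply(cand[at_max], function(thr) sum(x > thr), 0) - n / 2)
    at_max <- at_max[order(balance, cand[at_max])]
  }
  pick <- at_max[1]
  thr <- cand[pick]
  # direction from the sign of (O - E) in the above-threshold group
  ome <- stats_["o_minus_e", pick]
  screen_p <- tryCatch(suppressWarnings(cox_univariable(tm, ev, x)$p),
                       error = function(e) NA_real_)
  structure(list(name = feature, threshold = thr,
                 direction = if (ome >= 0) "high_above" else "high_below",
                 logrank_stat = best_stat, screen_p = screen_p,
                 n_above = sum(x > thr), n_below = sum(x <= thr)),
            class = "dichotomized_feature")
}

#' Apply a dichotomization
#' @param dich a `dichotomized_feature`.
#' @param x numeric values.
#' @return Logical: TRUE where the value is above the threshold.
#' @export
dichotomize_apply <- function(dich, x) x > dich$threshold

#' Cluster patients into molecular subtypes
#'
#' Unsupervised hierarchical clustering (Euclidean distance, complete
#' linkage) of a patients-by-features 0/1 matrix, cut to exactly `k`
#' clusters. Rows are sorted lexicographically before linkage so the
#' result does not depend on patient order despite the many tied 0/1
#' distances. Cluster labels are canonicalized deterministically:
#' TP53-mutant-majority clusters take labels 1-3 (ascending TMB-high
#' fraction; tie broken by descending 9p24.1-deleted fraction, so the
#' deletion-dominated cluster is 2), TP53-wild-type clusters take labels
#' 4-6 (descending TMB-high fraction; tie broken by ascending purity-high
#' fraction, so the high-purity cluster is 6). This matches the published
#' subtype semantics so the fixed risk map (low = {3,4,5},
#' high = {1,2,6}) is meaningful.
#'
#' @param binary_matrix numeric 0/1 matrix (or data frame), patients in
#'   rows; typically 13 dichotomized genomic features plus viral status.
#'   Canonicalization looks for columns named `tp53_mut`, `tmb_high`,
#'   `del_9p24_1`, `purity_high` (absent columns contribute 0).
#' @param k number of clusters (default 6).
#' @return Object of class `subtype_model`: list with `assignments`
#'   (integer 1..k per patient, original order), `tree` (hclust), `k`,
#'   `risk_map`, `feature_names`, `cluster_profiles` (per-cluster feature
#'   fractions).
#' @export
cluster_subtypes <- function(binary_matrix, k = 6) {
  mat <- as.matrix(binary_matrix)
  storage.mode(mat) <- "double"
  if (anyNA(mat) || !all(mat %in% c(0, 1)))
    .icb_stop("cluster_subtypes: matrix must be complete 0/1", "icb_validation_error")
  n <- nrow(mat)
  if (n < k)
    .icb_stop(sprintf("cluster_subtypes: cannot produce %d clusters from %d patients", k, n),
              "icb_domain_error")
  ord <- do.call(order, as.data.frame(mat))
  m_sorted <- mat[ord, , drop = FALSE]
  tree <- hclust(dist(m_sorted, method = "euclidean"), method = "complete")
  raw_sorted <- cutree(tree, k = k)
  raw <- integer(n)
  raw[ord] <- raw_sorted
  relab <- .canonical_subtype_labels(mat, raw, k)
  assignments <- relab[raw]
  profiles <- t(vapply(seq_len(k), function(s)
    colMeans(mat[assignments == s, , drop = FALSE]), numeric(ncol(mat))))
  rownames(profiles) <- paste0("subtype_", seq_len(k))
  structure(list(assignments = assignments, tree = tree, k = k,
                 risk_map = list(low = c(3L, 4L, 5L), high = c(1L, 2L, 6L)),
                 feature_names = colnames(mat), cluster_profiles = profiles),
            class = "subtype_model")
}

# Deterministic relabeling of raw cluster ids to canonical subtype numbers:
# split clusters into a TP53-mutant-majority block (labels 1-3) and a
# wild-type block (4-6); within the mutant block the 9p24.1-deletion-
# dominated cluster is 2 and the remaining two are 1/3 by ascending
# TMB-high fraction; within the wild-type block the TMB-high cluster is 4,
# the higher-purity cluster of the remainder is 6 and the other is 5.
# Ties break by descending size then lowest raw id, so relabeling is total.
.canonical_subtype_labels <- function(mat, raw, k) {
  col_or_zero <- function(nm) if (nm %in% colnames(mat)) mat[, nm] else rep(0, nrow(mat))
  frac <- function(v) vapply(seq_len(k), function(c) mean(v[raw == c]), 0)
  f_tp53 <- frac(col_or_zero("tp53_mut")); f_tmb <- frac(col_or_zero("tmb_high"))
  f_del <- frac(col_or_zero("del_9p24_1")); f_pur <- frac(col_or_zero("purity_high"))
  sizes <- tabulate(raw, k)
  n_mut_block <- ceiling(k / 2)
  mut_block <- order(-f_tp53, -sizes, seq_len(k))[seq_len(n_mut_block)]
  wt_block <- setdiff(seq_len(k), mut_block)
  pick <- function(block, key) block[order(-key[block], -sizes[block], block)][1]
  relab <- integer(k)
  if (k == 6) {
    s2 <- pick(mut_block, f_del)
    rest_m <- setdiff(mut_block, s2)
    rest_m <- rest_m[order(f_tmb[rest_m], -sizes[rest_m], rest_m)]
    s4 <- pick(wt_block, f_tmb)
    rest_w <- setdiff(wt_block, s4)
    s6 <- pick(rest_w, f_pur)
    s5 <- setdiff(rest_w, s6)
    relab[c(rest_m[1], s2, rest_m[2], s4, s5, s6)] <- 1:6
  } else {
    ordered <- c(mut_block[order(f_tmb[mut_block], -sizes[mut_block], mut_block)],
                 wt_block[order(-f_tmb[wt_block], -sizes[wt_block], wt_block)])
    relab[ordered] <- seq_len(k)
  }
  relab
}

#' Map subtypes to risk groups
#' @param subtype integer subtype labels 1..6.
#' @param risk_map list with `low` and `high` label sets.
#' @return Character vector `"low_risk"`/`"high_risk"`.
#' @export
subtype_risk_group <- function(subtype, risk_map = list(low = c(3, 4, 5), high = c(1, 2, 6))) {
  out <- rep(NA_character_, length(subtype))
  out[subtype %in% risk_map$low] <- "low_risk"
  out[subtype %in% risk_map$high] <- "high_risk"
  out
}

#' Immunogenomic radar profile
#'
#' Fractions of a patient group positive for the seven parameters
#' associated with checkpoint-blockade response: CD8 infiltration above
#' the cohort median, CPS >= 1, TMB at or above the PFS-derived threshold
#' (3.34 muts/Mbp by default), virus positivity, intact 9p24.1, absent
#' smoking signature, and present APOBEC signature.
#'
#' @param patients data frame rows for the group (columns `cd8_per_roi`,
#'   `cps`, `tmb`, `virus_positive`, `del_9p24_1`, `sbs4`, `sbs2`, `sbs13`).
#' @param cd8_cutoff cohort-median CD8 count per ROI (pass the full-cohort
#'   median, not the group's).
#' @param tmb_threshold TMB high/low threshold (default 3.34).
#' @param cps_threshold CPS positivity threshold (default 1).
#' @param signature_threshold minimum contribution fraction for a
#'   signature to count as present (default 0.05).
#' @return Named numeric vector of 7 fractions in `[0, 1]`.
#' @export
radar_profile <- function(patients, cd8_cutoff, tmb_threshold = 3.34,
                          cps_threshold = 1, signature_threshold = 0.05) {
  if (nrow(patients) == 0)
    .icb_stop("radar_profile: empty patient group", "icb_domain_error")
  c(
    cd8_high = mean(patients$cd8_per_roi > cd8_cutoff, na.rm = TRUE),
    cps_positive = mean(patients$cps >= cps_threshold, na.rm = TRUE),
    tmb_high = mean(patients$tmb >= tmb_threshold, na.rm = TRUE),
    virus_positive = mean(patients$virus_positive, na.rm = TRUE),
    no_9p24_1_deletion = mean(!patients$del_9p24_1, na.rm = TRUE),
    smoking_signature_absent = mean(patients$sbs4 <= signature_threshold, na.rm = TRUE),
    apobec_signature_present = mean(patients$sbs2 + patients$sbs13 > signature_threshold,
                                    na.rm = TRUE)
  )
}

#' Canonical binarized feature matrix for subtyping
#'
#' Builds the patients-by-features 0/1 matrix the reference classification
#' uses, from frozen thresholds: TMB at `tmb_threshold` (3.34 muts/Mbp),
#' smoking signature present when SBS4 exceeds `signature_threshold`,
#' APOBEC present when SBS2+SBS13 exceeds it, aging signature from SBS1,
#' clonal and indel load above the cohort median, hyperploidy (mean copy
#' number > 2.5), purity above the cohort median, plus the already-binary
#' TP53, 9p24.1-deletion, HLA-LOH and viral-status columns.
#'
#' @param cohort analysis-ready cohort table.
#' @param tmb_threshold TMB high/low cut (default 3.34).
#' @param signature_threshold signature presence cut (default 0.05).
#' @param purity_threshold `"median"` or a number.
#' @return Numeric 0/1 matrix with `patient_id` rownames.
#' @export
make_binary_matrix <- function(cohort, tmb_threshold = 3.34,
                               signature_threshold = 0.05,
                               purity_threshold = "median") {
  pth <- if (identical(purity_threshold, "median"))
    median(cohort$purity, na.rm = TRUE) else purity_threshold
  mat <- cbind(
    tp53_mut = as.numeric(cohort$tp53_mut),
    tmb_high = as.numeric(cohort$tmb >= tmb_threshold),
    clonal_high = as.numeric(cohort$clonal_load > median(cohort$clonal_load, na.rm = TRUE)),
    indel_high = as.numeric(cohort$indel_load > median(cohort$indel_load, na.rm = TRUE)),
    smoking_sig = as.numeric(cohort$sbs4 > signature_threshold),
    apobec_sig = as.numeric(cohort$sbs2 + cohort$sbs13 > signature_threshold),
    aging_sig = as.numeric(cohort$sbs1 > signature_threshold),
    del_9p24_1 = as.numeric(cohort$del_9p24_1),
    hla_loh = as.numeric(cohort$hla_loh),
    hyperploid = as.numeric(cohort$mean_copy_number > 2.5),
    purity_high = as.numeric(cohort$purity > pth),
    virus_positive = as.numeric(cohort$virus_positive)
  )
  rownames(mat) <- cohort$patient_id
  mat
}

#' Fit the full subtype model on a cohort
#'
#' Convenience wrapper: screens candidate continuous features, dichotomizes
#' the retained ones at their best PFS-separating thresholds, assembles the
#' binary matrix (adding the already-binary features and viral status) and
#' clusters into `k` subtypes.
#'
#' @param cohort analysis-ready cohort table.
#' @param continuous_features continuous candidates to screen+dichotomize.
#' @param binary_features already-binary columns entering the matrix as-is.
#' @param endpoint survival endpoint for screening/dichotomization.
#' @param alpha screening threshold.
#' @param k number of subtypes.
#' @return List with `model` (`subtype_model`), `thresholds` (list of
#'   `dichotomized_feature`), `screen` (screening table), `matrix`.
#' @export
fit_subtypes <- function(cohort,
                         continuous_features = c("tmb", "clonal_load", "indel_load",
                                                 "sbs1", "sbs2", "sbs4", "sbs13",
                                                 "purity", "mean_copy_number"),
                         binary_features = c("tp53_mut", "del_9p24_1", "hla_loh"),
                         endpoint = "pfs", alpha = 0.1, k = 6) {
  scr <- screen_features(cohort, continuous_features, endpoint, alpha)
  retained <- attr(scr, "retained")
  dichs <- lapply(retained, function(f) dichotomize_by_pfs(cohort, f, endpoint))
  names(dichs) <- retained
  cols <- list()
  for (f in retained) {
    nm <- if (f %in% c("purity", "tmb", "mean_copy_number", "clonal_load", "indel_load"))
      paste0(f, "_high") else paste0(f, "_high")
    cols[[nm]] <- as.numeric(dichotomize_apply(dichs[[f]], cohort[[f]]))
  }
  for (f in binary_features) cols[[f]] <- as.numeric(cohort[[f]])
  cols[["virus_positive"]] <- as.numeric(cohort$virus_positive)
  mat <- do.call(cbind, cols)
  rownames(mat) <- cohort$patient_id
  list(model = cluster_subtypes(mat, k = k), thresholds = dichs,
       screen = scr, matrix = mat)
}
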