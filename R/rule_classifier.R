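# Portable 4-feature subtype classifier (TP53, 9p24.1, TMB, purity) with
# cross-cohort TMB quantile calibration and concordance auditing.

#' Rule-based molecular subtype assignment
#'
#' Decision table over four binary inputs. TP53-mutant branch: 9p24.1
#' deleted gives subtype 2 (deletion is that subtype's dominant feature);
#' otherwise high TMB gives subtype 3; otherwise subtype 1. TP53-wild-type
#' branch (default order checks TMB first): high TMB gives subtype 4; else
#' high purity gives subtype 6 (high purity is subtype 6's principal
#' characteristic); else subtype 5. The branch order is a configuration
#' switch because the source prose is ambiguous for TMB-high + purity-high
#' wild-type tumors.
#'
#' @param tp53_mutated,del_9p24_1,tmb_high,purity_high logical vectors
#'   (no missing values allowed; the rule is total on complete inputs).
#' @param wt_order `c("tmb", "purity")` (default) or `c("purity", "tmb")`.
#' @return Integer subtype 1..6 per patient.
#' @export
classify_subtype <- function(tp53_mutated, del_9p24_1, tmb_high, purity_high,
                             wt_order = c("tmb", "purity")) {
  inputs <- cbind(tp53_mutated, del_9p24_1, tmb_high, purity_high)
  if (anyNA(inputs))
    .icb_stop("classify_subtype: all four rule inputs must be present", "icb_validation_error")
  wt_order <- match.arg(wt_order[1], c("tmb", "purity"))
  n <- nrow(inputs)
  out <- integer(n)
  mut <- as.logical(inputs[, 1])
  out[mut] <- ifelse(inputs[mut, 2], 2L, ifelse(inputs[mut, 3], 3L, 1L))
  if (wt_order == "tmb") {
    out[!mut] <- ifelse(inputs[!mut, 3], 4L, ifelse(inputs[!mut, 4], 6L, 5L))
  } else {
    out[!mut] <- ifelse(inputs[!mut, 4], 6L, ifelse(inputs[!mut, 3], 4L, 5L))
  }
  out
}

#' Map a TMB threshold across cohorts by quantile normalization
#'
#' Computes the quantile of `reference_threshold` in the reference TMB
#' distribution (inverse of the type-7 sample quantile, linear between
#' order statistics) and returns that quantile of the target distribution.
#' This is how a 3.34 muts/Mbp whole-exome threshold transfers to a
#' muts-per-exome scale in an external cohort.
#'
#' @param reference_tmb,target_tmb non-empty numeric vectors.
#' @param reference_threshold threshold on the reference scale.
#' @return Threshold on the target scale.
#' @export
map_tmb_threshold <- function(reference_tmb, target_tmb, reference_threshold) {
  if (!length(reference_tmb) || !length(target_tmb))
    .icb_stop("map_tmb_threshold: empty cohort vector", "icb_validation_error")
  rs <- sort(reference_tmb)
  n <- length(rs)
  if (reference_threshold <= rs[1]) {
    p <- 0
  } else if (reference_threshold >= rs[n]) {
    p <- 1
  } else if (n == 1) {
    p <- 0.5
  } else {
    # inverse of quantile(type = 7): plotting positions (i-1)/(n-1)
    pos <- (seq_len(n) - 1) / (n - 1)
    p <- stats::approx(rs, pos, xout = reference_threshold, ties = "ordered")$y
  }
  unname(quantile(target_tmb, p, type = 7))
}

#' Audit rule-versus-clustering concordance
#'
#' @param rule_assignments,clustering_assignments integer subtype labels.
#' @param risk_map list with `low`/`high` subtype sets.
#' @return List with `subtype_concordance` and `risk_concordance`
#'   (fractions of patients with matching labels at each granularity).
#' @export
audit_concordance <- function(rule_assignments, clustering_assignments,
                              risk_map = list(low = c(3, 4, 5), high = c(1, 2, 6))) {
  stopifnot(length(rule_assignments) == length(clustering_assignments))
  ok <- !is.na(rule_assignments) & !is.na(clustering_assignments)
  if (!all(ok))
    message(sprintf("audit_concordance: %d unclassified patient(s) excluded", sum(!ok)))
  list(
    subtype_concordance = mean(rule_assignments[ok] == clustering_assignments[ok]),
    risk_concordance = mean(subtype_risk_group(rule_assignments[ok], risk_map) ==
                              subtype_risk_group(clustering_assignments[ok], risk_map))
  )
}

#' Flag hypermutated TMB outliers
#'
#' Samples with TMB above `factor` times the cohort median (e.g.
#' POLE-driven hypermutators) cannot be classified against a reference
#' cohort lacking comparable tumors and are flagged for exclusion.
#'
#' @param tmb numeric TMB vector.
#' @param factor outlier multiple (default 10).
#' @param reference_median optional externally supplied median.
#' @return Logical vector; flagged samples reported via a message.
#' @export
flag_tmb_outliers <- function(tmb, factor = 10, reference_median = NULL) {
  med <- if (is.null(reference_median)) median(tmb, na.rm = TRUE) else reference_median
  out <- !is.na(tmb) & tmb > factor * med
  if (any(out))
    message(sprintf("flag_tmb_outliers: %d sample(s) above %g x median TMB flagged",
                    sum(out), factor))
  out
}

#' Build, serialize and apply a frozen rule model
#'
#' A rule model freezes the thresholds that binarize the four inputs
#' (TMB threshold, purity threshold, wild-type branch order) so the
#' published classifier ships as a reviewable data file.
#'
#' @param tmb_threshold TMB high/low cutpoint (3.34 muts/Mbp in the
#'   reference analysis).
#' @param purity_threshold purity cutpoint; default is "median", resolved
#'   against the cohort at application time (no printed value exists).
#' @param wt_order wild-type branch order, see [classify_subtype()].
#' @return Object of class `rule_model`.
#' @export
rule_model <- function(tmb_threshold = 3.34, purity_threshold = "median",
                       wt_order = c("tmb", "purity")) {
  structure(list(tmb_threshold = tmb_threshold,
                 purity_threshold = purity_threshold,
                 wt_order = match.arg(wt_order[1], c("tmb", "purity"))),
            class = "rule_model")
}

#' @rdname rule_model
#' @param model a `rule_model`.
#' @param path JSON file path.
#' @export
write_rule_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rule_model
#' @export
read_rule_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rule_model(obj$tmb_threshold, obj$purity_threshold, obj$wt_order)
}

#' @rdname rule_model
#' @param cohort cohort table with `tp53_mut`, `del_9p24_1`, `tmb`,
#'   `purity`.
#' @param exclude_outliers drop TMB hypermutators (> 10 x median) before
#'   classification, returning NA for them.
#' @return For `apply_rule_model`: integer subtype per patient (NA for
#'   excluded outliers).
#' @export
apply_rule_model <- function(model, cohort, exclude_outliers = TRUE) {
  pth <- model$purity_threshold
  if (identical(pth, "median")) pth <- median(cohort$purity, na.rm = TRUE)
  out <- rep(NA_integer_, nrow(cohort))
  keep <- rep(TRUE, nrow(cohort))
  if (exclude_outliers) keep <- !flag_tmb_outliers(cohort$tmb)
  out[keep] <- classify_subtype(
    cohort$tp53_mut[keep],
    cohort$del_9p24_1[keep],
    cohort$tmb[keep] >= model$tmb_threshold,
    cohort$purity[keep] > pth,
    wt_order = model$wt_order)
  out
}
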