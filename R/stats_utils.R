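# Contingency-table and rank statistics used by all group comparisons.

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test computed by direct enumeration of the
#' conditional distribution of the top-left cell given fixed margins.
#' The two-sided p-value uses the probability-mass rule: the sum of the
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A list with `p_two_sided`, `p_less` (lower tail for the `[1,1]`
#'   cell), `p_greater` (upper tail), and the observed table.
#' @examples
#' fisher_exact_2x2(matrix(c(15, 3, 45, 39), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- .check_contingency(table, 2L, 2L)
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 margin
  n2 <- sum(tab[2, ])         # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  # relative tolerance guards against FP noise in the mass comparison
  p_two <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(
    p_two_sided = min(1, p_two),
    p_less = sum(dens[support <= a]),
    p_greater = sum(dens[support >= a]),
    table = tab
  )
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalizes Fisher's exact test to tables larger than 2x2. Tables with a
#' grand total at or below `exact_max_n` are evaluated exactly (network
#' algorithm); larger tables use Monte-Carlo sampling of the conditional
#' null (Patefield's algorithm) with a reported standard error. A 2x2 input
#' reduces exactly to [fisher_exact_2x2()]'s two-sided p-value.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param exact_max_n grand-total crossover from exact to Monte-Carlo.
#' @param n_mc number of Monte-Carlo tables when sampling is used.
#' @return List with `p`, `method` ("exact" or "monte_carlo"), and for the
#'   Monte-Carlo route `mc_se`, the binomial standard error of `p`.
#' @export
freeman_halton <- function(table, exact_max_n = 200, n_mc = 1e5) {
  tab <- .check_contingency(table)
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    return(list(p = fisher_exact_2x2(tab)$p_two_sided, method = "exact"))
  }
  if (sum(tab) <= exact_max_n) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    return(list(p = min(1, p), method = "exact"))
  }
  # Monte-Carlo: sample tables from the conditional null given both margins
  # and compare multivariate hypergeometric log-probabilities.
  lp_obs <- .log_prob_table(tab)
  draws <- stats::r2dtable(n_mc, rowSums(tab), colSums(tab))
  lp <- vapply(draws, .log_prob_table, numeric(1))
  hits <- sum(lp <= lp_obs + 1e-7)
  p <- (hits + 1) / (n_mc + 1)
  list(p = p, method = "monte_carlo", mc_se = sqrt(p * (1 - p) / n_mc))
}

# log P(table | margins) under the multivariate hypergeometric null
.log_prob_table <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' OR = ad/bc for a 2x2 table with a Wald interval on the log scale,
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with a zero
#' cell receive the Haldane-Anscombe 0.5 continuity correction in every
#' cell, flagged in the result.
#'
#' @param table 2x2 matrix, rows = exposure groups, columns = outcome.
#' @param confidence interval coverage (default 0.95; the validation-cohort
#'   comparison in the source analysis reports a 90% interval).
#' @return List with `or`, `ci` (length-2), `confidence`, `corrected`.
#' @examples
#' odds_ratio_woolf(matrix(c(15, 3, 45, 39), 2), confidence = 0.90)
#' @export
odds_ratio_woolf <- function(table, confidence = 0.95) {
  tab <- .check_contingency(table, 2L, 2L)
  stopifnot(confidence > 0, confidence < 1)
  corrected <- any(tab == 0)
  if (corrected) {
    message("odds_ratio_woolf: zero cell, applying Haldane-Anscombe 0.5 correction")
    tab <- tab + 0.5
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- qnorm(1 - (1 - confidence) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
       confidence = confidence, corrected = corrected)
}

#' Rank test dispatching on the number of groups
#'
#' Two groups: Wilcoxon rank-sum (mid-ranks for ties; exact p for small
#' tie-free samples, normal approximation otherwise). More than two groups:
#' Kruskal-Wallis with the chi-squared approximation.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @param exact passed to [stats::wilcox.test()] for the 2-group case.
#' @return List with `p`, `statistic`, `method`, `n_groups`.
#' @export
rank_tests <- function(values, groups, exact = NULL) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  ng <- nlevels(groups)
  if (ng < 2) .icb_stop("rank_tests: need at least 2 groups", "icb_domain_error")
  if (ng == 2) {
    fit <- suppressWarnings(stats::wilcox.test(
      values[groups == levels(groups)[1]],
      values[groups == levels(groups)[2]],
      exact = exact, correct = FALSE))
    list(p = fit$p.value, statistic = unname(fit$statistic),
         method = "wilcoxon_rank_sum", n_groups = 2L)
  } else {
    fit <- stats::kruskal.test(values, groups)
    list(p = fit$p.value, statistic = unname(fit$statistic),
         method = "kruskal_wallis", n_groups = ng)
  }
}

.check_contingency <- function(table, nr = NULL, nc = NULL) {
  tab <- as.matrix(table)
  if (!is.null(nr) && (nrow(tab) != nr || ncol(tab) != nc))
    .icb_stop(sprintf("expected a %dx%d table", nr, nc), "icb_validation_error")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    .icb_stop("contingency table must hold non-negative integers", "icb_validation_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .icb_stop("every row and column needs a positive margin", "icb_validation_error")
  storage.mode(tab) <- "double"
  tab
}
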