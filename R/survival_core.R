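# Survival primitives: Kaplan-Meier, log-rank, Cox wrapper, Harrell's C,
# time-dependent IPCW ROC. KM and the log-rank statistic are computed from
# first principles; Cox fitting and the concordance computation delegate to
# the survival package (Efron ties / pair counting with 0.5 for score ties),
# which is the field-standard implementation.

#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' Product-limit estimator. Confidence bounds use the Greenwood variance on
#' the log(-log) scale (the default of mainstream survival software for
#' bounded intervals), falling back to the plain scale on request.
#'
#' @param time follow-up times (months), non-negative.
#' @param event logical or 0/1 event indicator.
#' @param conf_level interval coverage, default 0.95.
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return Object of class `km_fit`: data frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`) and
#'   attributes `n` and `conf_level`. With no events the curve is flat at 1.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95, conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  .check_surv(time, event, require_event = FALSE)
  event <- as.integer(event)
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  ut <- unique(t_s[e_s == 1])
  if (length(ut) == 0) {
    out <- data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                      surv = numeric(0), lower = numeric(0), upper = numeric(0))
  } else {
    counts <- as.vector(table(factor(t_s, levels = sort(unique(t_s)))))
    all_t <- sort(unique(t_s))
    n_before <- c(0, cumsum(counts))[seq_along(all_t)]
    n_risk_all <- n - n_before
    d_all <- as.vector(rowsum(e_s, t_s))          # events per distinct time
    keep <- d_all > 0
    tt <- all_t[keep]; d <- d_all[keep]; r <- n_risk_all[keep]
    surv <- cumprod(1 - d / r)
    # Greenwood variance of log S
    gw <- cumsum(d / (r * (r - d)))
    z <- qnorm(1 - (1 - conf_level) / 2)
    if (conf_type == "log-log") {
      # CI on the log(-log S) scale; undefined where S is 0 or 1
      with_ci <- surv > 0 & surv < 1
      lower <- upper <- rep(NA_real_, length(surv))
      se_ll <- sqrt(gw) / abs(log(surv))
      lower[with_ci] <- surv[with_ci]^exp(z * se_ll[with_ci])
      upper[with_ci] <- surv[with_ci]^exp(-z * se_ll[with_ci])
      lower[surv == 0] <- 0; upper[surv == 0] <- 0
    } else {
      se <- surv * sqrt(gw)
      lower <- pmax(0, surv - z * se)
      upper <- pmin(1, surv + z * se)
    }
    out <- data.frame(time = tt, n_risk = r, n_event = d, surv = surv,
                      lower = lower, upper = upper)
  }
  structure(out, class = c("km_fit", "data.frame"), n = n, conf_level = conf_level)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param fit a `km_fit` object.
#' @param times times at which to read off the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(fit, times) {
  if (nrow(fit) == 0) return(rep(1, length(times)))
  idx <- findInterval(times, fit$time)
  ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
}

#' K-sample log-rank test
#'
#' Chi-squared log-rank statistic on k-1 degrees of freedom, computed from
#' the observed-minus-expected event counts and their covariance across
#' distinct event times (the hypergeometric variance form).
#'
#' @param time,event as in [kaplan_meier()]; at least one event required.
#' @param group group labels (2 or more groups).
#' @return List with `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- factor(group)
  if (nlevels(group) < 2) .icb_stop("log-rank needs >= 2 groups", "icb_domain_error")
  event <- as.integer(event)
  k <- nlevels(group)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; g_s <- group[ord]
  all_t <- sort(unique(t_s))
  nt_all <- length(t_s) - c(0, cumsum(as.vector(table(factor(t_s, levels = all_t)))))[seq_along(all_t)]
  d_all <- as.vector(rowsum(e_s, t_s))
  # per-group at-risk counts at each distinct time (k columns)
  G <- matrix(0, length(all_t), k)
  D <- matrix(0, length(all_t), k)
  for (j in seq_len(k)) {
    inj <- g_s == levels(group)[j]
    cnt <- as.vector(rowsum(as.integer(inj), t_s))
    G[, j] <- sum(inj) - c(0, cumsum(cnt))[seq_along(all_t)]
    D[, j] <- as.vector(rowsum(e_s * inj, t_s))
  }
  keep <- d_all > 0
  G <- G[keep, , drop = FALSE]; D <- D[keep, , drop = FALSE]
  nt <- nt_all[keep]; dt <- d_all[keep]
  O <- colSums(D)
  E <- colSums(D * 0 + dt * G / nt)
  # covariance of (O - E), first k-1 groups
  V <- matrix(0, k, k)
  hyper <- dt * (nt - dt) / pmax(nt - 1, 1)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    del <- as.numeric(a == b)
    V[a, b] <- sum(hyper * (G[, a] / nt) * (del - G[, b] / nt))
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vk, u)), error = function(e) {
    drop(t(u) %*% MASSginv(Vk) %*% u)
  })
  list(statistic = stat, df = k - 1L, p = pchisq(stat, k - 1L, lower.tail = FALSE),
       observed = setNames(O, levels(group)), expected = setNames(E, levels(group)))
}

# Moore-Penrose fallback for singular covariance (e.g. a group with no risk
# overlap); tiny local implementation to avoid a MASS dependency.
MASSginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Fast 2-group log-rank chi-squared statistic on pre-sorted data; the inner
# loop of the threshold search. `grp` is logical (TRUE = second group).
.logrank2_stat <- function(t_s, e_s, grp) {
  n <- length(t_s)
  all_t <- sort(unique(t_s))
  cnt <- as.vector(table(factor(t_s, levels = all_t)))
  nt <- n - c(0, cumsum(cnt))[seq_along(all_t)]
  dt <- as.vector(rowsum(e_s, t_s))
  cnt1 <- as.vector(rowsum(as.integer(grp), t_s))
  n1t <- sum(grp) - c(0, cumsum(cnt1))[seq_along(all_t)]
  d1t <- as.vector(rowsum(e_s * grp, t_s))
  keep <- dt > 0
  nt <- nt[keep]; dt <- dt[keep]; n1t <- n1t[keep]; d1t <- d1t[keep]
  o_minus_e <- sum(d1t - dt * n1t / nt)
  v <- sum(dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / pmax(nt - 1, 1))
  if (v <= 0) return(c(stat = 0, o_minus_e = o_minus_e))
  c(stat = o_minus_e^2 / v, o_minus_e = o_minus_e)
}

#' Univariable Cox proportional hazards model
#'
#' Partial-likelihood fit (Efron tie handling) for a single covariate,
#' returning the hazard ratio with a Wald interval on the log scale.
#' Degenerate fits (monotone likelihood, too few events) are flagged via
#' `converged = FALSE` and a warning rather than silently returned.
#'
#' @param time,event survival outcome.
#' @param covariate numeric (or logical/2-level) covariate.
#' @param conf_level interval coverage.
#' @return List with `hr`, `ci`, `coef`, `se`, `p`, `converged`, `n_events`.
#' @export
cox_univariable <- function(time, event, covariate, conf_level = 0.95) {
  .check_surv(time, event)
  if (is.logical(covariate)) covariate <- as.numeric(covariate)
  if (is.factor(covariate)) {
    if (nlevels(covariate) != 2)
      .icb_stop("factor covariates must have exactly 2 levels", "icb_domain_error")
    covariate <- as.numeric(covariate) - 1
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, as.integer(event)) ~ covariate,
                    ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) converged <- FALSE
  if (!converged)
    warning("cox_univariable: convergence failure or monotone likelihood; estimates unreliable")
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * z * se), coef = beta, se = se,
       p = 2 * pnorm(-abs(beta / se)), converged = converged,
       n_events = sum(as.integer(event)))
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable under censoring) pairs in which the
#' patient with the higher risk score experiences the event earlier; score
#' ties count 0.5. Computed via [survival::concordance()] with
#' `reverse = TRUE` so that higher scores mean higher risk.
#'
#' @param time,event survival outcome.
#' @param risk_score numeric risk scores (higher = shorter expected survival).
#' @return Scalar C-index in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk_score) {
  .check_surv(time, event)
  stopifnot(length(risk_score) == length(time))
  fit <- survival::concordance(
    survival::Surv(time, as.integer(event)) ~ risk_score, reverse = TRUE)
  unname(fit$concordance)
}

#' Time-dependent ROC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects with an observed event by the horizon, controls are subjects
#' still event-free past the horizon. Cases are weighted by `1/G(T-)` where
#' `G` is the Kaplan-Meier estimate of the censoring distribution, so the
#' estimator is consistent under independent censoring (the Uno form).
#' Without censoring before the horizon it reduces exactly to the binary
#' ROC on event-by-horizon labels.
#'
#' @param time,event survival outcome.
#' @param score risk score (higher = event sooner).
#' @param horizon evaluation time (months).
#' @return List with `auc`, `fpr`, `tpr` (curve over score cutoffs),
#'   `horizon`, `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(time, event, score, horizon) {
  .check_surv(time, event)
  stopifnot(length(score) == length(time), is.finite(horizon), horizon > 0)
  event <- as.integer(event)
  cens_km <- kaplan_meier(time, 1L - event)
  g_left <- function(t) km_survival_at(cens_km, t - 1e-12)   # G(t-)
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  n_cases <- sum(is_case); n_ctrl <- sum(is_ctrl)
  if (n_cases == 0 || n_ctrl == 0)
    .icb_stop("time_dependent_roc: need at least one case and one control at the horizon",
              "icb_domain_error")
  w <- rep(0, length(time))
  gv <- g_left(time[is_case])
  if (any(gv <= 0)) .icb_stop("censoring weight is zero at a case time", "icb_domain_error")
  w[is_case] <- 1 / gv
  sc_case <- score[is_case]; w_case <- w[is_case]; sc_ctrl <- score[is_ctrl]
  # AUC: weighted probability that a case outranks a control (ties 0.5)
  cmp <- outer(sc_case, sc_ctrl, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum(w_case * rowSums(cmp)) / (sum(w_case) * n_ctrl)
  cuts <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) sum(w_case[sc_case >= c]) / sum(w_case), 0)
  fpr <- vapply(cuts, function(c) mean(sc_ctrl >= c), 0)
  list(auc = auc, fpr = c(0, fpr, 1), tpr = c(0, tpr, 1), horizon = horizon,
       n_cases = n_cases, n_controls = n_ctrl)
}

#' Plain ROC AUC for a binary outcome
#'
#' Rank-based (Mann-Whitney) AUC used for the response endpoint, where no
#' time dimension applies.
#'
#' @param label logical/0-1 outcome.
#' @param score numeric score.
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(label, score) {
  label <- as.logical(label)
  stopifnot(length(label) == length(score), any(label), any(!label))
  r <- rank(score)
  n1 <- sum(label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * sum(!label))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, %d distinct event times, %.0f%% CI\n",
              attr(x, "n"), nrow(x), 100 * attr(x, "conf_level")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

.check_surv <- function(time, event, require_event = TRUE) {
  if (length(time) != length(event))
    .icb_stop("time and event lengths differ", "icb_validation_error")
  if (any(!is.finite(time)) || any(time < 0))
    .icb_stop("times must be finite and non-negative", "icb_validation_error")
  ev <- as.integer(event)
  if (any(is.na(ev)) || !all(ev %in% c(0L, 1L)))
    .icb_stop("event must be logical or 0/1", "icb_validation_error")
  if (require_event && sum(ev) == 0)
    .icb_stop("at least one event is required", "icb_domain_error")
  invisible(TRUE)
}
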