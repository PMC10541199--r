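# Independent oracles: every implementation-vs-oracle test in the suite
# checks the package against one of these (or against survival::/stats::),
# never against itself.

# product-limit estimator by explicit risk-set loop
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ut, surv = out)
}

# Harrell C by O(n^2) pair enumeration
oracle_cindex <- function(time, event, risk) {
  conc <- usable <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[i] < time[j] || (time[i] == time[j] && !event[j])
      if (!comparable) next
      usable <- usable + 1
      conc <- conc + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
    }
  }
  conc / usable
}

# permutation p-value for the 2-group log-rank statistic
oracle_logrank_perm_p <- function(time, event, group, n_perm, seed = 1) {
  obs <- logrank_test(time, event, group)$statistic
  set.seed(seed)
  hits <- 0
  for (b in seq_len(n_perm)) {
    g <- sample(group)
    if (logrank_test(time, event, g)$statistic >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Cox partial likelihood maximized numerically (tie-free data only, where
# Breslow/Efron/exact coincide)
oracle_cox_hr <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  negll <- function(beta) {
    lp <- beta * x
    s <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s <- s - (lp[i] - log(sum(exp(lp[rs]))))
    }
    s
  }
  exp(stats::optimize(negll, c(-10, 10))$minimum)
}

# hand-written HPV integration truth: transliterated independently of the
# package (explicit case analysis rather than the exception-override form)
oracle_hpv <- function(p16, pcr, dna, rna) {
  performed <- c(p16, pcr, dna, rna) != "not_done"
  if (!any(performed)) stop("no assay")
  res <- c(p16 = p16, pcr = pcr, dna_ish = dna, rna_ish = rna)[performed]
  if (all(res == "pos")) return("HPV_positive")
  negs <- names(res)[res == "neg"]
  if (identical(negs, "dna_ish") && (p16 == "pos" || rna == "pos"))
    return("HPV_positive")
  "HPV_negative"
}

# exact 2x2 Fisher by direct enumeration with the factorial formula
# (independent of dhyper)
oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1]); N <- sum(tab)
  lp <- function(a) {
    b <- m - a; c <- k - a; d <- n2 - c
    lgamma(m + 1) + lgamma(n2 + 1) + lgamma(k + 1) + lgamma(N - k + 1) -
      lgamma(N + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) - lgamma(d + 1)
  }
  supp <- max(0, k - n2):min(k, m)
  probs <- exp(vapply(supp, lp, 0))
  p_obs <- exp(lp(tab[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact Freeman-Halton by recursive enumeration of all tables with the
# observed margins (tiny tables only)
oracle_freeman_halton <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logp <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(m) + 1) -
      sum(lgamma(m + 1))
  }
  lp_obs <- logp(tab)
  total <- 0
  fill <- function(m, r, c) {
    if (r > nrow(tab)) {
      if (all(colSums(m) == cs)) {
        lp <- logp(m)
        if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    rem_row <- rs[r]
    rec_cell <- function(m, c, left) {
      if (c == ncol(tab)) {
        m[r, c] <- left
        if (m[r, c] <= cs[c] - sum(m[seq_len(r - 1), c])) fill(m, r + 1, 1)
        return(invisible())
      }
      max_v <- min(left, cs[c] - sum(m[seq_len(r - 1), c]))
      for (v in 0:max_v) {
        m[r, c] <- v
        rec_cell(m, c + 1, left - v)
      }
    }
    rec_cell(m, 1, rem_row)
  }
  fill(matrix(0L, nrow(tab), ncol(tab)), 1, 1)
  total
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  (s - sr * sc / n2) / ((sr + sc) / 2 - sr * sc / n2)
}
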