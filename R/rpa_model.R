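# Recursive-partitioning survival risk classifier: greedy log-rank
# splitting (left branch = value <= threshold, thresholds at data
# midpoints), depth- and leaf-size-limited, followed by merging of leaves
# with similar hazard and ordering of the merged groups by hazard.

#' Fit a recursive-partitioning survival tree
#'
#' Greedy binary partitioning: at each node the split (feature, midpoint
#' threshold) maximizing the two-group log-rank statistic is taken,
#' subject to a minimum leaf size, a maximum depth and a minimum statistic
#' (default 3.84, the 5% chi-squared critical value — nodes that cannot be
#' split significantly become leaves). Leaf hazard ratios are estimated
#' against the best-survival leaf; adjacent leaves (in hazard order) whose
#' HR ratio is below `merge_tolerance` are merged. Final groups are
#' ordered by hazard and labelled `low`/`intermediate`/`high` when three
#' remain.
#'
#' @param cohort data frame with the feature and endpoint columns.
#' @param features candidate split features; the reference classifier uses
#'   SIRI, TMB and the smoking signature, with viral status offered to the
#'   search as a bias control (it is typically not retained).
#' @param endpoint `"pfs"` (default) or `"os"`.
#' @param min_leaf minimum patients per leaf (default 15).
#' @param max_depth maximum tree depth (default 3).
#' @param min_stat minimum log-rank chi-squared to accept a split. The
#'   default (`NULL`) uses the 5% critical value of the *maximally
#'   selected* log-rank statistic over the admissible split window
#'   (Miller-Siegmund approximation), recomputed per node; the naive 3.84
#'   cutoff ignores the selection over thresholds and overgrows the tree.
#' @param merge_tolerance leaves whose HR ratio falls below this are merged
#'   (default 1.25).
#' @return Object of class `rpa_tree`: `nodes` (data frame of split
#'   rules), `leaf_group` (leaf id -> group label), `group_levels`,
#'   `features_used`, `leaf_hr`, `endpoint`, `smoking_feature`.
#' @export
fit_rpa <- function(cohort, features = c("siri", "tmb", "sbs4", "virus_positive"),
                    endpoint = c("pfs", "os"), min_leaf = 15, max_depth = 3,
                    min_stat = NULL, merge_tolerance = 1.25) {
  endpoint <- match.arg(endpoint)
  tm <- cohort[[paste0(endpoint, "_time")]]
  ev <- as.integer(cohort[[paste0(endpoint, "_event")]])
  X <- .feature_matrix(cohort, features)
  keep <- complete.cases(X) & is.finite(tm) & !is.na(ev)
  X <- X[keep, , drop = FALSE]; tm <- tm[keep]; ev <- ev[keep]
  n <- nrow(X)
  nodes <- data.frame(id = 1L, parent = NA_integer_, feature = NA_character_,
                      threshold = NA_real_, left = NA_integer_, right = NA_integer_,
                      depth = 0L, n = n, events = sum(ev), is_leaf = TRUE,
                      stringsAsFactors = FALSE)
  membership <- list(`1` = seq_len(n))
  open <- 1L
  while (length(open)) {
    id <- open[1]; open <- open[-1]
    idx <- membership[[as.character(id)]]
    depth <- nodes$depth[nodes$id == id]
    if (length(idx) < 2 * min_leaf || sum(ev[idx]) < 2 || depth >= max_depth) next
    best <- .best_split(X[idx, , drop = FALSE], tm[idx], ev[idx], min_leaf)
    crit <- if (is.null(min_stat))  # Bonferroni over candidate features
      .maxsel_critical(min_leaf / length(idx), alpha = 0.05 / ncol(X)) else min_stat
    if (is.null(best) || best$stat < crit) next
    lid <- max(nodes$id) + 1L; rid <- lid + 1L
    nodes$is_leaf[nodes$id == id] <- FALSE
    nodes$feature[nodes$id == id] <- colnames(X)[best$feature]
    nodes$threshold[nodes$id == id] <- best$threshold
    nodes$left[nodes$id == id] <- lid
    nodes$right[nodes$id == id] <- rid
    go_left <- X[idx, best$feature] <= best$threshold
    for (side in list(list(id = lid, idx = idx[go_left]),
                      list(id = rid, idx = idx[!go_left]))) {
      nodes <- rbind(nodes, data.frame(
        id = side$id, parent = id, feature = NA_character_,
        threshold = NA_real_, left = NA_integer_, right = NA_integer_,
        depth = depth + 1L, n = length(side$idx), events = sum(ev[side$idx]),
        is_leaf = TRUE, stringsAsFactors = FALSE))
      membership[[as.character(side$id)]] <- side$idx
      open <- c(open, side$id)
    }
  }
  leaves <- nodes$id[nodes$is_leaf]
  if (length(leaves) < 2)
    .icb_stop("fit_rpa: no admissible split; degenerate tree", "icb_degenerate_tree_error")
  leaf_of <- integer(n)
  for (l in leaves) leaf_of[membership[[as.character(l)]]] <- l
  hr <- setNames(.leaf_hazard_ratios(tm, ev, leaf_of, leaves), as.character(leaves))
  merged <- .merge_similar_leaves(tm, ev, leaf_of, hr, merge_tolerance)
  g <- length(unique(merged$group))
  labels <- if (g == 2) c("low", "high")
  else if (g == 3) c("low", "intermediate", "high")
  else c("low", paste0("intermediate_", seq_len(g - 2)), "high")
  leaf_group <- setNames(labels[merged$group], as.character(merged$leaf))
  structure(list(nodes = nodes, leaf_group = leaf_group, group_levels = labels,
                 features_used = unique(stats::na.omit(nodes$feature)),
                 leaf_hr = hr,
                 endpoint = endpoint,
                 smoking_feature = intersect(c("sbs4", "smoking_sig"), features)[1]),
            class = "rpa_tree")
}

# 5% critical value (squared) of the maximally selected standardized
# log-rank statistic over the proportion window [eps, 1-eps]
# (Miller & Siegmund 1982 tail approximation, as used by maxstat-type
# cutpoint methods).
.maxsel_critical <- function(eps, alpha = 0.05) {
  eps <- min(max(eps, 0.02), 0.49)
  lg <- 2 * log((1 - eps) / eps)
  f <- function(b) stats::dnorm(b) * ((b - 1 / b) * lg + 4 / b) - alpha
  b <- uniroot(f, c(1.5, 6))$root
  b^2
}

# exhaustive midpoint split search maximizing the log-rank statistic
.best_split <- function(X, tm, ev, min_leaf) {
  ord <- order(tm)
  t_s <- tm[ord]; e_s <- ev[ord]
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ux <- sort(unique(x))
    if (length(ux) < 2) next
    mids <- (ux[-1] + ux[-length(ux)]) / 2
    for (thr in mids) {
      nl <- sum(x <= thr)
      if (nl < min_leaf || (length(x) - nl) < min_leaf) next
      st <- .logrank2_stat(t_s, e_s, x[ord] > thr)[["stat"]]
      if (is.null(best) || st > best$stat + 1e-12) {
        best <- list(feature = j, threshold = thr, stat = st)
      }
    }
  }
  best
}

# leaf HRs vs the best-survival leaf (lowest Nelson-Aalen-style event rate)
.leaf_hazard_ratios <- function(tm, ev, leaf_of, leaves) {
  rate <- vapply(leaves, function(l) {
    i <- leaf_of == l
    sum(ev[i]) / sum(tm[i])
  }, 0)
  ref <- leaves[which.min(rate)]
  vapply(leaves, function(l) {
    if (l == ref) return(1)
    i <- leaf_of %in% c(ref, l)
    fit <- tryCatch(suppressWarnings(
      cox_univariable(tm[i], ev[i], as.numeric(leaf_of[i] == l))),
      error = function(e) NULL)
    if (is.null(fit)) rate[match(l, leaves)] / rate[match(ref, leaves)] else fit$hr
  }, 0)
}

# Agglomerative merging of similar-hazard leaves: repeatedly pool the
# hazard-adjacent pair of groups with the smallest HR ratio, re-estimating
# pooled group hazards after each merge, until the closest pair's ratio
# reaches the tolerance. Pooled re-estimation keeps single-leaf noise from
# blocking merges the point estimates alone would miss.
.merge_similar_leaves <- function(tm, ev, leaf_of, hr, tolerance) {
  leaves <- as.integer(names(hr))
  groups <- as.list(leaves)            # each group = set of leaf ids
  group_rate <- function(g) {
    i <- leaf_of %in% g
    sum(ev[i]) / sum(tm[i])
  }
  repeat {
    if (length(groups) <= 1) break
    rates <- vapply(groups, group_rate, 0)
    ord <- order(rates)
    groups <- groups[ord]; rates <- rates[ord]
    # pooled HR of each adjacent pair via Cox on the two pooled groups
    ratios <- vapply(seq_len(length(groups) - 1), function(k) {
      i <- leaf_of %in% c(groups[[k]], groups[[k + 1]])
      upper <- as.numeric(leaf_of[i] %in% groups[[k + 1]])
      fit <- tryCatch(suppressWarnings(cox_univariable(tm[i], ev[i], upper)),
                      error = function(e) NULL)
      if (is.null(fit)) rates[k + 1] / max(rates[k], 1e-12) else fit$hr
    }, 0)
    k <- which.min(ratios)
    if (ratios[k] >= tolerance) break
    groups[[k]] <- c(groups[[k]], groups[[k + 1]])
    groups <- groups[-(k + 1)]
  }
  rates <- vapply(groups, group_rate, 0)
  groups <- groups[order(rates)]
  group_idx <- integer(length(leaves))
  for (g in seq_along(groups))
    group_idx[match(groups[[g]], leaves)] <- g
  list(leaf = leaves, group = group_idx)
}

#' Apply a fitted RPA tree
#'
#' Deterministic routing: left branch when value <= threshold. When the
#' smoking-signature column is absent (targeted-panel cohorts), a clinical
#' smoking history of 10 or more pack-years substitutes for a present
#' signature (routed to the above-threshold side), fewer than 10 to the
#' absent side.
#'
#' @param tree an `rpa_tree`.
#' @param patients cohort rows.
#' @param smoking_proxy allow the pack-year proxy (default TRUE).
#' @return Factor of risk-group labels, ordered `low` -> `high`.
#' @export
apply_rpa <- function(tree, patients, smoking_proxy = TRUE) {
  nodes <- tree$nodes
  feats <- tree$features_used
  cohort <- patients
  sf <- tree$smoking_feature
  if (!is.na(sf) && sf %in% feats && is.null(cohort[[sf]]) && smoking_proxy) {
    if (is.null(cohort$smoking_pack_years))
      .icb_stop("apply_rpa: smoking signature absent and no pack-year history for proxy",
                "icb_validation_error")
    thr_sf <- nodes$threshold[!is.na(nodes$feature) & nodes$feature == sf]
    anchor <- if (length(thr_sf)) max(thr_sf) else 0
    cohort[[sf]] <- ifelse(cohort$smoking_pack_years >= 10, anchor + 1e-9, anchor)
    message("apply_rpa: smoking signature imputed from pack-year history (>= 10 = present)")
  }
  miss <- setdiff(feats, names(cohort))
  if (length(miss))
    .icb_stop(paste0("apply_rpa: missing feature column(s): ", paste(miss, collapse = ", ")),
              "icb_validation_error")
  route <- function(i) {
    id <- 1L
    repeat {
      row <- nodes[nodes$id == id, ]
      if (row$is_leaf) return(tree$leaf_group[[as.character(id)]])
      v <- cohort[[row$feature]][i]
      if (is.na(v)) .icb_stop("apply_rpa: missing value during routing", "icb_validation_error")
      id <- if (v <= row$threshold) row$left else row$right
    }
  }
  factor(vapply(seq_len(nrow(cohort)), route, ""), levels = tree$group_levels)
}

#' Serialize / reload an RPA tree as human-readable JSON
#' @param tree an `rpa_tree`.
#' @param path JSON file path.
#' @export
write_rpa <- function(tree, path) {
  obj <- list(nodes = tree$nodes,
              leaf_group = as.list(tree$leaf_group),
              group_levels = tree$group_levels,
              features_used = tree$features_used,
              leaf_hr = as.list(tree$leaf_hr),
              endpoint = tree$endpoint,
              smoking_feature = tree$smoking_feature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_rpa
#' @export
read_rpa <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  for (col in c("parent", "left", "right", "id", "depth", "n", "events"))
    nodes[[col]] <- as.integer(nodes[[col]])
  structure(list(nodes = nodes,
                 leaf_group = unlist(obj$leaf_group),
                 group_levels = obj$group_levels,
                 features_used = obj$features_used,
                 leaf_hr = unlist(obj$leaf_hr),
                 endpoint = obj$endpoint,
                 smoking_feature = obj$smoking_feature),
            class = "rpa_tree")
}

#' @export
print.rpa_tree <- function(x, ...) {
  cat(sprintf("RPA survival tree (%s), %d leaves -> %d risk groups\n",
              x$endpoint, sum(x$nodes$is_leaf), length(x$group_levels)))
  sp <- x$nodes[!x$nodes$is_leaf, ]
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  node %d (depth %d): %s <= %.4g ? left %d : right %d\n",
                sp$id[i], sp$depth[i], sp$feature[i], sp$threshold[i],
                sp$left[i], sp$right[i]))
  lf <- x$nodes[x$nodes$is_leaf, ]
  for (i in seq_len(nrow(lf)))
    cat(sprintf("  leaf %d: n=%d, events=%d, HR=%.3g, group=%s\n",
                lf$id[i], lf$n[i], lf$events[i],
                x$leaf_hr[[as.character(lf$id[i])]],
                x$leaf_group[[as.character(lf$id[i])]]))
  invisible(x)
}
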