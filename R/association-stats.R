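# Univariate association of model outcomes with FC features across subjects:
# permutation-tested Pearson correlations, BH-FDR control, RSN summaries,
# and covariate group comparisons.

#' Build a feature table
#'
#' Either the Fisher-z sFC of every region pair (row-major strict upper
#' triangle, so the edge indexing is reproducible: (1,2), (1,3), ...,
#' (N-1,N)) or the per-region TC, stacked across subjects.
#'
#' @param metric_sets list of `fc_metric_set` objects, one per subject.
#' @param kind `"edge_sfc"` or `"node_tc"`.
#' @return matrix subjects x features with descriptive column names.
#' @export
feature_table <- function(metric_sets, kind = c("edge_sfc", "node_tc")) {
  kind <- match.arg(kind)
  rows <- lapply(metric_sets, function(m) {
    if (kind == "edge_sfc") upper_tri_vec(m$sfc) else m$tc
  })
  tab <- do.call(rbind, rows)
  if (kind == "edge_sfc") {
    n <- length(metric_sets[[1]]$tc)
    pairs <- upper_tri_pairs(n)
    colnames(tab) <- sprintf("e%d_%d", pairs[, 1], pairs[, 2])
  } else {
    colnames(tab) <- sprintf("n%d", seq_len(ncol(tab)))
  }
  attr(tab, "kind") <- kind
  tab
}

#' Per-feature Pearson correlation with a subject-level outcome
#'
#' @param outcome numeric subject vector (an optimal parameter or fit).
#' @param features subjects x features matrix.
#' @return named vector of correlations; constant feature columns yield `NA`
#'   with a warning.
#' @export
correlate_features <- function(outcome, features) {
  if (length(outcome) != nrow(features)) {
    stop_dmf("outcome length does not match feature rows",
             class = "dmfconn_format_error")
  }
  if (length(outcome) < 3) {
    stop_dmf("need at least 3 subjects", class = "dmfconn_value_error")
  }
  if (sd(outcome) == 0) {
    stop_dmf("outcome has zero variance", class = "dmfconn_value_error")
  }
  sds <- apply(features, 2, sd)
  r <- rep(NA_real_, ncol(features))
  names(r) <- colnames(features)
  ok <- sds > 0
  if (any(!ok)) warning("constant feature columns; r reported as NA")
  r[ok] <- as.numeric(cor(outcome, features[, ok, drop = FALSE]))
  r
}

#' Permutation p-values for feature correlations
#'
#' Two-sided p-values from permuting the outcome over subjects (one shared
#' permutation stream across all features) and recomputing every
#' correlation. The add-one estimator
#' `p = (1 + #(|r_perm| >= |r_obs|)) / (n_perm + 1)` never returns exactly 0.
#'
#' @param outcome numeric subject vector.
#' @param features subjects x features matrix.
#' @param n_perm number of permutations (full-scale analyses use 100000).
#' @param seed integer seed; identical seeds give identical p-vectors.
#' @return named vector of p-values.
#' @export
permutation_pvalues <- function(outcome, features, n_perm = 100000L,
                                seed = 1L) {
  stopifnot(n_perm >= 1)
  r_obs <- correlate_features(outcome, features)
  n <- length(outcome)
  fz <- scale(features)
  fz[, apply(features, 2, sd) == 0] <- 0
  oz <- as.numeric(scale(outcome))
  set.seed(seed)
  count <- numeric(ncol(features))
  thresh <- abs(r_obs) - 1e-12
  done <- 0L
  chunk <- 1000L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    P <- vapply(seq_len(m), function(i) oz[sample.int(n)], numeric(n))
    r_perm <- abs(crossprod(fz, P)) / (n - 1)   # features x m
    count <- count + rowSums(r_perm >= thresh)
    done <- done + m
  }
  p <- (1 + count) / (n_perm + 1)
  p[is.na(r_obs)] <- NA_real_
  names(p) <- names(r_obs)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]` (`NA` passed through).
#' @return vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_dmf("p-values out of [0, 1]", class = "dmfconn_value_error")
  }
  p.adjust(p, method = "BH")
}

#' Summarize significant values over resting-state networks
#'
#' Values whose q-value is at or above `alpha` are set to 0, then averaged
#' within each network (node values) or each unordered network pair (edge
#' values).
#'
#' @param values per-edge (upper-triangle order) or per-node vector.
#' @param q matching q-values.
#' @param parc a [parcellation()].
#' @param alpha significance threshold (default 0.05).
#' @return for nodes, a named per-network vector; for edges, a symmetric
#'   network x network matrix.
#' @export
summarize_by_rsn <- function(values, q, parc, alpha = 0.05) {
  stopifnot(length(values) == length(q))
  nets <- sort(unique(parc$network))
  v <- ifelse(!is.na(q) & q < alpha, values, 0)
  n <- length(parc$network)
  if (length(values) == n) {
    out <- vapply(nets, function(g) mean(v[parc$network == g]), numeric(1))
    return(out)
  }
  pairs <- upper_tri_pairs(n)
  if (length(values) != nrow(pairs)) {
    stop_dmf("values length matches neither nodes nor edges",
             class = "dmfconn_value_error")
  }
  net_i <- parc$network[pairs[, 1]]
  net_j <- parc$network[pairs[, 2]]
  out <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  for (a in seq_along(nets)) {
    for (b in seq(a, length(nets))) {
      sel <- (net_i == nets[a] & net_j == nets[b]) |
        (net_i == nets[b] & net_j == nets[a])
      m <- if (any(sel)) mean(v[sel]) else 0
      out[a, b] <- m
      out[b, a] <- m
    }
  }
  out
}

#' Group comparison of subject outcomes
#'
#' Two-sided Welch t-test (unequal variances) per outcome per pairwise level
#' contrast of the grouping factor.
#'
#' @param outcomes data.frame of subject-level outcomes (numeric columns).
#' @param grouping factor/character vector of group labels per subject.
#' @return data.frame with columns `outcome`, `group1`, `group2`,
#'   `estimate1`, `estimate2`, `t`, `p`.
#' @export
group_compare <- function(outcomes, grouping) {
  grouping <- as.factor(grouping)
  if (any(table(grouping) < 2)) {
    stop_dmf("every group needs at least 2 members",
             class = "dmfconn_value_error")
  }
  levs <- levels(grouping)
  contrasts <- combn(levs, 2, simplify = FALSE)
  rows <- list()
  for (col in names(outcomes)) {
    y <- outcomes[[col]]
    for (ct in contrasts) {
      a <- y[grouping == ct[1]]
      b <- y[grouping == ct[2]]
      tt <- t.test(a, b, var.equal = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = col, group1 = ct[1], group2 = ct[2],
        estimate1 = mean(a), estimate2 = mean(b),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  do.call(rbind, rows)
}
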