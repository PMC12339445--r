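# Static and dynamic functional-connectivity metrics.
#
# The dynamic pipeline follows the tapered sliding-window construction:
# windowed weighted Pearson correlations -> per-edge variance over windows
# (FCV); binarized top-density dynamic graph -> per-node temporal correlation
# (TC); per-window community detection with label matching -> per-pair
# co-switch counts (node cohesion, NC).

#' Sliding-window specification
#'
#' @param window_length window length (s); ~60 s at full scale.
#' @param step sliding step (s); 2 s.
#' @param taper_sigma Gaussian taper width (s); 6 s. Window weights are a
#'   rectangle convolved with a Gaussian of this width, normalized to sum 1.
#' @param tr sampling interval of the series (s).
#' @return an object of class `sliding_window_spec`.
#' @export
sliding_window_spec <- function(window_length = 60, step = 2, taper_sigma = 6,
                                tr = 0.72) {
  stopifnot(window_length > step, step > 0, taper_sigma > 0, tr > 0)
  structure(list(window_length = window_length, step = step,
                 taper_sigma = taper_sigma, tr = tr),
            class = "sliding_window_spec")
}

#' Static functional connectivity
#'
#' Pearson correlation between the time courses of each pair of regions;
#' optionally Fisher z-transformed (`atanh`) off the diagonal, with `|r| = 1`
#' clipped at `atanh(1 - 1e-7)`. The diagonal is set to 0.
#'
#' @param series a [bold_series()] or a T x N numeric matrix.
#' @param fisher apply Fisher's z-transformation (default `TRUE`).
#' @return N x N symmetric matrix with zero diagonal.
#' @export
static_fc <- function(series, fisher = TRUE) {
  x <- if (inherits(series, "bold_series")) series$data else as.matrix(series)
  if (nrow(x) < 3) stop_dmf("need T >= 3", class = "dmfconn_value_error")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop_dmf("zero-variance regions: %s",
             paste(which(sds == 0), collapse = ", "),
             class = "dmfconn_value_error")
  }
  r <- cor(x)
  if (fisher) {
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    r <- atanh(r)
  }
  diag(r) <- 0
  r
}

# tapered window weights: rectangle of L samples convolved with a Gaussian
# of taper_sigma seconds, evaluated within the window, normalized to sum 1
window_weights <- function(L, taper_sigma, tr) {
  pos <- seq_len(L)
  w <- vapply(pos, function(t) {
    sum(exp(-((t - pos) * tr)^2 / (2 * taper_sigma^2)))
  }, numeric(1))
  w / sum(w)
}

weighted_cor_matrix <- function(x, w) {
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  cov <- crossprod(xc * w, xc)
  s <- sqrt(diag(cov))
  r <- cov / tcrossprod(s)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Sliding-window dynamic FC
#'
#' Weighted Pearson correlation inside tapered windows. The window count is
#' `W = floor((T*tr - window_length)/step) + 1`; window `k` (0-based) starts
#' at sample `floor(k*step/tr) + 1` and spans `floor(window_length/tr)`
#' samples.
#'
#' @param series a [bold_series()] or T x N matrix (then `tr` is taken from
#'   `spec`).
#' @param spec a [sliding_window_spec()].
#' @return W x N x N array of windowed correlation matrices.
#' @export
sliding_window_fc <- function(series, spec = sliding_window_spec()) {
  x <- if (inherits(series, "bold_series")) series$data else as.matrix(series)
  tr <- if (inherits(series, "bold_series")) series$tr else spec$tr
  T_ <- nrow(x)
  n <- ncol(x)
  total <- T_ * tr
  if (total < spec$window_length) {
    stop_dmf("series (%.1f s) shorter than one window (%.1f s)", total,
             spec$window_length, class = "dmfconn_value_error")
  }
  W <- floor((total - spec$window_length) / spec$step) + 1
  L <- floor(spec$window_length / tr)
  wts <- window_weights(L, spec$taper_sigma, tr)
  out <- array(NA_real_, c(W, n, n))
  for (k in seq_len(W) - 1L) {
    start <- floor(k * spec$step / tr) + 1L
    seg <- x[start:(start + L - 1L), , drop = FALSE]
    out[k + 1L, , ] <- weighted_cor_matrix(seg, wts)
  }
  out
}

#' Variance of windowed FC (FCV)
#'
#' Per-pair sample variance (denominator `W - 1`) of the windowed
#' correlations across time.
#'
#' @param window_fc W x N x N array from [sliding_window_fc()].
#' @return N x N symmetric non-negative matrix.
#' @export
fc_variance <- function(window_fc) {
  if (dim(window_fc)[1] < 2) {
    stop_dmf("need at least 2 windows", class = "dmfconn_value_error")
  }
  apply(window_fc, c(2, 3), var)
}

#' Binarize windowed FC into a dynamic graph
#'
#' Per window, keeps the top `floor(density * N*(N-1)/2)` upper-triangle
#' values as edges. Ties are broken by value, then by `(i, j)` lexicographic
#' order, so the construction is deterministic.
#'
#' @param window_fc W x N x N array.
#' @param density target edge fraction in (0, 1); default 0.10.
#' @return an object of class `dynamic_graph`: list with `adjacency`
#'   (W x N x N binary array) and `density`.
#' @export
binarize_dynamic <- function(window_fc, density = 0.10) {
  stopifnot(density > 0, density < 1)
  W <- dim(window_fc)[1]
  n <- dim(window_fc)[2]
  pairs <- upper_tri_pairs(n)
  m <- floor(density * nrow(pairs))
  adj <- array(0L, c(W, n, n))
  for (w in seq_len(W)) {
    vals <- window_fc[w, , ][pairs]
    ord <- order(-vals, pairs[, 1], pairs[, 2])
    keep <- ord[seq_len(m)]
    for (k in keep) {
      adj[w, pairs[k, 1], pairs[k, 2]] <- 1L
      adj[w, pairs[k, 2], pairs[k, 1]] <- 1L
    }
  }
  structure(list(adjacency = adj, density = density), class = "dynamic_graph")
}

#' Serialize a dynamic graph as a windowed edge list
#'
#' One CSV row per edge per window (`window, i, j` with `i < j`), the
#' interchange format for binarized dynamic graphs.
#'
#' @param g a `dynamic_graph`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_dynamic_graph <- function(g, path) {
  W <- dim(g$adjacency)[1]
  n <- dim(g$adjacency)[2]
  pairs <- upper_tri_pairs(n)
  rows <- do.call(rbind, lapply(seq_len(W), function(w) {
    on <- g$adjacency[w, , ][pairs] == 1
    if (!any(on)) return(NULL)
    data.frame(window = w, i = pairs[on, 1], j = pairs[on, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a windowed edge list back into a dynamic graph
#'
#' @param path CSV written by [write_dynamic_graph()].
#' @param n_regions region count of the graph.
#' @param n_windows window count (defaults to the largest window index).
#' @param density the density recorded on the returned object.
#' @return a `dynamic_graph`.
#' @export
read_dynamic_graph <- function(path, n_regions, n_windows = NULL,
                               density = NA_real_) {
  df <- read.csv(path)
  if (is.null(n_windows)) n_windows <- max(df$window)
  adj <- array(0L, c(n_windows, n_regions, n_regions))
  for (k in seq_len(nrow(df))) {
    adj[df$window[k], df$i[k], df$j[k]] <- 1L
    adj[df$window[k], df$j[k], df$i[k]] <- 1L
  }
  structure(list(adjacency = adj, density = density),
            class = "dynamic_graph")
}

#' Temporal correlation (TC)
#'
#' Per-node consistency of the binarized neighborhood between consecutive
#' windows:
#' `C_i = 1/(W-1) * sum_t sum_j A_ij(t)A_ij(t+1) /
#'        sqrt(sum_j A_ij(t) * sum_j A_ij(t+1))`,
#' with a term counted as 0 whenever node `i` is isolated at `t` or `t+1`.
#'
#' @param g a `dynamic_graph` from [binarize_dynamic()].
#' @return length-N vector in `[0, 1]`.
#' @export
temporal_correlation <- function(g) {
  adj <- g$adjacency
  W <- dim(adj)[1]
  n <- dim(adj)[2]
  if (W < 2) stop_dmf("need at least 2 windows", class = "dmfconn_value_error")
  acc <- numeric(n)
  for (t in seq_len(W - 1)) {
    a <- adj[t, , ]
    b <- adj[t + 1, , ]
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a) * rowSums(b))
    term <- ifelse(den > 0, num / den, 0)
    acc <- acc + term
  }
  acc / (W - 1)
}

# greedy Jaccard matching of community labels across consecutive windows;
# ties resolved toward the smaller previous label, unmatched communities get
# fresh labels
match_labels <- function(prev, cur) {
  out <- integer(length(cur))
  prev_ids <- sort(unique(prev))
  cur_ids <- sort(unique(cur))
  jac <- matrix(0, length(cur_ids), length(prev_ids),
                dimnames = list(cur_ids, prev_ids))
  for (a in seq_along(cur_ids)) {
    A <- which(cur == cur_ids[a])
    for (b in seq_along(prev_ids)) {
      B <- which(prev == prev_ids[b])
      jac[a, b] <- length(intersect(A, B)) / length(union(A, B))
    }
  }
  taken_prev <- logical(length(prev_ids))
  assigned <- rep(NA_integer_, length(cur_ids))
  repeat {
    jj <- jac
    jj[, taken_prev] <- -1
    jj[!is.na(assigned), ] <- -1
    if (all(jj < 0) || max(jj) <= 0) break
    best <- which(jj == max(jj), arr.ind = TRUE)
    # ties: smallest previous label, then smallest current community
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    assigned[best[1]] <- prev_ids[best[2]]
    taken_prev[best[2]] <- TRUE
  }
  next_label <- max(c(prev_ids, 0L)) + 1L
  for (a in seq_along(cur_ids)) {
    if (is.na(assigned[a])) {
      assigned[a] <- next_label
      next_label <- next_label + 1L
    }
  }
  for (a in seq_along(cur_ids)) out[cur == cur_ids[a]] <- assigned[a]
  out
}

#' Detect communities in a dynamic graph
#'
#' Seeded per-window modularity optimization (Louvain) followed by label
#' matching across consecutive windows via greedy maximal Jaccard overlap
#' (ties toward the smaller previous label). Isolated nodes form singleton
#' communities. Deterministic given the seed.
#'
#' @param g a `dynamic_graph`.
#' @param seed integer seed.
#' @return an object of class `community_sequence`: list with `labels`
#'   (W x N integer matrix).
#' @export
detect_communities <- function(g, seed = 1L) {
  adj <- g$adjacency
  W <- dim(adj)[1]
  n <- dim(adj)[2]
  labels <- matrix(NA_integer_, W, n)
  for (w in seq_len(W)) {
    set.seed(derive_seed(seed, "louvain", w))
    gr <- igraph::graph_from_adjacency_matrix(adj[w, , ], mode = "undirected")
    memb <- igraph::membership(igraph::cluster_louvain(gr))
    raw <- as.integer(memb)
    labels[w, ] <- if (w == 1) raw else match_labels(labels[w - 1, ], raw)
  }
  structure(list(labels = labels), class = "community_sequence")
}

#' Node cohesion (NC)
#'
#' Number of times each pair of regions switches communities together:
#' consecutive window pairs where both nodes share a label before and after
#' and the label changed.
#'
#' @param cs a `community_sequence` from [detect_communities()].
#' @return N x N symmetric integer matrix with zero diagonal.
#' @export
node_cohesion <- function(cs) {
  labels <- cs$labels
  W <- nrow(labels)
  n <- ncol(labels)
  if (W < 2) stop_dmf("need at least 2 windows", class = "dmfconn_value_error")
  nc <- matrix(0L, n, n)
  for (t in seq_len(W - 1)) {
    l1 <- labels[t, ]
    l2 <- labels[t + 1, ]
    switched <- l1 != l2
    same1 <- outer(l1, l1, `==`)
    same2 <- outer(l2, l2, `==`)
    co <- same1 & same2 & outer(switched, switched, `&`)
    nc <- nc + co
  }
  diag(nc) <- 0L
  nc
}

#' Global efficiency of a weighted matrix
#'
#' Positive entries form edges with distance `1/weight`; efficiency is the
#' mean over ordered pairs of the inverse shortest-path distance, with
#' `1/Inf = 0` for disconnected pairs.
#'
#' @param fc N x N symmetric matrix (e.g., a simulated sFC).
#' @return scalar efficiency.
#' @export
global_efficiency <- function(fc) {
  n <- nrow(fc)
  stopifnot(n >= 2)
  w <- fc
  w[w < 0] <- 0
  diag(w) <- 0
  gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  d <- igraph::distances(gr, weights = 1 / igraph::E(gr)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Per-node graph metrics of a weighted matrix
#'
#' Degree (weighted strength), normalized betweenness centrality, and
#' closeness centrality on distances `1/weight`. Negative entries (possible
#' for FC input) are dropped.
#'
#' @param matrix N x N symmetric matrix.
#' @param kind one of `"weights"`, `"lengths"`, `"fc"` (label only).
#' @return data.frame with columns `degree`, `betweenness`, `closeness`.
#' @export
node_graph_metrics <- function(matrix, kind = c("weights", "lengths", "fc")) {
  kind <- match.arg(kind)
  w <- matrix
  w[w < 0] <- 0
  diag(w) <- 0
  gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  dist_w <- 1 / igraph::E(gr)$weight
  data.frame(
    degree = unname(rowSums(w)),
    betweenness = unname(igraph::betweenness(gr, weights = dist_w,
                                             normalized = TRUE)),
    closeness = unname(igraph::closeness(gr, weights = dist_w,
                                         normalized = TRUE)))
}

#' Full FC metric set of one series
#'
#' Computes the four fitting targets of the pipeline from one BOLD series:
#' Fisher-z static FC (`sfc`), per-edge FC variance (`fcv`), per-node
#' temporal correlation (`tc`), and node cohesion (`nc`).
#'
#' @param series a [bold_series()].
#' @param spec a [sliding_window_spec()]; its `tr` is overridden by the
#'   series'.
#' @param density binarization density for the dynamic graph.
#' @param seed seed for community detection.
#' @return an object of class `fc_metric_set` with elements `sfc`, `fcv`,
#'   `tc`, `nc`.
#' @export
fc_metric_set <- function(series, spec = sliding_window_spec(),
                          density = 0.10, seed = 1L) {
  stopifnot(inherits(series, "bold_series"))
  wfc <- sliding_window_fc(series, spec)
  g <- binarize_dynamic(wfc, density)
  cs <- detect_communities(g, seed)
  structure(list(sfc = static_fc(series, fisher = TRUE),
                 fcv = fc_variance(wfc),
                 tc = temporal_correlation(g),
                 nc = node_cohesion(cs)),
            class = "fc_metric_set")
}

#' Element-wise average of FC metric sets
#'
#' The two-session averaging contract: metrics computed per session are
#' combined by the element-wise mean of each matrix or vector.
#'
#' @param sets non-empty list of `fc_metric_set` objects.
#' @return an `fc_metric_set`.
#' @export
average_metric_sets <- function(sets) {
  if (length(sets) == 0) stop_dmf("empty list", class = "dmfconn_value_error")
  avg <- function(field) {
    Reduce(`+`, lapply(sets, `[[`, field)) / length(sets)
  }
  structure(list(sfc = avg("sfc"), fcv = avg("fcv"), tc = avg("tc"),
                 nc = avg("nc")),
            class = "fc_metric_set")
}
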