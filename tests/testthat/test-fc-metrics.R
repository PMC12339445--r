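# Brute-force loop oracles for every dynamic-FC metric, plus the window
# geometry and binarization-density contracts.

test_that("static FC handles perfect correlation, decorrelation and Fisher z", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4), 200, 4)
  x[, 2] <- x[, 1]   # perfect copy
  fc <- static_fc(x, fisher = TRUE)
  expect_equal(fc[1, 2], atanh(1 - 1e-7))
  expect_true(all(diag(fc) == 0))
  # closed-form arctanh: r = 0.5 -> z = 0.5493
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  y <- matrix(rnorm(20), 10, 2)
  y2 <- y %*% chol(r)
  fc_raw <- static_fc(y2, fisher = FALSE)
  fc_z <- static_fc(y2, fisher = TRUE)
  expect_equal(fc_z[1, 2], atanh(fc_raw[1, 2]))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # long independent white noise decorrelates
  set.seed(2)
  big <- matrix(rnorm(10000 * 3), 10000, 3)
  expect_lt(max(abs(upper_tri_vec(static_fc(big, fisher = FALSE)))), 0.1)
  # zero-variance region flagged with its index
  bad <- cbind(rnorm(50), 1)
  expect_error(static_fc(bad), "2", class = "dmfconn_value_error")
})

test_that("window count follows the time-based formula", {
  # T*tr = 864 s, window 60 s, step 2 s -> floor((864-60)/2)+1 = 403
  spec <- sliding_window_spec(60, 2, 6, 0.72)
  x <- matrix(rnorm(1200 * 3), 1200, 3)
  wfc <- sliding_window_fc(bold_series(x, 0.72), spec)
  expect_equal(dim(wfc)[1], 403)
  # series shorter than one window errors
  expect_error(sliding_window_fc(bold_series(x[1:50, ], 0.72), spec),
               class = "dmfconn_value_error")
})

test_that("tapered windowed correlation has the right limits", {
  set.seed(3)
  x <- matrix(rnorm(400 * 3), 400, 3)
  # uniform-weights limit: huge taper reproduces unweighted Pearson
  spec_u <- sliding_window_spec(60, 30, 1e6, 1)
  wfc <- sliding_window_fc(bold_series(x, 1), spec_u)
  seg <- x[1:60, ]
  expect_equal(wfc[1, , ], unname(cor(seg)) - diag(0, 3), tolerance = 1e-10)
  # stationary series: windowed FC approaches static FC as windows grow
  set.seed(4)
  base <- rnorm(2000)
  y <- cbind(base + rnorm(2000, 0, 0.8), base + rnorm(2000, 0, 0.8),
             rnorm(2000))
  spec_big <- sliding_window_spec(1500, 100, 20, 1)
  wbig <- sliding_window_fc(bold_series(y, 1), spec_big)
  sfc <- static_fc(y, fisher = FALSE)
  dev <- mean(abs(wbig[1, , ][upper.tri(sfc)] - sfc[upper.tri(sfc)]))
  expect_lt(dev, 0.06)
})

test_that("FC variance matches hand and loop oracles", {
  # two windows with r = 0.2 and 0.6 -> sample variance 0.08
  wfc <- array(0, c(2, 2, 2))
  wfc[1, , ] <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  wfc[2, , ] <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(fc_variance(wfc)[1, 2], 0.08)
  # identical windows -> all zero
  same <- array(rep(wfc[1, , ], each = 3), c(3, 2, 2))
  expect_true(all(fc_variance(same) == 0))
  # random 5-window input equals the brute-force loop
  rnd <- random_window_fc(5, 4, seed = 9)
  got <- fc_variance(rnd)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(got[i, j], var(rnd[, i, j]))
  }
  expect_error(fc_variance(rnd[1, , , drop = FALSE]),
               class = "dmfconn_value_error")
})

test_that("binarization keeps exactly the target edge count with fixed ties", {
  # N=5, density 0.1 -> exactly 1 edge per window
  rnd <- random_window_fc(4, 5, seed = 2)
  g <- binarize_dynamic(rnd, 0.1)
  for (w in 1:4) {
    expect_equal(sum(g$adjacency[w, , ][upper.tri(diag(5))]), 1)
    expect_identical(g$adjacency[w, , ], t(g$adjacency[w, , ]))
  }
  # edge set equals the sort-and-threshold oracle
  rnd2 <- random_window_fc(3, 6, seed = 5)
  g2 <- binarize_dynamic(rnd2, 0.3)
  m <- floor(0.3 * 15)
  for (w in 1:3) {
    vals <- rnd2[w, , ][upper.tri(diag(6))]
    thresh <- sort(vals, decreasing = TRUE)[m]
    kept <- which(g2$adjacency[w, , ][upper.tri(diag(6))] == 1)
    expect_equal(length(kept), m)
    expect_true(all(vals[kept] >= thresh))
  }
  # all-equal values: lexicographically first pairs win
  tie <- array(0.5, c(1, 4, 4))
  gt <- binarize_dynamic(tie, 0.34)   # floor(0.34*6) = 2 edges
  expect_equal(gt$adjacency[1, 1, 2], 1L)
  expect_equal(gt$adjacency[1, 1, 3], 1L)
  expect_equal(sum(gt$adjacency[1, , ]) / 2, 2)
})

test_that("temporal correlation matches its definition and bounds", {
  # time-constant graph with no isolated nodes -> TC = 1
  adj <- array(0L, c(3, 4, 4))
  ring <- matrix(0L, 4, 4)
  ring[1, 2] <- ring[2, 3] <- ring[3, 4] <- ring[4, 1] <- 1L
  ring <- ring + t(ring)
  for (w in 1:3) adj[w, , ] <- ring
  g <- structure(list(adjacency = adj, density = 0.5),
                 class = "dynamic_graph")
  expect_equal(temporal_correlation(g), rep(1, 4))
  # disjoint consecutive edge sets -> TC = 0
  adj2 <- array(0L, c(2, 4, 4))
  adj2[1, 1, 2] <- adj2[1, 2, 1] <- 1L
  adj2[2, 3, 4] <- adj2[2, 4, 3] <- 1L
  g2 <- structure(list(adjacency = adj2, density = 0.5),
                  class = "dynamic_graph")
  expect_equal(temporal_correlation(g2), rep(0, 4))
  # random graph equals the per-term loop oracle
  set.seed(6)
  W <- 3; n <- 4
  adj3 <- array(0L, c(W, n, n))
  for (w in 1:W) {
    a <- matrix(rbinom(n * n, 1, 0.4), n, n)
    a[lower.tri(a, diag = TRUE)] <- 0
    adj3[w, , ] <- a + t(a)
  }
  g3 <- structure(list(adjacency = adj3, density = 0.4),
                  class = "dynamic_graph")
  got <- temporal_correlation(g3)
  for (i in 1:n) {
    acc <- 0
    for (t in 1:(W - 1)) {
      num <- 0; d1 <- 0; d2 <- 0
      for (j in 1:n) {
        num <- num + adj3[t, i, j] * adj3[t + 1, i, j]
        d1 <- d1 + adj3[t, i, j]
        d2 <- d2 + adj3[t + 1, i, j]
      }
      if (d1 > 0 && d2 > 0) acc <- acc + num / sqrt(d1 * d2)
    }
    expect_equal(got[i], acc / (W - 1))
  }
  expect_true(all(got >= 0 & got <= 1))
})

test_that("community detection is deterministic and tracks stable cliques", {
  # two disconnected cliques persisting -> two constant labels
  n <- 8
  cl <- matrix(0L, n, n)
  cl[1:4, 1:4] <- 1L
  cl[5:8, 5:8] <- 1L
  diag(cl) <- 0L
  adj <- array(0L, c(4, n, n))
  for (w in 1:4) adj[w, , ] <- cl
  g <- structure(list(adjacency = adj, density = 0.4),
                 class = "dynamic_graph")
  cs <- detect_communities(g, seed = 3)
  for (w in 1:4) {
    expect_equal(length(unique(cs$labels[w, ])), 2)
    expect_identical(cs$labels[w, ], cs$labels[1, ])
  }
  # determinism
  cs2 <- detect_communities(g, seed = 3)
  expect_identical(cs$labels, cs2$labels)
  # half-swap keeps the majority label (exhaustive 2-community matching)
  adj_sw <- array(0L, c(2, n, n))
  adj_sw[1, , ] <- cl
  cl2 <- matrix(0L, n, n)
  cl2[c(1, 2, 3, 5), c(1, 2, 3, 5)] <- 1L   # node 5 joins community 1
  cl2[c(4, 6, 7, 8), c(4, 6, 7, 8)] <- 1L   # node 4 joins community 2
  diag(cl2) <- 0L
  adj_sw[2, , ] <- cl2
  gsw <- structure(list(adjacency = adj_sw, density = 0.4),
                   class = "dynamic_graph")
  css <- detect_communities(gsw, seed = 1)
  # majority of {1,2,3} keeps its window-1 label; majority of {6,7,8} too
  expect_equal(css$labels[2, 1], css$labels[1, 1])
  expect_equal(css$labels[2, 6], css$labels[1, 6])
  expect_equal(css$labels[2, 5], css$labels[2, 1])
  expect_equal(css$labels[2, 4], css$labels[2, 6])
})

test_that("node cohesion counts simultaneous community switches", {
  # constant partitions -> all zero
  labels <- matrix(rep(c(1L, 1L, 2L, 2L), 3), 3, 4, byrow = TRUE)
  cs <- structure(list(labels = labels), class = "community_sequence")
  expect_true(all(node_cohesion(cs) == 0))
  # two nodes moving together once -> nc = 1 for the pair
  lab2 <- rbind(c(1L, 1L, 2L, 2L), c(2L, 2L, 2L, 2L))
  cs2 <- structure(list(labels = lab2), class = "community_sequence")
  nc <- node_cohesion(cs2)
  expect_equal(nc[1, 2], 1)
  expect_equal(nc[3, 4], 0)   # they stayed put
  expect_equal(nc[1, 3], 0)
  # random label sequences equal the triple-loop enumeration
  set.seed(8)
  W <- 6; n <- 5
  lab3 <- matrix(sample(1:3, W * n, replace = TRUE), W, n)
  cs3 <- structure(list(labels = lab3), class = "community_sequence")
  got <- node_cohesion(cs3)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    cnt <- 0
    for (t in 1:(W - 1)) {
      if (lab3[t, i] == lab3[t, j] && lab3[t + 1, i] == lab3[t + 1, j] &&
          lab3[t, i] != lab3[t + 1, i]) {
        cnt <- cnt + 1
      }
    }
    expect_equal(got[i, j], cnt)
  }
  expect_true(all(got <= W - 1))
})

test_that("global efficiency matches hand values and Floyd-Warshall", {
  # complete unit-weight graph -> 1
  m <- matrix(1, 4, 4); diag(m) <- 0
  expect_equal(global_efficiency(m), 1)
  # 3-node unit path -> (1 + 1 + 1/2)/3 = 5/6
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 1
  p[2, 3] <- p[3, 2] <- 1
  expect_equal(global_efficiency(p), 5 / 6)
  # random 8-node weighted graph vs Floyd-Warshall oracle
  set.seed(10)
  n <- 8
  a <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) > 0.4)
  a[lower.tri(a, diag = TRUE)] <- 0
  a <- a + t(a)
  d <- ifelse(a > 0, 1 / a, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  expect_equal(global_efficiency(a), sum(inv) / (n * (n - 1)))
})

test_that("node graph metrics match star properties and equivariance", {
  # star: center betweenness 1 (normalized), leaves 0
  n <- 6
  star <- matrix(0, n, n)
  star[1, 2:n] <- 1
  star <- star + t(star)
  met <- node_graph_metrics(star, "weights")
  expect_equal(met$betweenness[1], 1)
  expect_equal(met$betweenness[2:n], rep(0, n - 1))
  expect_equal(met$degree[1], n - 1)
  # permutation equivariance
  set.seed(11)
  a <- matrix(runif(25), 5, 5) * (matrix(runif(25), 5, 5) > 0.3)
  a[lower.tri(a, diag = TRUE)] <- 0
  a <- a + t(a)
  perm <- c(3, 5, 1, 2, 4)
  m1 <- node_graph_metrics(a, "fc")
  m2 <- node_graph_metrics(a[perm, perm], "fc")
  expect_equal(m2$degree, m1$degree[perm])
  expect_equal(m2$betweenness, m1$betweenness[perm])
  expect_equal(m2$closeness, m1$closeness[perm])
})

test_that("metric-set averaging is the element-wise mean", {
  set.seed(12)
  mk <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(160 * 6), 160, 6)
    fc_metric_set(bold_series(x, 1), sliding_window_spec(40, 10, 6, 1),
                  density = 0.2, seed = seed)
  }
  a <- mk(1); b <- mk(2)
  avg <- average_metric_sets(list(a, b))
  expect_equal(avg$sfc, (a$sfc + b$sfc) / 2)
  expect_equal(avg$tc, (a$tc + b$tc) / 2)
  expect_equal(avg$nc, (a$nc + b$nc) / 2)
  expect_equal(avg$fcv, (a$fcv + b$fcv) / 2)
  # invariants of the full metric set
  expect_true(all(a$fcv >= 0))
  expect_true(all(a$tc >= 0 & a$tc <= 1))
  expect_true(all(a$nc == round(a$nc)))
})

test_that("dynamic graphs round-trip through the windowed edge list", {
  rnd <- random_window_fc(4, 6, seed = 33)
  g <- binarize_dynamic(rnd, 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dynamic_graph(g, path)
  back <- read_dynamic_graph(path, n_regions = 6, n_windows = 4,
                             density = 0.3)
  expect_identical(back$adjacency, g$adjacency)
})
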