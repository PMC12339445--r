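# Synthetic connectomes, parcellations, and ground-truth cohorts.
#
# The generators emulate the geometry of empirical inputs — a sparse
# symmetric hub-heavy connectome with distance-like tract lengths, a
# 7-network parcellation with mirrored hemispheres, and per-subject BOLD of
# HCP-like geometry (N ~ 70, ~1200 samples, TR 0.72 s) driven by known
# ground-truth model parameters — so every pipeline stage is testable
# without downloads.

#' Generate a synthetic parcellation
#'
#' Balanced random assignment to `n_networks` networks, alternating
#' hemispheres, centroids mirrored across the midline (x axis) on a sphere
#' of ~70 mm radius. For odd region counts the last region is unpaired (left
#' hemisphere).
#'
#' @param n_regions region count.
#' @param n_networks number of networks (<= 7; labels from the canonical
#'   seven).
#' @param seed integer seed.
#' @param centroids optional precomputed N x 3 centroid matrix.
#' @return a [parcellation()].
#' @export
generate_parcellation <- function(n_regions, n_networks = 7, seed = 1L,
                                  centroids = NULL) {
  stopifnot(n_regions >= 4, n_networks <= n_regions, n_networks <= 7)
  set.seed(derive_seed(seed, "parcellation"))
  if (is.null(centroids)) {
    centroids <- mirrored_centroids(n_regions)
  }
  hemi <- rep(c("left", "right"), length.out = n_regions)
  labels <- RSN_LABELS[seq_len(n_networks)]
  # balanced assignment: cycle labels, then shuffle
  net <- sample(rep(labels, length.out = n_regions))
  parcellation(sprintf("region-%02d", seq_len(n_regions)), hemi, net,
               centroids)
}

# centroids mirrored across x = 0: pairs (2k-1, 2k) are left/right partners;
# an odd final region stands alone on the left
mirrored_centroids <- function(n_regions, radius = 70) {
  half <- ceiling(n_regions / 2)
  pts <- matrix(rnorm(half * 3), half, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * runif(half, 0.7, 1)^(1 / 3)
  pts[, 1] <- -abs(pts[, 1]) - 2   # keep off the midline
  out <- matrix(NA_real_, n_regions, 3)
  left_idx <- seq(1, n_regions, 2)
  out[left_idx, ] <- pts[seq_along(left_idx), ]
  right <- pts
  right[, 1] <- -right[, 1]
  right_idx <- seq(2, n_regions, 2)
  out[right_idx, ] <- right[seq_along(right_idx), ]
  out
}

#' Generate a synthetic structural connectome
#'
#' Random mirrored centroids in a sphere; tract lengths are Euclidean
#' distances; connection probability decays as `exp(-d/decay_scale)` and is
#' boosted for a designated fraction of hub nodes; weights are log-normal
#' scaled by the same distance decay and hub boost. A random spanning tree
#' is always added, so the graph is connected.
#'
#' @param n_regions even region count.
#' @param density target edge fraction in (0, 1].
#' @param hub_fraction fraction of regions designated hubs.
#' @param decay_scale distance-decay scale (mm).
#' @param hub_boost multiplicative connection-probability and weight boost
#'   for hub incidences.
#' @param seed integer seed.
#' @param parcellation optional [parcellation()] supplying centroids.
#' @return a [structural_connectome()] carrying its parcellation; the
#'   indices of the hub regions are in `attr(sc, "hubs")`.
#' @export
generate_connectome <- function(n_regions = 70, density = 0.3,
                                hub_fraction = 0.15, decay_scale = 60,
                                hub_boost = 3, seed = 1L,
                                parcellation = NULL) {
  stopifnot(density > 0, density <= 1)
  set.seed(derive_seed(seed, "connectome"))
  if (is.null(parcellation)) {
    cent <- mirrored_centroids(n_regions)
    parcellation <- generate_parcellation(n_regions, min(7, n_regions),
                                          seed = seed, centroids = cent)
  }
  cent <- parcellation$centroids
  d <- as.matrix(dist(cent))
  n_hubs <- max(1, round(hub_fraction * n_regions))
  set.seed(derive_seed(seed, "edges"))
  hubs <- sample.int(n_regions, n_hubs)
  boost <- matrix(1, n_regions, n_regions)
  boost[hubs, ] <- boost[hubs, ] * hub_boost
  boost[, hubs] <- boost[, hubs] * hub_boost
  prob <- exp(-d / decay_scale) * boost
  diag(prob) <- 0
  pairs <- upper_tri_pairs(n_regions)
  m <- max(n_regions - 1, floor(density * nrow(pairs)))
  score <- prob[pairs] * runif(nrow(pairs))
  keep <- order(-score)[seq_len(min(m, nrow(pairs)))]
  adj <- matrix(FALSE, n_regions, n_regions)
  adj[pairs[keep, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  if (density >= 1) adj[] <- TRUE
  # guarantee connectivity with a random spanning tree
  perm <- sample.int(n_regions)
  for (k in seq_len(n_regions - 1)) {
    adj[perm[k], perm[k + 1]] <- TRUE
    adj[perm[k + 1], perm[k]] <- TRUE
  }
  diag(adj) <- FALSE
  w <- matrix(0, n_regions, n_regions)
  raw <- exp(rnorm(nrow(pairs), 0, 0.5)) * exp(-d[pairs] / decay_scale) *
    boost[pairs]
  wvals <- ifelse(adj[pairs], raw, 0)
  w[pairs] <- wvals
  w <- w + t(w)
  w <- w / max(w)
  lengths <- d * (adj | t(adj))
  sc <- structural_connectome(w, lengths, parcellation)
  attr(sc, "hubs") <- sort(hubs)
  sc
}

#' Synthetic cohort specification
#'
#' Per-parameter truncated-normal distributions for the ground truth; the
#' defaults mirror the empirical geometry scaled to desk size.
#'
#' @param n_regions region count of the connectome the cohort will run on.
#' @param n_subjects number of subjects.
#' @param G_mean,G_sd,J_N_mean,J_N_sd,J_i_mean,J_i_sd,w_p_mean,w_p_sd
#'   ground-truth parameter distributions (sd 0 fixes the value).
#' @param bold_length BOLD samples per subject (the HCP geometry is 1200).
#' @param tr sampling interval (s).
#' @param noise_seed_base base seed; subject `i` uses a seed derived from it.
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_regions = 70, n_subjects = 10,
                                  G_mean = 1.5, G_sd = 0.5,
                                  J_N_mean = 0.15, J_N_sd = 0.02,
                                  J_i_mean = 1.0, J_i_sd = 0.1,
                                  w_p_mean = 1.4, w_p_sd = 0.1,
                                  bold_length = 300, tr = 0.72,
                                  noise_seed_base = 1L) {
  stopifnot(n_regions >= 4, n_subjects >= 1,
            G_sd >= 0, J_N_sd >= 0, J_i_sd >= 0, w_p_sd >= 0)
  structure(list(n_regions = n_regions, n_subjects = n_subjects,
                 G_mean = G_mean, G_sd = G_sd, J_N_mean = J_N_mean,
                 J_N_sd = J_N_sd, J_i_mean = J_i_mean, J_i_sd = J_i_sd,
                 w_p_mean = w_p_mean, w_p_sd = w_p_sd,
                 bold_length = as.integer(bold_length), tr = tr,
                 noise_seed_base = as.integer(noise_seed_base)),
            class = "synthetic_cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a ground-truth cohort
#'
#' Draws per-subject parameters from the spec's distributions (truncated to
#' valid ranges), simulates each subject through the forward model with a
#' subject-specific seed, and returns the BOLD series together with the true
#' parameters. Deterministic given the spec's seeds.
#'
#' @param sc a [structural_connectome()] with `N = spec$n_regions`.
#' @param spec a [synthetic_cohort_spec()].
#' @param config a [simulation_config()] template; duration is derived from
#'   `spec$bold_length` and `tr`.
#' @return list with `subjects` (list of [bold_series()]) and `truth`
#'   (data.frame of per-subject G, J_N, J_i, w_p).
#' @export
generate_cohort <- function(sc, spec = synthetic_cohort_spec(),
                            config = simulation_config()) {
  stopifnot(nrow(sc$weights) == spec$n_regions)
  set.seed(derive_seed(spec$noise_seed_base, "cohort-params"))
  truth <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(spec$n_subjects)),
    G = rtrunc_norm(spec$n_subjects, spec$G_mean, spec$G_sd, 0, 10),
    J_N = rtrunc_norm(spec$n_subjects, spec$J_N_mean, spec$J_N_sd, 0.01, 1),
    J_i = rtrunc_norm(spec$n_subjects, spec$J_i_mean, spec$J_i_sd, 0.1, 3),
    w_p = rtrunc_norm(spec$n_subjects, spec$w_p_mean, spec$w_p_sd, 0.1, 2.5))
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    cfg <- config
    cfg$tr <- spec$tr
    cfg$duration <- config$burn_in + spec$bold_length * spec$tr + spec$tr
    cfg$seed <- derive_seed(spec$noise_seed_base, "cohort-sim", i)
    params <- model_parameters(G = truth$G[i], J_N = truth$J_N[i],
                               J_i = truth$J_i[i], w_p = truth$w_p[i])
    res <- tryCatch(dmf_simulate(sc, params, cfg),
                    error = function(e) {
                      stop_dmf("subject %s failed: %s", truth$subject_id[i],
                               conditionMessage(e),
                               class = "dmfconn_integration_error")
                    })
    bold <- res$bold[seq_len(min(spec$bold_length, nrow(res$bold))), ,
                     drop = FALSE]
    subjects[[i]] <- bold_series(bold, spec$tr, truth$subject_id[i])
  }
  names(subjects) <- truth$subject_id
  list(subjects = subjects, truth = truth)
}

#' Plant a linear target in a feature table
#'
#' Target = linear combination of `k_signal` random feature columns plus
#' Gaussian noise calibrated so the population R^2 equals `noise_r2`
#' (`noise_r2 = 1` gives a noiseless target, 0 an independent one).
#'
#' @param features subjects x features matrix.
#' @param k_signal number of signal-carrying columns.
#' @param noise_r2 population R^2 in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `target`, `support` (signal column indices), and
#'   `coefficients`.
#' @export
generate_linear_target <- function(features, k_signal, noise_r2, seed = 1L) {
  stopifnot(k_signal <= ncol(features), noise_r2 >= 0, noise_r2 <= 1)
  set.seed(derive_seed(seed, "target"))
  support <- sort(sample.int(ncol(features), k_signal))
  # planted coefficients of comparable magnitude, bounded away from zero,
  # so each signal feature carries a detectable share of the variance
  beta <- sample(c(-1, 1), k_signal, replace = TRUE) *
    runif(k_signal, 0.5, 1.5)
  if (noise_r2 == 0) {
    return(list(target = rnorm(nrow(features)), support = integer(0),
                coefficients = numeric(0)))
  }
  signal <- as.numeric(scale(features[, support, drop = FALSE]) %*% beta)
  var_sig <- var(signal)
  var_noise <- if (noise_r2 >= 1) 0 else var_sig * (1 - noise_r2) / noise_r2
  target <- signal + rnorm(nrow(features), 0, sqrt(var_noise))
  list(target = target, support = support, coefficients = beta)
}
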