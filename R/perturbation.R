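# Region-wise coupling perturbation of the fitted group-level model and
# spatial-null (spin-test) correlation of the resulting impact maps.

#' Fit the group-level default parameters
#'
#' Grid-search winner under the combined criterion against the group-average
#' empirical metrics (element-wise mean of the subject metric sets).
#'
#' @param group_emp group-average `fc_metric_set` (see
#'   [average_metric_sets()]).
#' @param library a `simulation_library` built on the group connectome.
#' @return a [model_parameters()] carrying the winning `G, J_N, J_i, w_p`.
#' @export
fit_group_default <- function(group_emp, library) {
  sel <- grid_search(group_emp, library, "group")
  win <- sel[sel$criterion == "combined", ]
  model_parameters(G = win$G, J_N = win$J_N, J_i = win$J_i, w_p = win$w_p)
}

#' Region-wise coupling sweep
#'
#' For each coupling value, re-simulates the default model with `G` replaced
#' in a single region only (all other regions keep the default), computes
#' the sFC fit and TC fit against the group-average empirical metrics and
#' the global efficiency of the simulated sFC (correlation scale), and
#' reports deltas `default - perturbed` per G value plus their mean and
#' variance across the sweep. The same noise seed is shared between the
#' default and every perturbed run, so deltas reflect the parameter change,
#' not the noise realization: at the default `G` the deltas are exactly 0.
#'
#' @param sc a [structural_connectome()].
#' @param default_params the group-level [model_parameters()].
#' @param region region index to perturb.
#' @param group_emp group-average `fc_metric_set`.
#' @param G_values coupling values for the sweep (the full-scale sweep uses 101
#'   values uniformly in `[0, 10]`).
#' @param config a [simulation_config()]; its seed is shared across runs.
#' @param window a [sliding_window_spec()].
#' @param density binarization density for the TC graph.
#' @return an object of class `perturbation_outcome`: list with `region`,
#'   `G_values`, per-G `delta_sfc_fit`, `delta_tc_fit`, `delta_efficiency`,
#'   their means/variances, and `failed` (count of failed G values).
#' @export
regional_sweep <- function(sc, default_params, region, group_emp,
                           G_values = seq(0, 10, length.out = 101),
                           config = simulation_config(),
                           window = sliding_window_spec(), density = 0.10) {
  n <- nrow(sc$weights)
  if (region < 1 || region > n) {
    stop_dmf("region %d out of range", region, class = "dmfconn_value_error")
  }
  eval_run <- function(override) {
    cfg <- config
    cfg$regional_G_override <- override
    res <- dmf_simulate(sc, default_params, cfg)
    series <- bold_series(res$bold, cfg$tr, "perturb")
    sfc_z <- static_fc(series, fisher = TRUE)
    wfc <- sliding_window_fc(series, window)
    g <- binarize_dynamic(wfc, density)
    tc <- temporal_correlation(g)
    r_sfc <- cor(upper_tri_vec(sfc_z), upper_tri_vec(group_emp$sfc))
    r_tc <- cor(tc, group_emp$tc)
    eff <- global_efficiency(static_fc(series, fisher = FALSE))
    c(r_sfc = r_sfc, r_tc = r_tc, eff = eff)
  }
  base <- eval_run(NULL)
  d_sfc <- d_tc <- d_eff <- rep(NA_real_, length(G_values))
  failed <- 0L
  for (k in seq_along(G_values)) {
    override <- rep(default_params$G, n)
    override[region] <- G_values[k]
    pert <- tryCatch(eval_run(override), error = function(e) NULL)
    if (is.null(pert)) {
      failed <- failed + 1L
      next
    }
    d_sfc[k] <- base["r_sfc"] - pert["r_sfc"]
    d_tc[k] <- base["r_tc"] - pert["r_tc"]
    d_eff[k] <- base["eff"] - pert["eff"]
  }
  ok <- !is.na(d_sfc)
  structure(list(region = region, G_values = G_values,
                 delta_sfc_fit = d_sfc, delta_tc_fit = d_tc,
                 delta_efficiency = d_eff,
                 mean_delta_sfc = mean(d_sfc[ok]),
                 var_delta_sfc = var(d_sfc[ok]),
                 mean_delta_tc = mean(d_tc[ok]), var_delta_tc = var(d_tc[ok]),
                 mean_delta_eff = mean(d_eff[ok]),
                 var_delta_eff = var(d_eff[ok]), failed = failed),
            class = "perturbation_outcome")
}

# random 3x3 rotation matrix (uniform over SO(3)) from the QR decomposition
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

spin_permutation <- function(centroids, hemisphere, rotation) {
  unit <- centroids / sqrt(rowSums(centroids^2))
  perm <- integer(nrow(centroids))
  mirror <- diag(c(-1, 1, 1))
  for (h in c("left", "right")) {
    idx <- which(hemisphere == h)
    if (length(idx) == 0) next
    rot <- if (h == "left") mirror %*% rotation %*% mirror else rotation
    rotated <- unit[idx, , drop = FALSE] %*% t(rot)
    # nearest original centroid within the hemisphere (duplicates allowed)
    d <- rotated %*% t(unit[idx, , drop = FALSE])
    perm[idx] <- idx[max.col(d)]
  }
  perm
}

#' Spin-test correlation of two region maps
#'
#' Pearson correlation of two per-region maps with a significance level from
#' spatial-autocorrelation-preserving nulls: the centroid sphere is randomly
#' rotated `n_spins` times (the left hemisphere receives the mirrored
#' rotation), regions are reassigned to their nearest rotated neighbour
#' within hemisphere, and the two-sided add-one p-value counts null
#' correlations at least as extreme as the observed one. The identity
#' rotation reproduces the original map exactly.
#'
#' @param impact,reference length-N numeric maps.
#' @param parc a [parcellation()] supplying centroids and hemispheres.
#' @param n_spins number of rotations (default 1000).
#' @param seed integer seed.
#' @return list with `r`, `p_spin`, and the null correlations `null_r`.
#' @export
correlate_maps <- function(impact, reference, parc, n_spins = 1000L,
                           seed = 1L) {
  stopifnot(length(impact) == length(reference),
            length(impact) == length(parc$region_names))
  if (sd(impact) == 0 || sd(reference) == 0) {
    stop_dmf("degenerate map variance", class = "dmfconn_value_error")
  }
  r_obs <- cor(impact, reference)
  set.seed(seed)
  null_r <- numeric(n_spins)
  for (b in seq_len(n_spins)) {
    perm <- spin_permutation(parc$centroids, parc$hemisphere,
                             random_rotation())
    null_r[b] <- cor(impact[perm], reference)
  }
  p <- (1 + sum(abs(null_r) >= abs(r_obs) - 1e-12)) / (n_spins + 1)
  list(r = r_obs, p_spin = p, null_r = null_r)
}
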