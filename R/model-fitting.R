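# Grid construction, multistability screening, fit scoring, and optimal
# parameter selection.

#' Parameter grid for the simulation library
#'
#' @param G_values coupling values (sorted ascending).
#' @param J_N_values,J_i_values,w_p_values local-parameter values inside the
#'   multistability range.
#' @return an object of class `parameter_grid`.
#' @export
parameter_grid <- function(G_values = seq(0, 5, length.out = 5),
                           J_N_values = c(0.1, 0.15, 0.2, 0.25),
                           J_i_values = c(0.5, 0.8, 1.1, 1.4),
                           w_p_values = c(1.0, 1.25, 1.5, 1.75)) {
  chk <- function(v) length(v) > 0 && !is.unsorted(v)
  if (!chk(G_values) || !chk(J_N_values) || !chk(J_i_values) ||
      !chk(w_p_values)) {
    stop_dmf("grid value lists must be non-empty and sorted ascending",
             class = "dmfconn_value_error")
  }
  structure(list(G_values = G_values, J_N_values = J_N_values,
                 J_i_values = J_i_values, w_p_values = w_p_values),
            class = "parameter_grid")
}

grid_points <- function(grid) {
  pts <- expand.grid(w_p = grid$w_p_values, J_i = grid$J_i_values,
                     J_N = grid$J_N_values, G = grid$G_values,
                     KEEP.OUT.ATTRS = FALSE)
  pts[, c("G", "J_N", "J_i", "w_p")]
}

#' Screen local parameter combinations for multistability
#'
#' For each `(J_N, J_i, w_p)` candidate, runs short noise-free simulations
#' from a low and a high initial gating state across the coupling values and
#' flags the combination multistable when the two branches' mean excitatory
#' firing rates differ by more than `tol` (Hz) for at least one `G`.
#'
#' @param sc a [structural_connectome()].
#' @param local_grid data.frame with columns `J_N`, `J_i`, `w_p`.
#' @param G_values coupling values to test (the full-scale sweep uses 101 values
#'   equally spaced in `[0, 10]`).
#' @param config a [simulation_config()] for the short screens; noise and
#'   jitter are forced off.
#' @param tol branch-separation tolerance on the mean E firing rate (Hz).
#' @param base_params named list of [model_parameters()] overrides (e.g.,
#'   a different external input `I_0`) applied to every screened point.
#' @return `local_grid` with a logical `multistable` column and the maximal
#'   branch separation `max_gap` (Hz).
#' @export
multistability_screen <- function(sc, local_grid,
                                  G_values = seq(0, 10, length.out = 101),
                                  config = simulation_config(duration = 4,
                                                             burn_in = 0),
                                  tol = 1, base_params = list()) {
  stopifnot(all(c("J_N", "J_i", "w_p") %in% names(local_grid)))
  run_branch <- function(params, init) {
    cfg <- config
    cfg$init_value <- init
    cfg$init_jitter <- 0
    cfg$store_states <- TRUE
    cfg$state_stride <- 1L
    res <- dmf_simulate(sc, params, cfg)
    tail_rows <- max(1, nrow(res$r_E) - round(1 / (config$dt)) + 1)
    mean(res$r_E[tail_rows:nrow(res$r_E), ])
  }
  out <- local_grid
  out$multistable <- FALSE
  out$max_gap <- 0
  for (k in seq_len(nrow(local_grid))) {
    gap <- 0
    for (G in G_values) {
      params <- do.call(model_parameters, c(
        list(G = G, J_N = local_grid$J_N[k], J_i = local_grid$J_i[k],
             w_p = local_grid$w_p[k], sigma = 0),
        base_params))
      r_low <- tryCatch(run_branch(params, 0.001), error = function(e) {
        stop_dmf("screen failed at J_N=%g J_i=%g w_p=%g G=%g: %s",
                 local_grid$J_N[k], local_grid$J_i[k], local_grid$w_p[k], G,
                 conditionMessage(e), class = "dmfconn_integration_error")
      })
      r_high <- run_branch(params, 0.9)
      gap <- max(gap, abs(r_high - r_low))
    }
    out$max_gap[k] <- gap
    out$multistable[k] <- gap > tol
  }
  out
}

#' Pearson fit between simulated and empirical metric sets
#'
#' Matrix metrics (sFC, FCV, NC) are compared over the strict upper triangle
#' only; TC over the length-N vectors. The combined criterion is
#' [combined_score()] of the sFC and TC fits.
#'
#' @param sim,emp `fc_metric_set` objects with equal N.
#' @param strict if `TRUE` (default) a zero-variance metric raises an
#'   undefined-correlation error; if `FALSE` that fit is reported as `NA`
#'   (used by [grid_search()], where a single degenerate library point must
#'   not abort the scan).
#' @return an object of class `fit_metrics`: list with `r_sfc`, `r_fcv`,
#'   `r_tc`, `r_nc`, `combined`.
#' @export
compute_fit <- function(sim, emp, strict = TRUE) {
  if (length(sim$tc) != length(emp$tc)) {
    stop_dmf("metric sets differ in N", class = "dmfconn_format_error")
  }
  pear <- function(a, b, what) {
    if (sd(a) == 0 || sd(b) == 0) {
      if (strict) {
        stop_dmf("undefined correlation: zero variance in %s", what,
                 class = "dmfconn_value_error")
      }
      return(NA_real_)
    }
    cor(a, b)
  }
  r_sfc <- pear(upper_tri_vec(sim$sfc), upper_tri_vec(emp$sfc), "sfc")
  r_fcv <- pear(upper_tri_vec(sim$fcv), upper_tri_vec(emp$fcv), "fcv")
  r_tc <- pear(sim$tc, emp$tc, "tc")
  r_nc <- pear(as.numeric(upper_tri_vec(sim$nc)),
               as.numeric(upper_tri_vec(emp$nc)), "nc")
  structure(list(r_sfc = r_sfc, r_fcv = r_fcv, r_tc = r_tc, r_nc = r_nc,
                 combined = combined_score(r_sfc, r_tc)),
            class = "fit_metrics")
}

#' Combined (l2-norm) fitting criterion
#'
#' Euclidean distance of `(r_sfc, r_tc)` from the ideal point `(1, 1)`:
#' `sqrt((1 - r_sfc)^2 + (1 - r_tc)^2)`. Lower is better; selection
#' minimizes it, so improving either correlation strictly decreases the
#' score.
#'
#' @param r_sfc,r_tc correlations in `[-1, 1]`.
#' @return scalar score in `[0, 2*sqrt(2)]`.
#' @export
combined_score <- function(r_sfc, r_tc) {
  sqrt((1 - r_sfc)^2 + (1 - r_tc)^2)
}

#' Build the simulation library over a parameter grid
#'
#' Simulates each grid point once (seed derived per point from `seed_base`)
#' on the given connectome and computes its FC metric set. The library is
#' computed once per connectome and reused across all subjects.
#'
#' @param sc a [structural_connectome()].
#' @param grid a [parameter_grid()].
#' @param config a [simulation_config()] template; the per-point seed is
#'   derived internally.
#' @param window a [sliding_window_spec()] used for the simulated metrics.
#' @param density binarization density.
#' @param seed_base master seed for per-point seeds.
#' @param bold_dir optional directory; when given, each grid point's BOLD is
#'   written there as `lib-<k>.tsv` (the pipeline's simulation cache).
#' @return an object of class `simulation_library`: list with `points`
#'   (data.frame of G, J_N, J_i, w_p) and `metrics` (list of
#'   `fc_metric_set`).
#' @export
build_simulation_library <- function(sc, grid, config = simulation_config(),
                                     window = sliding_window_spec(),
                                     density = 0.10, seed_base = 1L,
                                     bold_dir = NULL) {
  pts <- grid_points(grid)
  metrics <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    cfg <- config
    cfg$seed <- derive_seed(seed_base, "library", k)
    params <- model_parameters(G = pts$G[k], J_N = pts$J_N[k],
                               J_i = pts$J_i[k], w_p = pts$w_p[k])
    res <- dmf_simulate(sc, params, cfg)
    series <- bold_series(res$bold, cfg$tr, sprintf("sim-%03d", k))
    if (!is.null(bold_dir)) {
      write_bold(series, file.path(bold_dir, sprintf("lib-%04d.tsv", k)))
    }
    metrics[[k]] <- fc_metric_set(series, window, density,
                                  seed = derive_seed(seed_base, "metrics", k))
  }
  structure(list(points = pts, metrics = metrics, seed_base = seed_base),
            class = "simulation_library")
}

#' @export
print.simulation_library <- function(x, ...) {
  cat(sprintf("<simulation_library> %d grid points\n", nrow(x$points)))
  invisible(x)
}

#' Select optimal parameter sets for one subject
#'
#' Scans the simulation library and selects, per criterion, the grid point
#' with the highest Pearson fit (sfc, fcv, tc, nc) or the lowest combined
#' score. Ties are broken by the lexicographically smallest
#' `(G, J_N, J_i, w_p)`. All four fits are reported for every winner.
#'
#' @param emp the subject's empirical `fc_metric_set`.
#' @param library a `simulation_library`.
#' @param subject_id identifier echoed in the output.
#' @return data.frame with one row per criterion (`sfc`, `fcv`, `tc`, `nc`,
#'   `combined`) and columns for the winning parameters and all fits.
#' @export
grid_search <- function(emp, library, subject_id = "subject") {
  pts <- library$points
  if (nrow(pts) == 0) stop_dmf("empty library", class = "dmfconn_value_error")
  fits <- lapply(library$metrics, compute_fit, emp = emp, strict = FALSE)
  tab <- data.frame(
    r_sfc = vapply(fits, `[[`, numeric(1), "r_sfc"),
    r_fcv = vapply(fits, `[[`, numeric(1), "r_fcv"),
    r_tc = vapply(fits, `[[`, numeric(1), "r_tc"),
    r_nc = vapply(fits, `[[`, numeric(1), "r_nc"),
    combined = vapply(fits, `[[`, numeric(1), "combined"))
  lex <- order(pts$G, pts$J_N, pts$J_i, pts$w_p)
  pick <- function(score, minimize = FALSE) {
    s <- if (minimize) -score else score
    if (all(is.na(s))) return(lex[1])   # criterion undefined everywhere
    best <- max(s, na.rm = TRUE)
    cand <- which(!is.na(s) & s >= best)
    cand[order(match(cand, lex))][1]
  }
  rows <- lapply(c(sfc = "r_sfc", fcv = "r_fcv", tc = "r_tc", nc = "r_nc",
                   combined = "combined"),
                 function(col) {
                   k <- pick(tab[[col]], minimize = col == "combined")
                   cbind(pts[k, , drop = FALSE], tab[k, , drop = FALSE],
                         grid_index = k)
                 })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = subject_id, criterion = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Fit every subject against a prebuilt simulation library
#'
#' Pure selection: triggers no re-simulation (assertable through
#' [simulation_count()]).
#'
#' @param emp_sets named list of empirical `fc_metric_set` objects.
#' @param library a `simulation_library`.
#' @return data.frame, one row per subject x criterion.
#' @export
fit_subjects <- function(emp_sets, library) {
  ids <- names(emp_sets)
  if (is.null(ids)) ids <- sprintf("subject-%03d", seq_along(emp_sets))
  do.call(rbind, Map(function(emp, id) grid_search(emp, library, id),
                     emp_sets, ids))
}
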