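# End-to-end pipeline: synthetic inputs -> simulation library -> per-subject
# metrics and fits -> association -> prediction -> perturbation, with JSON
# manifests and artifact caching keyed by a config hash.

#' Pipeline configuration
#'
#' @param output_dir directory for stage outputs and manifests.
#' @param master_seed integer master seed; every stage derives its own seeds
#'   from it, so any subset re-runs identically.
#' @param scale `"desk"` (small synthetic preset: 12 regions, 5x2x2x2 grid,
#'   short runs) or `"full"` (the full-scale configuration: 70 regions,
#'   101x10x10x10 grid; cluster-intended).
#' @param n_subjects cohort size.
#' @param n_regions region count (desk default 12).
#' @param grid a [parameter_grid()], or `NULL` for the preset default.
#' @param window a [sliding_window_spec()], or `NULL` for a preset scaled to
#'   the BOLD length.
#' @param bold_length BOLD samples per subject.
#' @param perturb_regions region indices to sweep (desk default: first 3).
#' @param perturb_G_values sweep values (desk default: 11 values in [0, 5]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, master_seed = 1L,
                            scale = c("desk", "full"), n_subjects = 8,
                            n_regions = if (scale[1] == "full") 70 else 12,
                            grid = NULL, window = NULL, bold_length = 220,
                            perturb_regions = 1:3,
                            perturb_G_values = seq(0, 5, length.out = 11)) {
  scale <- match.arg(scale)
  if (is.null(grid)) {
    grid <- if (scale == "full") {
      parameter_grid(G_values = seq(0, 10, length.out = 101),
                     J_N_values = seq(0.1, 0.3, length.out = 10),
                     J_i_values = seq(0.5, 1.5, length.out = 10),
                     w_p_values = seq(1.0, 1.8, length.out = 10))
    } else {
      parameter_grid(G_values = seq(0, 4, length.out = 5),
                     J_N_values = c(0.12, 0.18),
                     J_i_values = c(0.8, 1.2),
                     w_p_values = c(1.2, 1.6))
    }
  }
  if (is.null(window)) {
    window <- sliding_window_spec(window_length = 40, step = 2,
                                  taper_sigma = 6, tr = 0.72)
  }
  structure(list(output_dir = output_dir, master_seed = as.integer(master_seed),
                 scale = scale, n_subjects = n_subjects, n_regions = n_regions,
                 grid = grid, window = window, bold_length = bold_length,
                 perturb_regions = perturb_regions,
                 perturb_G_values = perturb_G_values),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config)[setdiff(names(unclass(config)),
                                                "output_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  derive_seed(0L, as.character(s))
}

write_manifest <- function(path, stage, config, extra = list()) {
  manifest <- c(list(stage = stage, config_hash = config_hash(config),
                     master_seed = config$master_seed,
                     package_version = as.character(
                       utils::packageVersion("dmfconn"))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_cached <- function(dir, stage, config) {
  mf <- file.path(dir, paste0(stage, "_manifest.json"))
  if (!file.exists(mf)) return(FALSE)
  m <- jsonlite::read_json(mf)
  identical(as.integer(m$config_hash), config_hash(config))
}

#' Run the end-to-end pipeline
#'
#' Executes the stages simulate-grid, metrics, fit, associate, predict, and
#' perturb on a synthetic cohort, writing every stage's outputs as CSV/TSV
#' plus a JSON manifest (config hash, seeds, package version) under the
#' config's output directory. Stages whose manifest matches the current
#' config hash are reused rather than recomputed. Identical master seeds
#' give bit-identical fit tables and outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of stage results (`connectome`, `cohort`, `library`, `fits`,
#'   `association`, `prediction`, `perturbation`) plus the run manifest
#'   path.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  seed <- config$master_seed
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- inputs ---------------------------------------------------------
  sc <- generate_connectome(config$n_regions, density = 0.4,
                            seed = derive_seed(seed, "sc"))
  write_connectome(sc, file.path(out, "weights.tsv"),
                   file.path(out, "lengths.tsv"),
                   file.path(out, "regions.csv"))
  cohort_spec <- synthetic_cohort_spec(
    n_regions = config$n_regions, n_subjects = config$n_subjects,
    bold_length = config$bold_length,
    noise_seed_base = derive_seed(seed, "cohort"))
  sim_cfg <- simulation_config(duration = 30, burn_in = 5, tr = 0.72,
                               seed = seed)

  # --- stage 1+2: simulation library & subject metrics ----------------
  # cached: when the simulate manifest matches the config hash, cohort and
  # library BOLD are read back from TSV rather than re-simulated
  sim_dir <- file.path(out, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  pts <- grid_points(config$grid)
  lib_cfg <- simulation_config(
    duration = 5 + config$bold_length * 0.72 + 0.72, burn_in = 5,
    tr = 0.72, seed = seed)
  use_cache <- stage_cached(out, "simulate", config)
  if (use_cache) {
    say("simulate-grid: reusing cached BOLD")
    truth <- read.csv(file.path(sim_dir, "truth.csv"))
    subjects <- lapply(truth$subject_id, function(id) {
      read_bold(file.path(sim_dir, paste0(id, ".tsv")), cohort_spec$tr, id)
    })
    names(subjects) <- truth$subject_id
    cohort <- list(subjects = subjects, truth = truth)
    metrics <- lapply(seq_len(nrow(pts)), function(k) {
      b <- read_bold(file.path(sim_dir, sprintf("lib-%04d.tsv", k)),
                     lib_cfg$tr, sprintf("sim-%03d", k))
      fc_metric_set(b, config$window,
                    seed = derive_seed(derive_seed(seed, "library"),
                                       "metrics", k))
    })
    library <- structure(list(points = pts, metrics = metrics,
                              seed_base = derive_seed(seed, "library")),
                         class = "simulation_library")
  } else {
    say("simulate-grid: %d points", nrow(pts))
    cohort <- generate_cohort(sc, cohort_spec, sim_cfg)
    write.csv(cohort$truth, file.path(sim_dir, "truth.csv"),
              row.names = FALSE)
    for (id in names(cohort$subjects)) {
      write_bold(cohort$subjects[[id]], file.path(sim_dir,
                                                  paste0(id, ".tsv")))
    }
    library <- build_simulation_library(
      sc, config$grid, config = lib_cfg, window = config$window,
      seed_base = derive_seed(seed, "library"), bold_dir = sim_dir)
  }
  emp_sets <- lapply(seq_along(cohort$subjects), function(i) {
    fc_metric_set(cohort$subjects[[i]], config$window,
                  seed = derive_seed(seed, "emp-metrics", i))
  })
  names(emp_sets) <- names(cohort$subjects)
  write_manifest(file.path(out, "simulate_manifest.json"), "simulate",
                 config, list(n_grid_points = nrow(library$points)))

  # --- stage 3: fits --------------------------------------------------
  say("fit: %d subjects", length(emp_sets))
  fits <- fit_subjects(emp_sets, library)
  write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
  write_manifest(file.path(out, "fit_manifest.json"), "fit", config)

  # --- stage 4: association -------------------------------------------
  comb <- fits[fits$criterion == "combined", ]
  feats <- feature_table(emp_sets, "edge_sfc")
  assoc <- data.frame(outcome = character(), feature = character(),
                      r = numeric(), p = numeric(), q = numeric())
  if (sd(comb$G) > 0) {
    r <- correlate_features(comb$G, feats)
    p <- permutation_pvalues(comb$G, feats, n_perm = 1000L,
                             seed = derive_seed(seed, "assoc"))
    q <- fdr_adjust(p)
    assoc <- data.frame(outcome = "G", feature = names(r), r = unname(r),
                        p = unname(p), q = unname(q))
  }
  write.csv(assoc, file.path(out, "association.csv"), row.names = FALSE)
  write_manifest(file.path(out, "associate_manifest.json"), "associate",
                 config)

  # --- stage 5: prediction --------------------------------------------
  pred <- NULL
  if (length(emp_sets) >= 10) {
    spec <- prediction_spec("edge_sfc", seed = derive_seed(seed, "predict"))
    pred <- ridge_nested_cv(feats, comb$r_sfc, spec)
    write.csv(data.frame(target = "r_sfc", feature_kind = "edge_sfc",
                         r2_mean = pred$r2_mean, r2_sem = pred$r2_sem),
              file.path(out, "prediction.csv"), row.names = FALSE)
  }
  write_manifest(file.path(out, "predict_manifest.json"), "predict", config)

  # --- stage 6: perturbation (cached like the simulations) -------------
  pert_csv <- file.path(out, "perturbation.csv")
  if (stage_cached(out, "perturb", config) && file.exists(pert_csv)) {
    say("perturb: reusing cached sweep")
    pert_tab <- read.csv(pert_csv)
  } else {
    say("perturb: %d regions", length(config$perturb_regions))
    group_emp <- average_metric_sets(emp_sets)
    default_params <- fit_group_default(group_emp, library)
    pert_cfg <- simulation_config(duration = 30, burn_in = 5, tr = 0.72,
                                  seed = derive_seed(seed, "perturb"))
    pert <- lapply(config$perturb_regions, function(rg) {
      regional_sweep(sc, default_params, rg, group_emp,
                     G_values = config$perturb_G_values, config = pert_cfg,
                     window = sliding_window_spec(window_length = 15,
                                                  step = 2, taper_sigma = 6,
                                                  tr = 0.72))
    })
    pert_tab <- do.call(rbind, lapply(pert, function(p) {
      data.frame(region = p$region, mean_delta_sfc = p$mean_delta_sfc,
                 var_delta_sfc = p$var_delta_sfc,
                 mean_delta_tc = p$mean_delta_tc,
                 var_delta_tc = p$var_delta_tc,
                 mean_delta_eff = p$mean_delta_eff,
                 var_delta_eff = p$var_delta_eff, failed = p$failed)
    }))
    write.csv(pert_tab, pert_csv, row.names = FALSE)
  }
  write_manifest(file.path(out, "perturb_manifest.json"), "perturb", config)

  run_manifest <- file.path(out, "run_manifest.json")
  write_manifest(run_manifest, "run", config,
                 list(stages = c("simulate", "fit", "associate", "predict",
                                 "perturb")))
  invisible(list(connectome = sc, cohort = cohort, library = library,
                 fits = fits, association = assoc, prediction = pred,
                 perturbation = pert_tab, manifest = run_manifest))
}
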