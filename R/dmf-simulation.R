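# Reduced Wong-Wang excitatory/inhibitory mean-field model on a connectome,
# with Balloon-Windkessel hemodynamic forward modelling.
#
# Per region i the model tracks excitatory (E) and inhibitory (I) synaptic
# gating S and firing rates r:
#   I_E_i = w_E*I_0 + w_p*J_N*S_E_i + G_i*J_N * sum_j C_ij S_E_j(t - D_ij)
#           - J_i*S_I_i
#   I_I_i = w_I*I_0 + J_N*S_E_i - S_I_i
#   r     = H(I) = (a*I - b) / (1 - exp(-d*(a*I - b)))
#   dS_E/dt = -S_E/tau_E + (1 - S_E)*gamma_E*r_E + sigma*nu(t)
#   dS_I/dt = -S_I/tau_I + r_I + sigma*nu(t)
# integrated with Euler-Maruyama; delays D_ij = lengths/(speed*dt) steps.

#' Model parameters of the reduced Wong-Wang E/I mean-field model
#'
#' The four free parameters of the fitting procedure are the global coupling
#' `G`, the excitatory (NMDA) synaptic coupling `J_N` (nA), the local feedback
#' inhibitory coupling `J_i` (nA), and the local excitatory recurrence `w_p`.
#' The remaining constants default to the published values of the source
#' mean-field model and are rarely changed: transfer-function gain/threshold/
#' saturation per population (`a_E` 310 nC^-1, `b_E` 125 Hz, `d_E` 0.16 s;
#' `a_I` 615, `b_I` 177, `d_I` 0.087), synaptic time constants (`tau_E` 0.1 s
#' NMDA, `tau_I` 0.01 s GABA), kinetic rate `gamma_E` 0.641, noise amplitude
#' `sigma` (nA), external input `I_0` 0.382 nA with scaling weights `w_E`,
#' `w_I`.
#'
#' @param G global coupling (unitless, >= 0).
#' @param J_N excitatory synaptic coupling (nA).
#' @param J_i local feedback inhibitory coupling (nA).
#' @param w_p local excitatory recurrence weight.
#' @param a_E,b_E,d_E,a_I,b_I,d_I transfer-function constants.
#' @param tau_E,tau_I synaptic time constants (s).
#' @param gamma_E kinetic rate.
#' @param sigma noise amplitude (nA).
#' @param I_0 external input (nA).
#' @param w_E,w_I external-input scaling weights.
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(G = 1.0, J_N = 0.15, J_i = 1.0, w_p = 1.4,
                             a_E = 310, b_E = 125, d_E = 0.16,
                             a_I = 615, b_I = 177, d_I = 0.087,
                             tau_E = 0.1, tau_I = 0.01, gamma_E = 0.641,
                             sigma = 0.01, I_0 = 0.382, w_E = 1.0,
                             w_I = 0.7) {
  stopifnot(G >= 0, tau_E > 0, tau_I > 0, sigma >= 0,
            a_E > 0, a_I > 0, d_E > 0, d_I > 0)
  structure(list(G = G, J_N = J_N, J_i = J_i, w_p = w_p,
                 a_E = a_E, b_E = b_E, d_E = d_E,
                 a_I = a_I, b_I = b_I, d_I = d_I,
                 tau_E = tau_E, tau_I = tau_I, gamma_E = gamma_E,
                 sigma = sigma, I_0 = I_0, w_E = w_E, w_I = w_I),
            class = "model_parameters")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Standard values of the hemodynamic forward model: signal decay rate
#' `kappa` (s^-1), flow-dependent elimination `gamma_f` (s^-1), hemodynamic
#' transit time `tau_h` (s), Grubb's exponent `alpha`, resting oxygen
#' extraction fraction `rho`, resting venous volume fraction `V0`, and BOLD
#' readout coefficients `k1 = 7*rho`, `k2 = 2`, `k3 = 2*rho - 0.2`.
#'
#' @param kappa,gamma_f,tau_h,alpha,rho,V0,k1,k2,k3 see description.
#' @return an object of class `hemodynamic_parameters`.
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma_f = 0.41, tau_h = 0.98,
                                   alpha = 0.32, rho = 0.34, V0 = 0.02,
                                   k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  stopifnot(kappa > 0, gamma_f > 0, tau_h > 0,
            alpha > 0, alpha <= 1, rho > 0, rho < 1, V0 > 0)
  structure(list(kappa = kappa, gamma_f = gamma_f, tau_h = tau_h,
                 alpha = alpha, rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3),
            class = "hemodynamic_parameters")
}

#' Simulation configuration
#'
#' @param dt integration step (s).
#' @param duration total simulated time including burn-in (s).
#' @param burn_in discarded initial time (s).
#' @param tr BOLD sampling interval (s); HCP resting-state uses 0.72 s.
#' @param seed integer seed for the noise stream and initial jitter.
#' @param conduction_speed finite speed in mm/s, or `Inf` for the documented
#'   no-delays mode (the default: the tract-length delay structure is
#'   retained in the connectome but not applied).
#' @param regional_G_override optional length-N vector replacing the scalar
#'   `G` per region (used by the perturbation module), or `NULL`.
#' @param init_value initial gating level for both populations (jittered).
#' @param init_jitter amplitude of the seeded uniform jitter on the initial
#'   conditions; set 0 for exactly equal starts.
#' @param store_states whether to keep the gating/rate time courses (at
#'   `state_stride` steps) in addition to BOLD.
#' @param state_stride stride (integration steps) for stored states.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.001, duration = 120, burn_in = 10,
                              tr = 0.72, seed = 1L, conduction_speed = Inf,
                              regional_G_override = NULL, init_value = 0.001,
                              init_jitter = 0.001, store_states = FALSE,
                              state_stride = 10L) {
  if (dt <= 0) stop_dmf("dt must be positive", class = "dmfconn_config_error")
  if (!(duration > burn_in) || burn_in < 0) {
    stop_dmf("need duration > burn_in >= 0", class = "dmfconn_config_error")
  }
  if (tr < dt) stop_dmf("tr must be >= dt", class = "dmfconn_config_error")
  structure(list(dt = dt, duration = duration, burn_in = burn_in, tr = tr,
                 seed = as.integer(seed), conduction_speed = conduction_speed,
                 regional_G_override = regional_G_override,
                 init_value = init_value, init_jitter = init_jitter,
                 store_states = store_states,
                 state_stride = as.integer(state_stride)),
            class = "simulation_config")
}

#' Population transfer function
#'
#' `H(x) = (a*x - b) / (1 - exp(-d*(a*x - b)))`, the sigmoidal-like
#' current-to-rate transfer of the mean-field model. The removable
#' singularity at `a*x = b` evaluates to the analytic limit `1/d`; the
#' function is continuous, non-negative, and asymptotically linear.
#'
#' @param current input current (nA), vectorized.
#' @param a gain (nC^-1).
#' @param b threshold (Hz-scaled).
#' @param d saturation (s).
#' @return firing rate (Hz), same length as `current`.
#' @export
transfer_function <- function(current, a, b, d) {
  transfer_cpp(as.numeric(current), a, b, d)
}

#' Input currents of the coupled E/I populations
#'
#' Reference implementation of the current equations (used directly by tests
#' and oracles; the integrator evaluates the identical expressions in
#' compiled code).
#'
#' @param S_E,S_I length-N gating vectors.
#' @param delayed_S_E N x N matrix whose `[i, j]` entry is region `j`'s
#'   excitatory gating lagged by the `i`-`j` conduction delay.
#' @param params a [model_parameters()].
#' @param sc a [structural_connectome()].
#' @param regional_G_override optional per-region G vector.
#' @return list with `I_E` and `I_I` length-N vectors (nA).
#' @export
compute_currents <- function(S_E, S_I, delayed_S_E, params, sc,
                             regional_G_override = NULL) {
  n <- nrow(sc$weights)
  if (length(S_E) != n || length(S_I) != n ||
      nrow(delayed_S_E) != n || ncol(delayed_S_E) != n) {
    stop_dmf("state dimensions do not match the connectome (N = %d)", n,
             class = "dmfconn_format_error")
  }
  G <- if (is.null(regional_G_override)) rep(params$G, n) else {
    stopifnot(length(regional_G_override) == n)
    regional_G_override
  }
  long_range <- rowSums(sc$weights * delayed_S_E)
  I_E <- params$w_E * params$I_0 + params$w_p * params$J_N * S_E +
    G * params$J_N * long_range - params$J_i * S_I
  I_I <- params$w_I * params$I_0 + params$J_N * S_E - S_I
  list(I_E = I_E, I_I = I_I)
}

delay_steps_matrix <- function(sc, speed, dt) {
  n <- nrow(sc$lengths)
  if (!is.finite(speed)) {
    return(matrix(0L, n, n))
  }
  d <- matrix(as.integer(round(sc$lengths / (speed * dt))), n, n)
  d[sc$weights == 0] <- 0L
  d
}

#' Simulate the mean-field model on a connectome
#'
#' Euler-Maruyama integration at step `dt` with independent Gaussian
#' increments `sigma*sqrt(dt)*N(0,1)` per population and region; gating is
#' clipped to `[0, 1]` after every step. Conduction delays (when
#' `conduction_speed` is finite) are applied through a ring buffer with
#' `round(length/(speed*dt))` steps per connection. Excitatory gating drives
#' the Balloon-Windkessel hemodynamics in lockstep and BOLD is sampled every
#' `tr` after the burn-in is discarded. Identical seed and config give
#' bit-identical output.
#'
#' @param sc a [structural_connectome()].
#' @param params a [model_parameters()].
#' @param config a [simulation_config()].
#' @param hemo a [hemodynamic_parameters()].
#' @return an object of class `simulation_result` with elements `bold`
#'   (T_bold x N), `S_E`, `S_I`, `r_E` (stored-state matrices, possibly
#'   0-row), `terminal_S_E`, `terminal_S_I`, `params_echo`, `config_echo`.
#' @export
dmf_simulate <- function(sc, params, config = simulation_config(),
                         hemo = hemodynamic_parameters()) {
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(params, "model_parameters"),
            inherits(config, "simulation_config"))
  n <- nrow(sc$weights)
  Gvec <- if (is.null(config$regional_G_override)) rep(params$G, n) else {
    stopifnot(length(config$regional_G_override) == n)
    as.numeric(config$regional_G_override)
  }
  n_steps <- as.integer(round(config$duration / config$dt))
  burn_steps <- as.integer(round(config$burn_in / config$dt))
  bold_stride <- as.integer(round(config$tr / config$dt))
  dmat <- delay_steps_matrix(sc, config$conduction_speed, config$dt)

  set.seed(config$seed)
  jit <- if (config$init_jitter > 0) {
    runif(2 * n, 0, config$init_jitter)
  } else rep(0, 2 * n)
  init_SE <- pmin(pmax(config$init_value + jit[seq_len(n)], 0), 1)
  init_SI <- pmin(pmax(config$init_value + jit[n + seq_len(n)], 0), 1)

  res <- tryCatch(
    integrate_dmf_cpp(sc$weights, dmat, Gvec, params$J_N, params$J_i,
                      params$w_p, params$a_E, params$b_E, params$d_E,
                      params$a_I, params$b_I, params$d_I, params$tau_E,
                      params$tau_I, params$gamma_E, params$sigma, params$I_0,
                      params$w_E, params$w_I, config$dt, n_steps, burn_steps,
                      bold_stride, init_SE, init_SI, hemo$kappa, hemo$gamma_f,
                      hemo$tau_h, hemo$alpha, hemo$rho, hemo$V0, hemo$k1,
                      hemo$k2, hemo$k3, config$store_states,
                      config$state_stride),
    error = function(e) stop_dmf("integration failed: %s",
                                 conditionMessage(e),
                                 class = "dmfconn_integration_error"))
  .dmf_counters$integrations <- .dmf_counters$integrations + 1L
  check_no_nonfinite(res$bold, "BOLD output")
  structure(list(bold = res$bold, S_E = res$S_E, S_I = res$S_I,
                 r_E = res$r_E, terminal_S_E = res$terminal_S_E,
                 terminal_S_I = res$terminal_S_I, params_echo = params,
                 config_echo = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> BOLD %d x %d (tr = %g s), G = %g\n",
              nrow(x$bold), ncol(x$bold), x$config_echo$tr, x$params_echo$G))
  invisible(x)
}

#' Write a simulation result with a provenance sidecar
#'
#' Writes the BOLD matrix as a headerless TSV plus a JSON sidecar carrying
#' the full model parameters, the simulation configuration (including the
#' seed), and optionally the hemodynamic parameters, so the run can be
#' reproduced from the files alone.
#'
#' @param result a `simulation_result` from [dmf_simulate()].
#' @param bold_path output TSV path; the sidecar is written next to it as
#'   `<bold_path>.json`.
#' @param hemo the [hemodynamic_parameters()] used, recorded in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_simulation <- function(result, bold_path,
                             hemo = hemodynamic_parameters()) {
  stopifnot(inherits(result, "simulation_result"))
  write_matrix_tsv(result$bold, bold_path)
  sidecar <- paste0(bold_path, ".json")
  cfg <- result$config_echo
  cfg$regional_G_override <- as.numeric(cfg$regional_G_override)
  jsonlite::write_json(list(params = unclass(result$params_echo),
                            config = unclass(cfg),
                            hemodynamics = unclass(hemo)),
                       sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Balloon-Windkessel hemodynamic transform
#'
#' Integrates the four-state hemodynamic ODEs (vasodilatory signal, inflow,
#' venous volume, deoxyhemoglobin) per region, driven by the excitatory
#' synaptic gating, and emits
#' `BOLD = V0*(k1*(1 - q) + k2*(1 - q/v) + k3*(1 - v))` sampled every `tr`.
#' Zero input leaves the states at baseline (0, 1, 1, 1) and BOLD at 0.
#'
#' @param S_E T x N matrix of excitatory gating sampled at `dt`.
#' @param hemo a [hemodynamic_parameters()].
#' @param dt input sampling step (s).
#' @param tr output sampling interval (s), `tr >= dt`.
#' @return T_bold x N BOLD matrix.
#' @export
balloon_windkessel <- function(S_E, hemo = hemodynamic_parameters(),
                               dt = 0.001, tr = 0.72) {
  S_E <- as.matrix(S_E)
  if (nrow(S_E) * dt < tr) {
    stop_dmf("input shorter than one BOLD sample",
             class = "dmfconn_config_error")
  }
  out <- tryCatch(
    balloon_windkessel_cpp(S_E, dt, tr, hemo$kappa, hemo$gamma_f, hemo$tau_h,
                           hemo$alpha, hemo$rho, hemo$V0, hemo$k1, hemo$k2,
                           hemo$k3),
    error = function(e) stop_dmf("hemodynamic integration failed: %s",
                                 conditionMessage(e),
                                 class = "dmfconn_integration_error"))
  check_no_nonfinite(out, "BOLD output")
  out
}
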