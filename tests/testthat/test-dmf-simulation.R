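# Oracles: closed-form/limit checks for the transfer function, root-finding
# for the noise-free fixed point, and a stiff ODE solver for the
# hemodynamic steady state.

test_that("transfer function matches high-accuracy evaluation and limits", {
  # analytic limit at a*x = b
  expect_equal(transfer_function(125 / 310, 310, 125, 0.16), 1 / 0.16,
               tolerance = 1e-9)
  expect_equal(transfer_function(177 / 615, 615, 177, 0.087), 1 / 0.087,
               tolerance = 1e-9)
  # asymptotic linearity: relative error < 1e-6 at a*x - b = 50/d
  a <- 310; b <- 125; d <- 0.16
  u <- 50 / d
  x <- (u + b) / a
  expect_lt(abs(transfer_function(x, a, b, d) - u) / u, 1e-6)
  # high-accuracy oracle over an (a, b, d, x) grid: series expansion near the
  # singularity, expm1-based closed form elsewhere
  oracle <- function(x, a, b, d) {
    u <- a * x - b
    v <- d * u
    if (abs(v) < 1e-5) {
      (1 + v / 2 + v^2 / 12 - v^4 / 720) / d
    } else {
      u / (-expm1(-v))
    }
  }
  grid <- expand.grid(a = c(10, 310, 615), b = c(0, 125, 177),
                      d = c(0.087, 0.16, 1), x = c(-1, 0, 0.2, 0.4, 1, 5))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    got <- transfer_function(g$x, g$a, g$b, g$d)
    want <- oracle(g$x, g$a, g$b, g$d)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gte(got, 0)
  }
  # continuity across the singularity
  xs <- 125 / 310 + seq(-1e-6, 1e-6, length.out = 101)
  h <- transfer_function(xs, 310, 125, 0.16)
  expect_lt(max(abs(diff(h))), 1e-4)
})

test_that("input currents follow the coupled E/I equations", {
  sc <- tiny_connectome(6, seed = 2)
  n <- 6
  params <- model_parameters(G = 1.7, J_N = 0.2, J_i = 0.9, w_p = 1.3)
  # zero state: I_E = w_E*I_0, I_I = w_I*I_0 everywhere
  z <- rep(0, n)
  cur <- compute_currents(z, z, matrix(0, n, n), params, sc)
  expect_equal(cur$I_E, rep(params$w_E * params$I_0, n))
  expect_equal(cur$I_I, rep(params$w_I * params$I_0, n))
  # random state: equals triple-loop evaluation
  set.seed(9)
  S_E <- runif(n); S_I <- runif(n)
  lag <- matrix(runif(n * n), n, n)
  cur <- compute_currents(S_E, S_I, lag, params, sc)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + sc$weights[i, j] * lag[i, j]
    ie <- params$w_E * params$I_0 + params$w_p * params$J_N * S_E[i] +
      params$G * params$J_N * acc - params$J_i * S_I[i]
    ii <- params$w_I * params$I_0 + params$J_N * S_E[i] - S_I[i]
    expect_equal(cur$I_E[i], ie)
    expect_equal(cur$I_I[i], ii)
  }
  # G = 0 decouples regions
  p0 <- model_parameters(G = 0, J_N = 0.2, J_i = 0.9, w_p = 1.3)
  cur0 <- compute_currents(S_E, S_I, lag, p0, sc)
  lag2 <- matrix(runif(n * n), n, n)
  cur0b <- compute_currents(S_E, S_I, lag2, p0, sc)
  expect_equal(cur0$I_E, cur0b$I_E)
})

test_that("noise-free single-region terminal state matches the root-finder", {
  # sigma = 0, G = 0: S_E converges to the fixed point of
  # -S/tau_E + (1 - S)*gamma_E*H_E(I_E(S, S_I*(S))) = 0,
  # with S_I*(S) the inner fixed point of the inhibitory equation
  sc <- structural_connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  params <- model_parameters(G = 0, J_N = 0.15, J_i = 1.0, w_p = 1.4,
                             sigma = 0)
  cfg <- simulation_config(duration = 60, burn_in = 0, seed = 1,
                           init_jitter = 0)
  res <- dmf_simulate(sc, params, cfg)
  S_I_star <- function(S_E) {
    uniroot(function(si) {
      -si / params$tau_I +
        transfer_function(params$w_I * params$I_0 + params$J_N * S_E - si,
                          params$a_I, params$b_I, params$d_I)
    }, c(0, 1), tol = 1e-12)$root
  }
  dSE <- function(s) {
    ie <- params$w_E * params$I_0 + params$w_p * params$J_N * s -
      params$J_i * S_I_star(s)
    -s / params$tau_E + (1 - s) * params$gamma_E *
      transfer_function(ie, params$a_E, params$b_E, params$d_E)
  }
  # bracket around the terminal value
  term <- res$terminal_S_E[1]
  root <- uniroot(dSE, c(max(0, term - 0.2), min(1, term + 0.2)),
                  tol = 1e-10)$root
  expect_equal(term, root, tolerance = 1e-6)
})

test_that("integration is deterministic, clipped, and noise-scales exactly", {
  sc <- tiny_connectome(6, seed = 4)
  params <- model_parameters(G = 1.2)
  cfg <- quick_config(seed = 33, duration = 6, burn_in = 1,
                      store_states = TRUE, state_stride = 1L)
  r1 <- dmf_simulate(sc, params, cfg)
  r2 <- dmf_simulate(sc, params, cfg)
  expect_identical(r1$bold, r2$bold)
  expect_identical(r1$S_E, r2$S_E)
  expect_true(all(r1$S_E >= 0 & r1$S_E <= 1))
  expect_true(all(r1$S_I >= 0 & r1$S_I <= 1))
  expect_true(all(r1$r_E >= 0))
  # with sigma = 0 runs are identical regardless of seed (jitter off)
  p0 <- model_parameters(G = 1.2, sigma = 0)
  cfgA <- quick_config(seed = 1, duration = 3, init_jitter = 0,
                       store_states = TRUE)
  cfgB <- quick_config(seed = 999, duration = 3, init_jitter = 0,
                       store_states = TRUE)
  expect_identical(dmf_simulate(sc, p0, cfgA)$S_E,
                   dmf_simulate(sc, p0, cfgB)$S_E)
  # pathwise noise scaling: after one Euler step from identical ICs,
  # the increment due to noise doubles exactly when sigma doubles
  one_step <- function(sigma) {
    p <- model_parameters(G = 1.2, sigma = sigma)
    cfg1 <- simulation_config(dt = 0.001, duration = 0.001, burn_in = 0,
                              tr = 0.001, seed = 77, init_jitter = 0,
                              store_states = TRUE, state_stride = 1L)
    dmf_simulate(sc, p, cfg1)$terminal_S_E
  }
  s0 <- one_step(0)
  s1 <- one_step(0.005)
  s2 <- one_step(0.010)
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-12)
})

test_that("Euler integration converges at first order in dt", {
  sc <- structural_connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  params <- model_parameters(G = 0, sigma = 0)
  term <- function(dt) {
    cfg <- simulation_config(dt = dt, duration = 2, burn_in = 0, tr = 2,
                             seed = 1, init_jitter = 0)
    dmf_simulate(sc, params, cfg)$terminal_S_E[1]
  }
  ref <- term(0.0000625)  # high-accuracy reference
  e1 <- abs(term(0.002) - ref)
  e2 <- abs(term(0.001) - ref)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 2.6)
})

test_that("simulation is equivariant under region permutation", {
  sc <- tiny_connectome(6, seed = 8)
  perm <- c(3, 1, 6, 2, 5, 4)
  scp <- structural_connectome(sc$weights[perm, perm],
                               sc$lengths[perm, perm])
  params <- model_parameters(G = 1.5, sigma = 0)
  cfg <- quick_config(duration = 4, burn_in = 0, init_jitter = 0,
                      store_states = TRUE, conduction_speed = 500)
  a <- dmf_simulate(sc, params, cfg)
  b <- dmf_simulate(scp, params, cfg)
  expect_equal(b$terminal_S_E, a$terminal_S_E[perm], tolerance = 1e-12)
})

test_that("hemodynamic model holds baseline and matches the steady state", {
  hemo <- hemodynamic_parameters()
  # zero input -> BOLD identically 0
  z <- matrix(0, 5000, 3)
  b <- balloon_windkessel(z, hemo, dt = 0.01, tr = 0.72)
  expect_true(all(b == 0))
  # identical inputs -> identical columns
  set.seed(2)
  drive <- abs(rnorm(4000, 0.1, 0.02))
  two <- balloon_windkessel(cbind(drive, drive), hemo, dt = 0.01, tr = 0.5)
  expect_identical(two[, 1], two[, 2])
  # constant input: steady state matches a stiff ODE solve and the
  # analytic fixed point f = 1 + c/gamma_f, v = f^alpha, q = v*E(f)/rho
  c0 <- 0.08
  f_ss <- 1 + c0 / hemo$gamma_f
  v_ss <- f_ss^hemo$alpha
  E_ss <- 1 - (1 - hemo$rho)^(1 / f_ss)
  q_ss <- v_ss * E_ss / hemo$rho
  bold_ss <- hemo$V0 * (hemo$k1 * (1 - q_ss) + hemo$k2 * (1 - q_ss / v_ss) +
                          hemo$k3 * (1 - v_ss))
  deriv <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    E <- 1 - (1 - hemo$rho)^(1 / f)
    list(c(c0 - hemo$kappa * s - hemo$gamma_f * (f - 1), s,
           (f - v^(1 / hemo$alpha)) / hemo$tau_h,
           (f * E / hemo$rho - v^(1 / hemo$alpha) * q / v) / hemo$tau_h))
  }
  ode_ss <- deSolve::lsoda(c(0, 1, 1, 1), c(0, 200), deriv, NULL,
                           rtol = 1e-10, atol = 1e-12)
  ode_bold <- hemo$V0 * (hemo$k1 * (1 - ode_ss[2, 5]) +
                           hemo$k2 * (1 - ode_ss[2, 5] / ode_ss[2, 4]) +
                           hemo$k3 * (1 - ode_ss[2, 4]))
  expect_equal(unname(ode_bold), bold_ss, tolerance = 1e-7)
  const <- matrix(c0, 120000, 1)
  sim <- balloon_windkessel(const, hemo, dt = 0.001, tr = 1)
  expect_equal(sim[nrow(sim), 1], bold_ss, tolerance = 1e-5)
})

test_that("conduction delays shift the coupling without breaking bounds", {
  sc <- toy_sc()
  params <- model_parameters(G = 2, sigma = 0)
  cfg_inst <- quick_config(duration = 4, burn_in = 0, init_jitter = 0,
                           store_states = TRUE)
  cfg_del <- quick_config(duration = 4, burn_in = 0, init_jitter = 0,
                          store_states = TRUE, conduction_speed = 100)
  a <- dmf_simulate(sc, params, cfg_inst)
  b <- dmf_simulate(sc, params, cfg_del)
  expect_true(all(b$S_E >= 0 & b$S_E <= 1))
  # delays change the trajectory but not the invariants
  expect_false(identical(a$S_E, b$S_E))
})

test_that("simulation writer records full provenance in the sidecar", {
  sc <- toy_sc()
  cfg <- quick_config(seed = 42, duration = 5, burn_in = 1)
  res <- dmf_simulate(sc, model_parameters(G = 1.1), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  side <- write_simulation(res, path)
  back <- read_bold(path, cfg$tr)
  expect_equal(back$data, unname(res$bold), tolerance = 1e-15)
  meta <- jsonlite::read_json(side)
  expect_equal(meta$config$seed, 42)
  expect_equal(meta$params$G, 1.1)
  expect_equal(meta$hemodynamics$alpha, 0.32)
})
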