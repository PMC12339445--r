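# Shared fixtures: tiny connectomes and fast simulation configs.

tiny_connectome <- function(n = 5, seed = 11, density = 0.8) {
  generate_connectome(if (n %% 2) n + 1 else n, density = density,
                      seed = seed)
}

# hand-built 3-region connectome with known structure
toy_sc <- function() {
  w <- matrix(c(0, 1, 0.5,
                1, 0, 0.25,
                0.5, 0.25, 0), 3, 3)
  l <- matrix(c(0, 10, 20,
                10, 0, 30,
                20, 30, 0), 3, 3)
  parc <- parcellation(c("a", "b", "c"), c("left", "right", "left"),
                       c("VN", "VN", "DMN"),
                       matrix(c(-1, 0, 0, 1, 0, 0, -1, 1, 0), 3, 3,
                              byrow = TRUE))
  structural_connectome(w, l, parc)
}

quick_config <- function(seed = 1, duration = 10, burn_in = 1, ...) {
  simulation_config(duration = duration, burn_in = burn_in, tr = 0.72,
                    seed = seed, ...)
}

# deterministic synthetic windowed-FC array
random_window_fc <- function(W, n, seed = 1) {
  set.seed(seed)
  out <- array(NA_real_, c(W, n, n))
  for (w in seq_len(W)) {
    x <- matrix(rnorm(40 * n), 40, n)
    out[w, , ] <- cor(x)
  }
  out
}

# brute-force Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
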