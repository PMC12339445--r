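#' @useDynLib dmfconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor var quantile median sd rnorm runif prcomp t.test
#'   p.adjust dist
#' @importFrom utils read.table combn read.csv write.csv
NULL

# Internal counters (simulation-call accounting used by the caching contract)
.dmf_counters <- new.env(parent = emptyenv())
.dmf_counters$integrations <- 0L

#' Number of full model integrations run so far
#'
#' Used to assert that fitting several subjects against a prebuilt simulation
#' library triggers no re-simulation.
#'
#' @param reset if `TRUE`, reset the counter to zero before returning.
#' @return integer count of calls to [dmf_simulate()] in this session.
#' @export
simulation_count <- function(reset = FALSE) {
  n <- .dmf_counters$integrations
  if (reset) .dmf_counters$integrations <- 0L
  n
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme: every stage/subject/grid-point seed is a pure
#' function of the master seed and a label, so any subset of a pipeline re-runs
#' identically. Result is kept below 2^31.
#'
#' @param master integer master seed.
#' @param ... labels (strings or integers) identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labs <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(labs)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# strict upper-triangle vector in row-major order (i < j, j fastest) --------
# Documented edge order: (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).
upper_tri_vec <- function(m) {
  t(m)[lower.tri(m)]
}

upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# even-integer rounding with half-way cases going up
round_even <- function(x) {
  2 * floor(x / 2 + 0.5)
}

stop_dmf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dmfconn_error")))
}

check_no_nonfinite <- function(x, what) {
  if (any(!is.finite(x))) {
    stop_dmf("%s contains NaN/Inf or missing values", what,
             class = "dmfconn_validation_error")
  }
  invisible(x)
}
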