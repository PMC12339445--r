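# Structural-connectome and BOLD containers plus their readers.
#
# File dialect: tab-separated matrices without header for connectome weights /
# lengths and BOLD tables (samples in rows, regions in columns); region
# metadata as CSV with columns region,hemisphere,network,x,y,z.

RSN_LABELS <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

#' Construct a parcellation
#'
#' A parcellation carries the region names, hemisphere assignment, the
#' resting-state-network (RSN) membership of each region out of the seven
#' canonical networks, and region centroid coordinates (used only by the
#' spin test).
#'
#' @param region_names character vector of unique region names.
#' @param hemisphere character vector, `"left"` or `"right"` per region.
#' @param network character vector of RSN labels; exactly 7 distinct labels
#'   are allowed across the parcellation's vocabulary.
#' @param centroids numeric N x 3 matrix of region centroid coordinates.
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(region_names, hemisphere, network, centroids) {
  n <- length(region_names)
  centroids <- as.matrix(centroids)
  if (length(hemisphere) != n || length(network) != n || nrow(centroids) != n) {
    stop_dmf("parcellation fields must share length N = %d", n,
             class = "dmfconn_format_error")
  }
  if (anyDuplicated(region_names)) {
    stop_dmf("region names must be unique", class = "dmfconn_validation_error")
  }
  if (!all(hemisphere %in% c("left", "right"))) {
    stop_dmf("hemisphere must be 'left' or 'right'",
             class = "dmfconn_validation_error")
  }
  if (length(unique(network)) > 7) {
    stop_dmf("more than 7 network labels", class = "dmfconn_validation_error")
  }
  if (ncol(centroids) != 3) {
    stop_dmf("centroids must be N x 3", class = "dmfconn_format_error")
  }
  check_no_nonfinite(centroids, "centroids")
  structure(list(region_names = as.character(region_names),
                 hemisphere = as.character(hemisphere),
                 network = as.character(network),
                 centroids = unname(centroids)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions, %d networks, %d left / %d right\n",
              length(x$region_names), length(unique(x$network)),
              sum(x$hemisphere == "left"), sum(x$hemisphere == "right")))
  invisible(x)
}

validate_sc_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_dmf("%s must be a square matrix", what, class = "dmfconn_format_error")
  }
  check_no_nonfinite(m, what)
  if (any(m < 0)) {
    stop_dmf("%s has negative entries", what, class = "dmfconn_validation_error")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    stop_dmf("%s asymmetry %.3g exceeds 1e-8", what, asym,
             class = "dmfconn_validation_error")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Construct a structural connectome
#'
#' Couples a non-negative symmetric tract-weight matrix (the coupling
#' substrate `C_ij` of the mean-field model) with a tract-length matrix (mm;
#' lengths set conduction delays) and a [parcellation()].
#'
#' @param weights,lengths square symmetric non-negative matrices with zero
#'   diagonal; `lengths[i,j] > 0` wherever `weights[i,j] > 0`.
#' @param parcellation a [parcellation()] of matching size, or `NULL`.
#' @return an object of class `structural_connectome`.
#' @export
structural_connectome <- function(weights, lengths, parcellation = NULL) {
  weights <- validate_sc_matrix(as.matrix(weights), "weights")
  lengths <- validate_sc_matrix(as.matrix(lengths), "lengths")
  if (nrow(weights) != nrow(lengths)) {
    stop_dmf("weights are %dx%d but lengths are %dx%d",
             nrow(weights), ncol(weights), nrow(lengths), ncol(lengths),
             class = "dmfconn_format_error")
  }
  if (any(weights > 0 & lengths == 0)) {
    stop_dmf("connections with positive weight but zero length",
             class = "dmfconn_validation_error")
  }
  if (!is.null(parcellation)) {
    stopifnot(inherits(parcellation, "parcellation"))
    if (length(parcellation$region_names) != nrow(weights)) {
      stop_dmf("parcellation has %d regions but matrices are %dx%d",
               length(parcellation$region_names), nrow(weights), ncol(weights),
               class = "dmfconn_format_error")
    }
  }
  structure(list(weights = weights, lengths = lengths,
                 parcellation = parcellation),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- nrow(x$weights)
  dens <- mean(upper_tri_vec(x$weights) > 0)
  cat(sprintf("<structural_connectome> N=%d, edge density %.2f\n", n, dens))
  invisible(x)
}

#' Construct a BOLD series
#'
#' @param data numeric T x N matrix, samples in rows, regions in columns.
#' @param tr sampling interval in seconds.
#' @param subject_id identifier string.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, tr, subject_id = "subject") {
  data <- as.matrix(data)
  if (nrow(data) < 2) {
    stop_dmf("BOLD series needs at least 2 samples",
             class = "dmfconn_validation_error")
  }
  if (!is.numeric(data)) {
    stop_dmf("BOLD data must be numeric", class = "dmfconn_format_error")
  }
  check_no_nonfinite(data, "BOLD data")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) {
    stop_dmf("tr must be a positive scalar", class = "dmfconn_validation_error")
  }
  structure(list(data = unname(data), tr = tr,
                 subject_id = as.character(subject_id)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s: %d samples x %d regions, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_dmf("file not found: %s", path, class = "dmfconn_format_error")
  }
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, colClasses = "numeric"),
    error = function(e) stop_dmf("cannot parse %s as a numeric TSV: %s",
                                 path, conditionMessage(e),
                                 class = "dmfconn_format_error"))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  m
}

write_matrix_tsv <- function(m, path) {
  # %.17g round-trips doubles exactly
  txt <- apply(m, 1, function(row) paste(sprintf("%.17g", row),
                                         collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Read a structural connectome from TSV matrices plus CSV metadata
#'
#' Matrices are headerless tab-separated files; metadata is a CSV with columns
#' `region,hemisphere,network,x,y,z`. Matrices are symmetrized by averaging
#' with their transpose when the maximum asymmetry is at most 1e-8, and
#' rejected otherwise.
#'
#' @param weights_path,lengths_path paths to the TSV matrices.
#' @param metadata_path optional path to the region metadata CSV.
#' @return a [structural_connectome()].
#' @export
read_connectome <- function(weights_path, lengths_path, metadata_path = NULL) {
  w <- read_matrix_tsv(weights_path)
  l <- read_matrix_tsv(lengths_path)
  parc <- NULL
  if (!is.null(metadata_path)) {
    md <- read.csv(metadata_path, stringsAsFactors = FALSE)
    need <- c("region", "hemisphere", "network", "x", "y", "z")
    if (!all(need %in% names(md))) {
      stop_dmf("metadata must have columns %s", paste(need, collapse = ","),
               class = "dmfconn_format_error")
    }
    parc <- parcellation(md$region, md$hemisphere, md$network,
                         cbind(md$x, md$y, md$z))
  }
  structural_connectome(w, l, parc)
}

#' Write a structural connectome to disk
#'
#' @param sc a [structural_connectome()].
#' @param weights_path,lengths_path,metadata_path output paths; metadata is
#'   only written when the connectome carries a parcellation.
#' @return invisibly, the weights path.
#' @export
write_connectome <- function(sc, weights_path, lengths_path,
                             metadata_path = NULL) {
  write_matrix_tsv(sc$weights, weights_path)
  write_matrix_tsv(sc$lengths, lengths_path)
  if (!is.null(metadata_path) && !is.null(sc$parcellation)) {
    p <- sc$parcellation
    write.csv(data.frame(region = p$region_names, hemisphere = p$hemisphere,
                         network = p$network, x = p$centroids[, 1],
                         y = p$centroids[, 2], z = p$centroids[, 3]),
              metadata_path, row.names = FALSE)
  }
  invisible(weights_path)
}

#' Element-wise average of structural connectomes
#'
#' Produces the group-average connectome (mean tract weights and mean tract
#' lengths) on which all simulations run.
#'
#' @param connectomes non-empty list of [structural_connectome()] objects
#'   sharing N and region order.
#' @return a [structural_connectome()].
#' @export
average_connectomes <- function(connectomes) {
  if (length(connectomes) == 0) {
    stop_dmf("empty connectome list", class = "dmfconn_value_error")
  }
  n <- nrow(connectomes[[1]]$weights)
  for (sc in connectomes) {
    if (nrow(sc$weights) != n) {
      stop_dmf("connectomes differ in size", class = "dmfconn_format_error")
    }
  }
  # element-wise mean over sorted values: exactly invariant to list order
  mean_sorted <- function(field) {
    arr <- vapply(connectomes, `[[`, matrix(0, n, n), field)
    apply(arr, c(1, 2), function(v) mean(sort(v)))
  }
  structural_connectome(mean_sorted("weights"), mean_sorted("lengths"),
                        connectomes[[1]]$parcellation)
}

#' Robust rescaling of a structural connectome
#'
#' For the weight and length matrices separately: over the nonzero entries,
#' the median is removed and the result scaled by the interquartile range
#' (robust to outlier streamline counts); negative scaled values are clipped
#' to 0 (the coupling term requires `C_ij >= 0`, so the weakest connections
#' are sparsified); finally every entry is rounded to the nearest even
#' integer, half-way cases rounding up. Zero entries (absent connections)
#' are untouched, the diagonal stays zero, and symmetry is preserved.
#'
#' @param sc a [structural_connectome()].
#' @return the rescaled [structural_connectome()]; all entries are even
#'   non-negative integers.
#' @export
robust_scale_connectome <- function(sc) {
  scale_one <- function(m, what) {
    nz <- m != 0
    v <- m[nz]
    if (length(v) == 0) {
      stop_dmf("%s has no nonzero entries", what,
               class = "dmfconn_degenerate_error")
    }
    iqr <- unname(diff(quantile(v, c(0.25, 0.75))))
    if (iqr <= 0) {
      stop_dmf("zero IQR over nonzero %s entries", what,
               class = "dmfconn_degenerate_error")
    }
    scaled <- (v - median(v)) / iqr
    scaled[scaled < 0] <- 0
    m[nz] <- round_even(scaled)
    m
  }
  w <- scale_one(sc$weights, "weights")
  l <- scale_one(sc$lengths, "lengths")
  # rounding can zero a weak connection's length while its weight survives;
  # keep the invariant lengths > 0 where weights > 0
  l[w > 0 & l == 0] <- 2
  structural_connectome(w, l, sc$parcellation)
}

#' Normalize connectome coupling strength
#'
#' Scales the weight matrix so the mean row strength is 1, the usual way a
#' coupling substrate is standardized before sweeping the global coupling
#' `G` (otherwise the interpretable range of `G` depends on the weight
#' units). Lengths are untouched.
#'
#' @param sc a [structural_connectome()].
#' @return the rescaled [structural_connectome()].
#' @export
normalize_coupling <- function(sc) {
  s <- mean(rowSums(sc$weights))
  if (s <= 0) {
    stop_dmf("connectome has no positive weights",
             class = "dmfconn_degenerate_error")
  }
  structural_connectome(sc$weights / s, sc$lengths, sc$parcellation)
}

#' Read a parcellated BOLD table
#'
#' @param path headerless TSV, samples in rows and regions in columns.
#' @param tr sampling interval (s).
#' @param subject_id identifier recorded on the series.
#' @param parcellation optional [parcellation()]; when given, the column
#'   count must match its region count.
#' @return a [bold_series()].
#' @export
read_bold <- function(path, tr, subject_id = basename(path),
                      parcellation = NULL) {
  m <- read_matrix_tsv(path)
  if (!is.null(parcellation) &&
      ncol(m) != length(parcellation$region_names)) {
    stop_dmf("BOLD has %d columns but parcellation has %d regions",
             ncol(m), length(parcellation$region_names),
             class = "dmfconn_format_error")
  }
  bold_series(m, tr, subject_id)
}

#' Write a BOLD series as a headerless TSV
#'
#' @param series a [bold_series()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bold <- function(series, path) {
  write_matrix_tsv(series$data, path)
  invisible(path)
}
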