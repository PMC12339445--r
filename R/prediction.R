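# Ridge-regression prediction of model outcomes from FC features with PCA
# reduction, nested cross-validation, and permutation feature importance.
#
# Pipeline per training set: standardize features -> PCA (minimal number of
# components explaining > pca_variance for edge features; all components for
# node features) -> ridge with the penalty picked by the inner CV. R^2 is
# the coefficient of determination on held-out data (can be negative; 0 is
# the constant-model baseline).

#' Prediction specification
#'
#' @param feature_kind `"edge_sfc"` or `"node_tc"`.
#' @param pca_variance explained-variance fraction for component selection
#'   (edge features use 0.90), or `NULL` to keep all components (node
#'   features).
#' @param alpha_grid ridge penalties; default 100 values log-spaced in
#'   `[0.01, 100]`.
#' @param outer_folds,outer_reps outer CV geometry (default 5 folds x 2
#'   repetitions).
#' @param inner_folds,inner_reps inner CV geometry (default 5 x 2).
#' @param seed integer seed controlling all fold shuffles.
#' @return an object of class `prediction_spec`.
#' @export
prediction_spec <- function(feature_kind = c("edge_sfc", "node_tc"),
                            pca_variance = if (feature_kind[1] == "edge_sfc")
                              0.90 else NULL,
                            alpha_grid = 10^seq(log10(0.01), log10(100),
                                                length.out = 100),
                            outer_folds = 5, outer_reps = 2,
                            inner_folds = 5, inner_reps = 2, seed = 1L) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(outer_folds >= 2, inner_folds >= 2,
            !is.unsorted(alpha_grid), all(alpha_grid > 0))
  structure(list(feature_kind = feature_kind, pca_variance = pca_variance,
                 alpha_grid = alpha_grid, outer_folds = outer_folds,
                 outer_reps = outer_reps, inner_folds = inner_folds,
                 inner_reps = inner_reps, seed = as.integer(seed)),
            class = "prediction_spec")
}

# closed-form ridge on centered scores: beta = (S'S + alpha I)^-1 S'y
ridge_solve <- function(S, y, alpha) {
  k <- ncol(S)
  solve(crossprod(S) + diag(alpha, k), crossprod(S, y))
}

r2_score <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

# standardize -> PCA -> ridge pipeline fitted on (X, y); returns a predictor
fit_pipeline <- function(X, y, alpha, pca_variance) {
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pca <- prcomp(Xs, center = FALSE, scale. = FALSE)
  k <- ncol(pca$rotation)
  if (!is.null(pca_variance)) {
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    k <- which(cum > pca_variance)[1]
  }
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  S <- Xs %*% rot
  ymu <- mean(y)
  beta <- ridge_solve(S, y - ymu, alpha)
  list(mu = mu, sds = sds, rot = rot, beta = beta, ymu = ymu, k = k)
}

predict_pipeline <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sds, "/")
  as.numeric(Xs %*% fit$rot %*% fit$beta) + fit$ymu
}

make_folds <- function(n, folds, reps, seed) {
  out <- list()
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, "folds", r))
    idx <- sample.int(n)
    assign_ <- rep(seq_len(folds), length.out = n)
    for (f in seq_len(folds)) {
      out[[length(out) + 1]] <- list(rep = r, fold = f,
                                     test = sort(idx[assign_ == f]))
    }
  }
  out
}

select_alpha <- function(X, y, spec, seed) {
  folds <- make_folds(nrow(X), spec$inner_folds, spec$inner_reps, seed)
  scores <- matrix(NA_real_, length(folds), length(spec$alpha_grid))
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]$test
    tr <- setdiff(seq_len(nrow(X)), te)
    fit0 <- fit_pipeline(X[tr, , drop = FALSE], y[tr], spec$alpha_grid[1],
                         spec$pca_variance)
    S_tr <- sweep(sweep(X[tr, , drop = FALSE], 2, fit0$mu), 2, fit0$sds,
                  "/") %*% fit0$rot
    S_te <- sweep(sweep(X[te, , drop = FALSE], 2, fit0$mu), 2, fit0$sds,
                  "/") %*% fit0$rot
    ytr <- y[tr] - fit0$ymu
    for (ai in seq_along(spec$alpha_grid)) {
      beta <- ridge_solve(S_tr, ytr, spec$alpha_grid[ai])
      yhat <- as.numeric(S_te %*% beta) + fit0$ymu
      scores[fi, ai] <- r2_score(y[te], yhat)
    }
  }
  spec$alpha_grid[which.max(colMeans(scores))]
}

#' Nested cross-validated ridge prediction
#'
#' The outer loop estimates the held-out coefficient of determination
#' `R^2 = 1 - SSE/SST`; the inner loop picks the ridge penalty by mean
#' inner-fold R^2. Standardization and PCA are fit on training portions
#' only. Deterministic given the spec's seed.
#'
#' @param features subjects x features matrix.
#' @param target numeric subject vector.
#' @param spec a [prediction_spec()].
#' @return list with `r2_mean`, `r2_sem` (over the outer folds x reps
#'   evaluations), `r2_values`, `alpha_chosen` per outer evaluation, and the
#'   full-data pipeline refit (`full_fit`, `full_alpha`) used by
#'   [permutation_importance()].
#' @export
ridge_nested_cv <- function(features, target, spec = prediction_spec()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 10) stop_dmf("need at least 10 subjects",
                       class = "dmfconn_value_error")
  if (length(target) != n) {
    stop_dmf("target length mismatch", class = "dmfconn_format_error")
  }
  if (sd(target) == 0) {
    stop_dmf("degenerate target variance", class = "dmfconn_value_error")
  }
  folds <- make_folds(n, spec$outer_folds, spec$outer_reps, spec$seed)
  r2 <- numeric(length(folds))
  alphas <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]$test
    tr <- setdiff(seq_len(n), te)
    alpha <- select_alpha(features[tr, , drop = FALSE], target[tr], spec,
                          derive_seed(spec$seed, "inner", fi))
    fit <- fit_pipeline(features[tr, , drop = FALSE], target[tr], alpha,
                        spec$pca_variance)
    yhat <- predict_pipeline(fit, features[te, , drop = FALSE])
    r2[fi] <- r2_score(target[te], yhat)
    alphas[fi] <- alpha
  }
  full_alpha <- select_alpha(features, target, spec,
                             derive_seed(spec$seed, "full"))
  full_fit <- fit_pipeline(features, target, full_alpha, spec$pca_variance)
  list(r2_mean = mean(r2), r2_sem = sd(r2) / sqrt(length(r2)),
       r2_values = r2, alpha_chosen = alphas,
       full_fit = full_fit, full_alpha = full_alpha)
}

#' Permutation feature importance
#'
#' With the full-data pipeline frozen (standardization, PCA rotation, ridge
#' coefficients), each original feature column is shuffled `n_perm` times;
#' its importance is the mean drop in full-data R^2. For edge features, a
#' per-region importance is the mean over the region's incident edges.
#'
#' @param features subjects x features matrix.
#' @param target numeric subject vector.
#' @param cv_result result of [ridge_nested_cv()] on the same data.
#' @param n_perm shuffles per feature (1000 at full scale).
#' @param seed integer seed.
#' @param n_regions region count (required to fold edge importances back to
#'   regions when `features` are edges), or `NULL`.
#' @return list with `importance` (per original feature) and
#'   `region_importance` (per region, or `NULL`).
#' @export
permutation_importance <- function(features, target, cv_result,
                                   n_perm = 1000L, seed = 1L,
                                   n_regions = NULL) {
  features <- as.matrix(features)
  fit <- cv_result$full_fit
  base_pred <- predict_pipeline(fit, features)
  base <- r2_score(target, base_pred)
  # the frozen pipeline is linear in the original features:
  # yhat = X %*% w + const with w = rot %*% beta scaled back by the sds,
  # so a shuffled column j shifts predictions by w_j * (x_perm - x_j)
  w <- as.numeric(fit$rot %*% fit$beta) / fit$sds
  imp <- numeric(ncol(features))
  n <- nrow(features)
  sst <- sum((target - mean(target))^2)
  for (j in seq_len(ncol(features))) {
    set.seed(derive_seed(seed, "importance", j))
    drop_acc <- 0
    xj <- features[, j]
    for (b in seq_len(n_perm)) {
      yhat <- base_pred + w[j] * (xj[sample.int(n)] - xj)
      drop_acc <- drop_acc + (base - (1 - sum((target - yhat)^2) / sst))
    }
    imp[j] <- drop_acc / n_perm
  }
  names(imp) <- colnames(features)
  region_importance <- NULL
  if (!is.null(n_regions)) {
    pairs <- upper_tri_pairs(n_regions)
    if (nrow(pairs) == ncol(features)) {
      region_importance <- vapply(seq_len(n_regions), function(i) {
        mean(imp[pairs[, 1] == i | pairs[, 2] == i])
      }, numeric(1))
    }
  }
  list(importance = imp, region_importance = region_importance)
}
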