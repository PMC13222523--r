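#' Shrink a covariance matrix toward its diagonal
#'
#' Returns `(1 - lambda) * cov + lambda * diag(cov) + epsilon * I`.
#' Shrinkage stabilizes off-diagonal structure estimated from limited
#' reference cells; the ridge guards exactly degenerate coordinates
#' (e.g. a feature constant within a reference subset), which shrinkage
#' alone cannot fix.
#'
#' @param cov symmetric d x d matrix.
#' @param lambda shrinkage weight in \[0, 1\].
#' @param epsilon nonnegative ridge added to the diagonal.
#' @return shrunk symmetric matrix; the diagonal changes only by `+epsilon`.
#' @export
shrink_covariance <- function(cov, lambda, epsilon = 0) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > 1e-9) {
    stop_scoor("covariance must be symmetric (tolerance 1e-9)")
  }
  if (!is_scalar_number(lambda) || lambda < 0 || lambda > 1) {
    stop_scoor("lambda must be in [0,1]")
  }
  if (!is_scalar_number(epsilon) || epsilon < 0) stop_scoor("epsilon must be >= 0")
  out <- (1 - lambda) * cov + lambda * diag(diag(cov), nrow = nrow(cov))
  out + diag(epsilon, nrow(cov))
}

#' Fit cluster-conditional reference distributions
#'
#' Estimates the mean vector and covariance matrix of the selected
#' uncertainty features over reference (control) cells. A global
#' mean/covariance is always fitted from all reference cells; when a
#' cluster column is configured, each cluster with at least
#' `config$min_cells` reference cells additionally gets its own
#' statistics, and smaller clusters fall back to the global ones
#' (`fallback_used = TRUE`). Covariances use the n-1 denominator and every
#' stored covariance (global and per-cluster) is shrunk with
#' [shrink_covariance()] for consistency.
#'
#' @param features feature table from [compute_feature_table()].
#' @param metadata aligned metadata with the configured condition column.
#' @param config a [run_config()] (fields `condition_column`,
#'   `reference_level`, `cluster_column`, `min_cells`, `shrinkage_lambda`,
#'   `ridge_epsilon`, `features` are used).
#' @return an `oor_reference` list: `feature_names`, `global` (mean, cov,
#'   n_ref), `per_cluster` (named list of mean/cov/n_ref/fallback_used),
#'   plus the fitting parameters.
#' @export
fit_reference <- function(features, metadata, config) {
  stopifnot(identical(features$cell_id, metadata$cell_id))
  fnames <- intersect(config$features, oor_feature_names())
  if (!length(fnames)) stop_scoor("empty feature selection for the reference model")
  d <- length(fnames)
  cond <- metadata[[config$condition_column]]
  if (is.null(cond)) {
    stop_scoor("metadata is missing required column(s): ", config$condition_column)
  }
  is_ref <- cond == config$reference_level
  if (!any(is_ref)) {
    stop_scoor("no reference cells: no row has ", config$condition_column,
               " == '", config$reference_level, "'")
  }
  X <- as.matrix(features[, fnames, drop = FALSE])
  Xr <- X[is_ref, , drop = FALSE]
  if (nrow(Xr) < d + 2L) {
    stop_scoor("need at least d + 2 = ", d + 2L, " reference cells globally, got ", nrow(Xr))
  }
  global <- fit_moments(Xr, config$shrinkage_lambda, config$ridge_epsilon)
  if (!is_positive_definite(global$cov)) {
    stop_scoor("global reference covariance is singular after shrinkage; ",
               "increase ridge_epsilon")
  }
  per_cluster <- list()
  if (!is.null(config$cluster_column)) {
    cl <- metadata[[config$cluster_column]]
    if (is.null(cl)) {
      stop_scoor("metadata is missing required column(s): ", config$cluster_column)
    }
    for (c_id in sort(unique(as.character(cl)))) {
      in_c <- is_ref & cl == c_id
      n_c <- sum(in_c)
      if (n_c >= config$min_cells) {
        mom <- fit_moments(X[in_c, , drop = FALSE],
                           config$shrinkage_lambda, config$ridge_epsilon)
        if (!is_positive_definite(mom$cov)) {
          warning("cluster '", c_id, "' covariance singular after shrinkage; ",
                  "using global fallback", call. = FALSE)
          mom <- global
          mom$fallback_used <- TRUE
        } else {
          mom$fallback_used <- FALSE
        }
        mom$n_ref <- n_c
      } else {
        mom <- global
        mom$n_ref <- n_c
        mom$fallback_used <- TRUE
      }
      per_cluster[[c_id]] <- mom
    }
  }
  structure(list(feature_names = fnames,
                 global = c(global, list(n_ref = nrow(Xr))),
                 per_cluster = per_cluster,
                 cluster_column = config$cluster_column,
                 min_cells = config$min_cells,
                 shrinkage_lambda = config$shrinkage_lambda,
                 ridge_epsilon = config$ridge_epsilon),
            class = "oor_reference")
}

fit_moments <- function(X, lambda, epsilon) {
  list(mean = colMeans(X),
       cov = shrink_covariance(stats::cov(X), lambda, epsilon))
}

is_positive_definite <- function(cov) {
  !inherits(tryCatch(chol(cov), error = function(e) e), "error")
}

#' Squared Mahalanobis distance of one feature vector
#'
#' `OOR = (x - mean)' cov^{-1} (x - mean)`, evaluated through a Cholesky
#' factorization and a triangular solve (no explicit inverse). The score
#' is scale-invariant: rescaling any feature together with its reference
#' statistics leaves it unchanged.
#'
#' @param x numeric d-vector.
#' @param mean reference mean d-vector.
#' @param cov symmetric positive-definite d x d reference covariance.
#' @return nonnegative scalar; 0 iff `x == mean`.
#' @export
oor_score <- function(x, mean, cov) {
  L <- tryCatch(chol(cov), error = function(e) {
    stop_scoor("covariance is not positive definite; apply shrinkage and/or a ridge")
  })
  z <- backsolve(L, x - mean, transpose = TRUE)
  sum(z^2)
}

#' Score every cell against its reference distribution
#'
#' All cells — reference and query alike — are scored against the stored
#' statistics of their cluster (or the global statistics when no cluster
#' column was configured). Cells in clusters absent from the model are
#' scored globally with a warning and flagged as fallback.
#'
#' @param features feature table (same feature subset the model was fitted
#'   on).
#' @param model an `oor_reference` from [fit_reference()].
#' @param metadata aligned metadata (only needed when the model is
#'   cluster-conditional).
#' @return data.frame with `cell_id`, `oor`, `cluster_used` (cluster id or
#'   "global"), `fallback_used`.
#' @export
score_all <- function(features, model, metadata = NULL) {
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  n <- nrow(X)
  oor <- numeric(n)
  cluster_used <- rep("global", n)
  fallback <- rep(FALSE, n)
  if (is.null(model$cluster_column) || !length(model$per_cluster)) {
    oor <- mahalanobis_batch(X, model$global$mean, model$global$cov)
  } else {
    stopifnot(!is.null(metadata), identical(features$cell_id, metadata$cell_id))
    cl <- as.character(metadata[[model$cluster_column]])
    unknown <- setdiff(unique(cl), names(model$per_cluster))
    if (length(unknown)) {
      warning("cluster(s) absent from the reference model, scored globally: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (c_id in unique(cl)) {
      idx <- which(cl == c_id)
      if (c_id %in% names(model$per_cluster)) {
        mom <- model$per_cluster[[c_id]]
        cluster_used[idx] <- c_id
        fallback[idx] <- mom$fallback_used
      } else {
        mom <- model$global
        mom$fallback_used <- TRUE
        fallback[idx] <- TRUE
      }
      oor[idx] <- mahalanobis_batch(X[idx, , drop = FALSE], mom$mean, mom$cov)
    }
  }
  data.frame(cell_id = features$cell_id, oor = oor,
             cluster_used = cluster_used, fallback_used = fallback,
             stringsAsFactors = FALSE)
}

# batched squared Mahalanobis via one Cholesky per reference
mahalanobis_batch <- function(X, mean, cov) {
  L <- tryCatch(chol(cov), error = function(e) {
    stop_scoor("covariance is not positive definite; apply shrinkage and/or a ridge")
  })
  Z <- backsolve(L, t(X) - mean, transpose = TRUE)
  colSums(Z^2)
}
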