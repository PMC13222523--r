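#' Construct and validate a run configuration
#'
#' Central configuration object for the end-to-end pipeline. All defaults
#' are the package defaults used throughout: hard threshold 0.5, no soft
#' threshold, raw (unnormalized) rows, minimum 50 reference cells per
#' cluster before the global covariance fallback, shrinkage lambda 0.1,
#' ridge 1e-8, all four uncertainty features, 0.9 tail quantile, binomial
#' test.
#'
#' @param prob_matrix,metadata,hierarchy input file paths (optional when
#'   the objects are passed to stages directly).
#' @param hard,soft,adaptive threshold settings, see [threshold_spec()].
#' @param soft_overrides_g0 see [threshold_spec()].
#' @param renormalize_rows logical; divide probability rows by their sums.
#' @param condition_column metadata column holding the condition.
#' @param reference_level value of `condition_column` marking reference
#'   (control) cells.
#' @param cluster_column optional metadata column for cluster-conditional
#'   references.
#' @param min_cells minimum reference cells for a cluster-specific
#'   covariance (below it the global reference is used as fallback).
#' @param shrinkage_lambda covariance shrinkage weight in \[0, 1\].
#' @param ridge_epsilon diagonal ridge added to every covariance.
#' @param features ordered subset of `c("P1","delta","admixture","entropy")`.
#' @param quantile reference-tail quantile for enrichment (in (0,1)).
#' @param test `"binomial"` or `"permutation"`.
#' @param n_permutations permutation count (when `test = "permutation"`).
#' @param seed integer seed for stochastic stages.
#' @param missing_label_policy `"error"` or `"own"` (each missing label
#'   becomes its own singleton lineage).
#' @param output_dir directory for [run_pipeline()] outputs.
#' @return a validated list of class `scoor_config`.
#' @export
run_config <- function(prob_matrix = NULL, metadata = NULL, hierarchy = NULL,
                       hard = 0.5, soft = NULL, adaptive = FALSE,
                       soft_overrides_g0 = TRUE,
                       renormalize_rows = FALSE,
                       condition_column = "condition",
                       reference_level = "control",
                       cluster_column = NULL,
                       min_cells = 50L,
                       shrinkage_lambda = 0.1,
                       ridge_epsilon = 1e-8,
                       features = c("P1", "delta", "admixture", "entropy"),
                       quantile = 0.9,
                       test = c("binomial", "permutation"),
                       n_permutations = 1000L,
                       seed = 1L,
                       missing_label_policy = c("error", "own"),
                       output_dir = NULL) {
  cfg <- list(
    prob_matrix = prob_matrix, metadata = metadata, hierarchy = hierarchy,
    hard = hard, soft = soft, adaptive = isTRUE(adaptive),
    soft_overrides_g0 = isTRUE(soft_overrides_g0),
    renormalize_rows = isTRUE(renormalize_rows),
    condition_column = condition_column,
    reference_level = reference_level,
    cluster_column = cluster_column,
    min_cells = as.integer(min_cells),
    shrinkage_lambda = shrinkage_lambda,
    ridge_epsilon = ridge_epsilon,
    features = features,
    quantile = quantile,
    test = match.arg(test),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    missing_label_policy = match.arg(missing_label_policy),
    output_dir = output_dir
  )
  class(cfg) <- "scoor_config"
  validate_config(cfg)
}

#' @rdname run_config
#' @param path YAML file; keys mirror the arguments of [run_config()]
#'   (nested sections `thresholds:`, `reference:` and `enrichment:` are
#'   flattened).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_scoor("config file not found: ", path)
  y <- yaml::read_yaml(path)
  nested <- c("thresholds", "reference", "enrichment", "normalization")
  flat <- c(y[setdiff(names(y), nested)],
            y[["thresholds"]], y[["reference"]],
            y[["enrichment"]], y[["normalization"]])
  known <- names(formals(run_config))
  unknown <- setdiff(names(flat), known)
  if (length(unknown)) stop_scoor("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, flat)
}

validate_config <- function(cfg) {
  if (!is_scalar_number(cfg$hard) || cfg$hard <= 0 || cfg$hard >= 1) {
    stop_scoor("hard threshold must be a number in (0,1)")
  }
  if (!is.null(cfg$soft)) {
    if (!is_scalar_number(cfg$soft) || cfg$soft <= 0 || cfg$soft >= cfg$hard) {
      stop_scoor("soft threshold must lie in (0, hard); got soft = ",
                 cfg$soft, ", hard = ", cfg$hard)
    }
  }
  if (!is_scalar_number(cfg$quantile) || cfg$quantile <= 0 || cfg$quantile >= 1) {
    stop_scoor("enrichment quantile must be in (0,1)")
  }
  if (!is_scalar_number(cfg$shrinkage_lambda) ||
      cfg$shrinkage_lambda < 0 || cfg$shrinkage_lambda > 1) {
    stop_scoor("shrinkage_lambda must be in [0,1]")
  }
  if (!is_scalar_number(cfg$ridge_epsilon) || cfg$ridge_epsilon < 0) {
    stop_scoor("ridge_epsilon must be >= 0")
  }
  if (cfg$min_cells < 1L) stop_scoor("min_cells must be >= 1")
  allowed <- c("P1", "delta", "admixture", "entropy")
  if (!length(cfg$features) || !all(cfg$features %in% allowed)) {
    stop_scoor("features must be a non-empty subset of: ", paste(allowed, collapse = ", "))
  }
  if (anyDuplicated(cfg$features)) stop_scoor("duplicate feature names in config")
  if (cfg$test == "permutation" && cfg$n_permutations < 100L) {
    stop_scoor("n_permutations must be >= 100")
  }
  cfg
}
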