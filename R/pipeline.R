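#' Run the full uncertainty / OOR pipeline
#'
#' Orchestrates read -> features -> classification -> reference fit ->
#' OOR scoring -> cluster summaries -> write. Identical inputs, config
#' and seed produce byte-identical output CSVs.
#'
#' @param config a [run_config()], or the path of a YAML file for
#'   [read_run_config()].
#' @return invisibly, the manifest list (config echo, input digests,
#'   per-stage timings, warnings, written paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "scoor_config"))
  if (is.null(config$prob_matrix) || is.null(config$output_dir)) {
    stop_scoor("config must set prob_matrix and output_dir")
  }
  warnings_seen <- character()
  note <- function(w) warnings_seen <<- c(warnings_seen, conditionMessage(w))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop_scoor("stage '", name, "' failed: ", conditionMessage(e))
      }),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  probs <- stage("read_probability_matrix",
                 read_probability_matrix(config$prob_matrix, config$renormalize_rows))
  row_sum_report <- attr(probs, "row_sum_report")
  hierarchy <- stage("read_hierarchy", read_hierarchy(config$hierarchy))
  required <- c(config$condition_column, config$cluster_column)
  metadata <- stage("read_metadata",
                    read_metadata(config$metadata, probs, required_columns = required))
  probs <- probs[metadata$cell_id, , drop = FALSE]

  features <- stage("features", compute_feature_table(probs))
  thresholds <- if (config$adaptive) {
    stage("suggest_thresholds",
          suggest_thresholds(features$P1,
                             soft_overrides_g0 = config$soft_overrides_g0))
  } else {
    threshold_spec(config$hard, config$soft,
                   soft_overrides_g0 = config$soft_overrides_g0)
  }
  cls <- stage("classify",
               classify_all(probs, thresholds, hierarchy,
                            missing_policy = config$missing_label_policy))
  model <- stage("fit_reference", fit_reference(features, metadata, config))
  scores <- stage("score", score_all(features, model, metadata))
  summaries <- stage("summarize", summarize_clusters(scores, metadata, config))

  manifest <- list(
    config = config[!vapply(config, is.null, logical(1))],
    seed = config$seed,
    thresholds = list(hard = thresholds$hard, soft = thresholds$soft,
                      adaptive = thresholds$adaptive),
    input_digests = as.list(tools::md5sum(
      c(config$prob_matrix, config$metadata, config$hierarchy))),
    group_fractions = as.list(cls$fractions),
    n_cells = nrow(probs),
    fallback_clusters = names(Filter(function(m) isTRUE(m$fallback_used),
                                     model$per_cluster)),
    skipped_clusters = attr(summaries, "skipped_clusters"),
    row_sum_report = as.list(row_sum_report),
    warnings = warnings_seen,
    timings = timings)
  paths <- stage("write",
                 write_results(config$output_dir, features, cls$groups,
                               scores, summaries, manifest))
  manifest$paths <- as.list(paths)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run --config config.yaml`, `classify --probs F
#' --hierarchy F --hard X [--soft X] [--out F]`, `score --probs F
#' --metadata F --ref-level L [--condition-col C] [--cluster-col C]
#' [--out F]`, `summarize --cells F --metadata F [--quantile X] [--test
#' binomial|permutation]`, `simulate --regime R --n N [--k K] --out DIR`.
#' Invoke as `Rscript -e 'scoor::cli_main()' <subcommand> ...` or through
#' the thin wrapper in `inst/cli/scoor.R`.
#'
#' @param args character vector of CLI arguments (defaults to the
#'   process's trailing command-line arguments).
#' @return exit status 0 on success (errors abort with nonzero status
#'   under Rscript).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: scoor <run|classify|score|summarize|simulate> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- parse_cli_options(args[-1L])
  switch(cmd,
    run = {
      run_pipeline(opts$config %||% stop_scoor("run needs --config"))
    },
    classify = {
      probs <- read_probability_matrix(opts$probs %||% stop_scoor("classify needs --probs"))
      hierarchy <- read_hierarchy(opts$hierarchy %||% stop_scoor("classify needs --hierarchy"))
      th <- threshold_spec(as.numeric(opts$hard %||% 0.5),
                           if (!is.null(opts$soft)) as.numeric(opts$soft))
      cls <- classify_all(probs, th, hierarchy)
      features <- compute_feature_table(probs)
      write_results(opts$out %||% ".", features, cls$groups)
    },
    score = {
      probs <- read_probability_matrix(opts$probs %||% stop_scoor("score needs --probs"))
      cfg <- run_config(condition_column = opts[["condition-col"]] %||% "condition",
                        reference_level = opts[["ref-level"]] %||% stop_scoor("score needs --ref-level"),
                        cluster_column = opts[["cluster-col"]])
      metadata <- read_metadata(opts$metadata %||% stop_scoor("score needs --metadata"),
                                probs,
                                required_columns = c(cfg$condition_column, cfg$cluster_column))
      probs <- probs[metadata$cell_id, , drop = FALSE]
      features <- compute_feature_table(probs)
      model <- fit_reference(features, metadata, cfg)
      scores <- score_all(features, model, metadata)
      write_results(opts$out %||% ".", features, scores = scores)
    },
    summarize = {
      cells <- utils::read.csv(opts$cells %||% stop_scoor("summarize needs --cells"),
                               stringsAsFactors = FALSE)
      if (is.null(cells$oor)) stop_scoor("cells file is missing the 'oor' column; run score first")
      meta <- utils::read.csv(opts$metadata %||% stop_scoor("summarize needs --metadata"),
                              stringsAsFactors = FALSE)
      cfg <- run_config(condition_column = opts[["condition-col"]] %||% "condition",
                        reference_level = opts[["ref-level"]] %||% "control",
                        cluster_column = opts[["cluster-col"]],
                        quantile = as.numeric(opts$quantile %||% 0.9),
                        test = opts$test %||% "binomial")
      meta <- meta[match(cells$cell_id, meta$cell_id), , drop = FALSE]
      oor <- data.frame(cell_id = cells$cell_id, oor = cells$oor,
                        stringsAsFactors = FALSE)
      s <- summarize_clusters(oor, meta, cfg)
      write_csv_precise(s, file.path(opts$out %||% ".", "clusters.csv"))
    },
    simulate = {
      ds <- simulate_condition_dataset(
        n_ref = as.integer(opts$n %||% 500L),
        n_query = as.integer(opts[["n-query"]] %||% opts$n %||% 500L),
        clusters = as.integer(opts$clusters %||% 1L),
        shift_sd = as.numeric(opts$shift %||% 0),
        K = as.integer(opts$k %||% 5L),
        seed = as.integer(opts$seed %||% 1L))
      write_simulated_dataset(ds, opts$out %||% stop_scoor("simulate needs --out"))
    },
    stop_scoor("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

# --flag value pairs (and bare --flag as TRUE) into a named list
parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_scoor("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
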