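#' Read a cells-by-labels probability matrix from CSV
#'
#' The CSV must carry the cell id in the first column and one column per
#' candidate label. Entries are per-class annotation probabilities in
#' \[0, 1\]. Per-class scores from one-vs-rest annotators frequently do not
#' sum to 1 across labels; by default rows are accepted as-is
#' (`renormalize = FALSE`) and a prominent warning is raised when any row
#' sum deviates from 1 by more than 1e-3. With `renormalize = TRUE` every
#' row with a positive sum is divided by that sum.
#'
#' Values marginally outside \[0, 1\] (within 1e-6, common from upstream
#' floating point) are clipped; anything further out is an error.
#'
#' @param path CSV file path.
#' @param renormalize logical; divide each row by its sum.
#' @return a numeric matrix with cell ids as rownames and label ids as
#'   colnames; attribute `"row_sum_report"` holds the min/max deviation of
#'   the raw row sums from 1 (for logging and the run manifest).
#' @export
read_probability_matrix <- function(path, renormalize = FALSE) {
  if (!file.exists(path)) stop_scoor("probability matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_scoor("probability matrix needs a cell-id column and at least 2 label columns")
  cell_ids <- as.character(df[[1L]])
  label_ids <- colnames(df)[-1L]
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop_scoor("non-numeric probability for cell '", cell_ids[bad],
                 "', label '", label_ids[j], "'")
    }
  }
  mat <- as.matrix(body)
  dimnames(mat) <- list(cell_ids, label_ids)
  validate_probability_matrix(mat)
  mat <- clip_unit_interval(mat)
  rs <- rowSums(mat)
  report <- c(min_deviation = min(rs) - 1, max_deviation = max(rs) - 1)
  if (renormalize) {
    pos <- rs > 0
    mat[pos, ] <- mat[pos, , drop = FALSE] / rs[pos]
  } else if (max(abs(rs - 1)) > 1e-3) {
    warning("probability rows deviate from sum 1 by up to ",
            signif(max(abs(rs - 1)), 3),
            "; raw per-class scores are used as-is (set renormalize = TRUE for distributions)",
            call. = FALSE)
  }
  attr(mat, "row_sum_report") <- report
  mat
}

# shared validation for in-memory matrices (used by readers and simulators)
validate_probability_matrix <- function(mat) {
  cell_ids <- rownames(mat)
  label_ids <- colnames(mat)
  if (is.null(cell_ids) || is.null(label_ids)) {
    stop_scoor("probability matrix must have cell ids (rownames) and label ids (colnames)")
  }
  if (anyDuplicated(cell_ids)) {
    stop_scoor("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(label_ids)) {
    stop_scoor("duplicate label ids: ", paste(unique(label_ids[duplicated(label_ids)]), collapse = ", "))
  }
  if (ncol(mat) < 2L) stop_scoor("at least 2 candidate labels are required")
  if (any(!is.finite(mat))) stop_scoor("probability matrix contains non-finite entries")
  if (min(mat) < -1e-6 || max(mat) > 1 + 1e-6) {
    bad <- which(mat < -1e-6 | mat > 1 + 1e-6, arr.ind = TRUE)[1L, ]
    stop_scoor("probability out of [0,1] beyond tolerance for cell '",
               cell_ids[bad[1L]], "', label '", label_ids[bad[2L]], "'")
  }
  if (any(rowSums(mat > 0) == 0L)) {
    bad <- which(rowSums(mat > 0) == 0L)[1L]
    stop_scoor("row with no positive probability (no identity signal): cell '",
               cell_ids[bad], "'")
  }
  invisible(mat)
}

clip_unit_interval <- function(mat) {
  mat[mat < 0] <- 0
  mat[mat > 1] <- 1
  mat
}

#' Read per-cell metadata and align it to a probability matrix
#'
#' Joins the metadata to the matrix on cell id (first column, or a column
#' named `cell_id`) and reorders rows to exactly match the matrix cell
#' order. Cells present on only one side are dropped with a warning; zero
#' overlap is an error.
#'
#' @param path CSV file path.
#' @param matrix probability matrix (rownames = cell ids).
#' @param required_columns character vector of column names that must be
#'   present (e.g. the configured condition column).
#' @return a data.frame with a `cell_id` column, aligned to the matrix.
#' @export
read_metadata <- function(path, matrix, required_columns = character()) {
  if (!file.exists(path)) stop_scoor("metadata file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  align_metadata(df, matrix, required_columns)
}

align_metadata <- function(df, matrix, required_columns = character()) {
  id_col <- if ("cell_id" %in% colnames(df)) "cell_id" else colnames(df)[1L]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop_scoor("duplicate cell ids in metadata: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing_cols <- setdiff(required_columns, colnames(df))
  if (length(missing_cols)) {
    stop_scoor("metadata is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  cells <- rownames(matrix)
  common <- intersect(cells, ids)
  if (!length(common)) stop_scoor("no overlapping cell ids between metadata and probability matrix")
  dropped <- c(setdiff(cells, ids), setdiff(ids, cells))
  if (length(dropped)) {
    warning(length(dropped), " cell id(s) present on only one side were dropped: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "",
            call. = FALSE)
  }
  keep <- cells[cells %in% ids]
  out <- df[match(keep, ids), , drop = FALSE]
  colnames(out)[colnames(out) == id_col] <- "cell_id"
  out$cell_id <- as.character(out$cell_id)
  rownames(out) <- NULL
  out
}

#' Read a label hierarchy from JSON
#'
#' The JSON maps each label to a record with `tissue` and `cell_class`;
#' two labels belong to the same lineage iff both coordinates match.
#'
#' @param path JSON file path.
#' @return a `label_hierarchy`: data.frame with columns `label`, `tissue`,
#'   `cell_class`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop_scoor("hierarchy file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_scoor("malformed hierarchy JSON: ", conditionMessage(e)))
  as_label_hierarchy(obj)
}

#' Build a label hierarchy from a named list
#'
#' @param entries named list, one record per label, each with `tissue` and
#'   `cell_class`.
#' @return a `label_hierarchy` data.frame.
#' @export
as_label_hierarchy <- function(entries) {
  if (!length(entries) || is.null(names(entries))) {
    stop_scoor("hierarchy must be a non-empty label -> {tissue, cell_class} mapping")
  }
  rows <- lapply(names(entries), function(lab) {
    e <- entries[[lab]]
    if (is.null(e$tissue) || is.null(e$cell_class)) {
      stop_scoor("hierarchy entry for label '", lab, "' lacks tissue or cell_class")
    }
    data.frame(label = lab, tissue = as.character(e$tissue),
               cell_class = as.character(e$cell_class),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$label)) stop_scoor("duplicate labels in hierarchy")
  class(out) <- c("label_hierarchy", "data.frame")
  out
}

#' Write classification, scoring and summary results to a directory
#'
#' Writes `cells.csv` (per-cell features, group, OOR score), `clusters.csv`
#' (per-cluster enrichment summaries) and `manifest.json` (config echo,
#' package version, warnings). Numeric values are written with 15
#' significant digits so a read-back reproduces them to better than 1e-12
#' relative.
#'
#' @param dir output directory (created if needed).
#' @param features feature table from [compute_feature_table()].
#' @param groups character vector of group labels aligned with the features.
#' @param scores OOR result data.frame from [score_all()], or `NULL`.
#' @param summaries cluster summary data.frame from [summarize_clusters()],
#'   or `NULL`.
#' @param manifest named list merged into `manifest.json`.
#' @return invisibly, a named character vector of written file paths.
#' @export
write_results <- function(dir, features, groups = NULL, scores = NULL,
                          summaries = NULL, manifest = list()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_scoor("cannot create output directory: ", dir)
  cells <- features
  if (!is.null(groups)) cells$group <- as.character(groups)
  if (!is.null(scores)) {
    stopifnot(identical(scores$cell_id, cells$cell_id))
    cells$oor <- scores$oor
    cells$cluster_used <- scores$cluster_used
    cells$fallback_used <- scores$fallback_used
  }
  paths <- c(cells = file.path(dir, "cells.csv"),
             clusters = file.path(dir, "clusters.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_csv_precise(cells, paths[["cells"]])
  cl <- if (is.null(summaries)) empty_cluster_summary() else summaries
  write_csv_precise(cl, paths[["clusters"]])
  manifest$package_version <- as.character(utils::packageVersion("scoor"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

# CSV writer with full double precision (15 significant digits)
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_scoor("cannot write ", path, ": ", conditionMessage(e))
  )
}

empty_cluster_summary <- function() {
  data.frame(cluster = character(), n_ref = integer(), n_query = integer(),
             median_ref = double(), median_query = double(),
             median_shift = double(), tail_quantile = double(),
             tail_threshold = double(), tail_fraction = double(),
             expected_fraction = double(), p_value = double(),
             q_value = double(), test = character(), fallback_used = logical(),
             stringsAsFactors = FALSE)
}
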