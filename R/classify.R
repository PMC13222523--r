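#' Threshold specification for group classification
#'
#' A hard threshold `T_h` defines confident label hits; an optional soft
#' threshold `T_s < T_h` captures weaker multi-identity signal. "Exceeds"
#' is inclusive (`>=`) by default so exact-threshold ties count as hits;
#' set `strict = TRUE` for strict comparison.
#'
#' @param hard hard threshold in (0,1).
#' @param soft soft threshold in (0, hard), or `NULL` to disable.
#' @param adaptive logical flag recording that the thresholds came from
#'   [suggest_thresholds()].
#' @param soft_overrides_g0 when `TRUE` (default), a cell with one hard hit
#'   but two or more soft hits is assigned to a soft multi-identity group
#'   (G2s/G3s) rather than G0.
#' @param strict use `>` instead of `>=` for threshold comparison.
#' @return a `threshold_spec` list.
#' @export
threshold_spec <- function(hard, soft = NULL, adaptive = FALSE,
                           soft_overrides_g0 = TRUE, strict = FALSE) {
  if (!is_scalar_number(hard) || hard <= 0 || hard >= 1) {
    stop_scoor("hard threshold must be in (0,1)")
  }
  if (!is.null(soft) && (!is_scalar_number(soft) || soft <= 0 || soft >= hard)) {
    stop_scoor("soft threshold must be in (0, hard)")
  }
  structure(list(hard = hard, soft = soft, adaptive = isTRUE(adaptive),
                 soft_overrides_g0 = isTRUE(soft_overrides_g0),
                 strict = isTRUE(strict)),
            class = "threshold_spec")
}

#' Labels whose probability exceeds a threshold
#'
#' @param row named probability vector.
#' @param threshold threshold in (0,1).
#' @param strict use `>` instead of the default inclusive `>=`.
#' @return character vector of hit labels, ordered by descending
#'   probability then ascending column index.
#' @export
count_hits <- function(row, threshold, strict = FALSE) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    stop_scoor("threshold must be in (0,1)")
  }
  labels <- names(row) %||% paste0("label", seq_along(row) - 1L)
  hit <- if (strict) row > threshold else row >= threshold
  idx <- which(hit)
  idx <- idx[order(-row[idx], idx)]
  labels[idx]
}

#' Do labels share one lineage?
#'
#' Two labels are same-lineage iff they agree on both hierarchy
#' coordinates (tissue and cell class).
#'
#' @param labels character vector, length >= 2.
#' @param hierarchy a `label_hierarchy` (see [read_hierarchy()]).
#' @param missing_policy `"error"` (default) or `"own"`: under `"own"` a
#'   label absent from the hierarchy forms its own singleton lineage
#'   (tissue = cell_class = label).
#' @return logical scalar.
#' @export
same_lineage <- function(labels, hierarchy, missing_policy = c("error", "own")) {
  missing_policy <- match.arg(missing_policy)
  if (length(labels) < 2L) stop_scoor("same_lineage needs at least 2 labels")
  idx <- match(labels, hierarchy$label)
  if (anyNA(idx)) {
    missing <- labels[is.na(idx)]
    if (missing_policy == "error") {
      stop_scoor("label(s) absent from hierarchy: ", paste(missing, collapse = ", "))
    }
    tissue <- ifelse(is.na(idx), labels, hierarchy$tissue[idx])
    cls <- ifelse(is.na(idx), labels, hierarchy$cell_class[idx])
  } else {
    tissue <- hierarchy$tissue[idx]
    cls <- hierarchy$cell_class[idx]
  }
  length(unique(tissue)) == 1L && length(unique(cls)) == 1L
}

#' Classify one cell into an identity-stability group
#'
#' Decision table (h = number of hard hits, s = number of soft hits; soft
#' hits include hard hits since `T_s < T_h`):
#' \itemize{
#'   \item h >= 2: G2 if all hard hits share a lineage, else G3.
#'   \item soft enabled, s >= 2, h <= 1 and (`soft_overrides_g0` or h = 0):
#'     G2s if all soft hits share a lineage, else G3s.
#'   \item h = 1 (not captured above): G0 — single confident identity.
#'   \item otherwise: G1 — no confident identity.
#' }
#' Lineage for the soft groups is evaluated over the full soft-hit set,
#' including the hard hit when present.
#'
#' @param row named probability vector.
#' @param thresholds a [threshold_spec()].
#' @param hierarchy a `label_hierarchy`.
#' @param missing_policy forwarded to [same_lineage()].
#' @return list with `group` (one of "G0","G1","G2","G2s","G3","G3s"),
#'   `hard_hits`, `soft_hits`, `lineage_consistent` (NA when no lineage
#'   comparison was needed).
#' @export
classify_cell <- function(row, thresholds, hierarchy,
                          missing_policy = c("error", "own")) {
  missing_policy <- match.arg(missing_policy)
  hard_hits <- count_hits(row, thresholds$hard, thresholds$strict)
  soft_hits <- if (!is.null(thresholds$soft)) {
    count_hits(row, thresholds$soft, thresholds$strict)
  } else {
    character()
  }
  h <- length(hard_hits)
  s <- length(soft_hits)
  lineage <- NA
  if (h >= 2L) {
    lineage <- same_lineage(hard_hits, hierarchy, missing_policy)
    group <- if (lineage) "G2" else "G3"
  } else if (!is.null(thresholds$soft) && s >= 2L &&
             (thresholds$soft_overrides_g0 || h == 0L)) {
    lineage <- same_lineage(soft_hits, hierarchy, missing_policy)
    group <- if (lineage) "G2s" else "G3s"
  } else if (h == 1L) {
    group <- "G0"
  } else {
    group <- "G1"
  }
  list(group = group, hard_hits = hard_hits, soft_hits = soft_hits,
       lineage_consistent = lineage)
}

#' Classify every cell of a probability matrix
#'
#' Vectorized over cells: hit counts are computed matrix-wise and the
#' lineage test runs only for cells with multi-hit patterns.
#'
#' @inheritParams classify_cell
#' @param matrix probability matrix (cells x labels).
#' @return list with `groups` (character vector, one entry per cell, named
#'   by cell id) and `fractions` (named fraction of each group among all
#'   cells; absent groups are 0).
#' @export
classify_all <- function(matrix, thresholds, hierarchy,
                         missing_policy = c("error", "own")) {
  validate_probability_matrix(matrix)
  missing_policy <- match.arg(missing_policy)
  cmp <- if (thresholds$strict) `>` else `>=`
  hardM <- cmp(matrix, thresholds$hard)
  h <- rowSums(hardM)
  soft_on <- !is.null(thresholds$soft)
  if (soft_on) {
    softM <- cmp(matrix, thresholds$soft)
    s <- rowSums(softM)
  } else {
    s <- rep(0L, nrow(matrix))
  }
  groups <- rep("G1", nrow(matrix))
  groups[h == 1L] <- "G0"
  multi_hard <- which(h >= 2L)
  for (i in multi_hard) {
    hits <- count_hits(matrix[i, ], thresholds$hard, thresholds$strict)
    groups[i] <- if (same_lineage(hits, hierarchy, missing_policy)) "G2" else "G3"
  }
  if (soft_on) {
    soft_cells <- which(h < 2L & s >= 2L &
                          (thresholds$soft_overrides_g0 | h == 0L))
    for (i in soft_cells) {
      hits <- count_hits(matrix[i, ], thresholds$soft, thresholds$strict)
      groups[i] <- if (same_lineage(hits, hierarchy, missing_policy)) "G2s" else "G3s"
    }
  }
  names(groups) <- rownames(matrix)
  all_groups <- c("G0", "G1", "G2", "G2s", "G3", "G3s")
  fractions <- table(factor(groups, levels = all_groups)) / length(groups)
  list(groups = groups, fractions = c(fractions))
}

#' Suggest thresholds from the P1 distribution
#'
#' Adaptive mode for datasets with heterogeneous confidence profiles: the
#' hard threshold is the Tukey lower fence of the top-probability (P1)
#' distribution, `Q1 - 1.5 * IQR`, clipped into \[0.05, 0.95\]; quartiles
#' use linear interpolation between order statistics (R's default type-7
#' convention). The soft threshold is `T_h / 2`, clipped into
#' \[0.01, T_h - 1e-6\].
#'
#' @param p1_values numeric vector of per-cell P1 values (length >= 4).
#' @param soft_overrides_g0,strict forwarded to [threshold_spec()].
#' @return a `threshold_spec` with `adaptive = TRUE`.
#' @export
suggest_thresholds <- function(p1_values, soft_overrides_g0 = TRUE, strict = FALSE) {
  p1_values <- p1_values[is.finite(p1_values)]
  if (length(p1_values) < 4L) stop_scoor("adaptive thresholds need >= 4 P1 values")
  qs <- stats::quantile(p1_values, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- qs[1L] - 1.5 * (qs[2L] - qs[1L])
  hard <- clip(fence, 0.05, 0.95)
  soft <- clip(hard / 2, 0.01, hard - 1e-6)
  threshold_spec(hard = hard, soft = soft, adaptive = TRUE,
                 soft_overrides_g0 = soft_overrides_g0, strict = strict)
}
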