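#' Uncertainty features of one probability row
#'
#' Derives the four uncertainty-aware features from a cell's per-class
#' probability vector:
#' \describe{
#'   \item{P1 (assurance)}{the largest probability, \eqn{P1 = \max_j P_j}.}
#'   \item{P2}{the second-largest probability; a duplicated maximum counts
#'     separately, so two labels tied at the top give \eqn{P2 = P1}.}
#'   \item{delta (confidence gap)}{\eqn{\Delta = P1 - P2}.}
#'   \item{admixture ratio}{\eqn{A = P2 / P1} (0 when \eqn{P1 = 0} cannot
#'     occur: an all-zero row is rejected).}
#'   \item{entropy}{normalized Shannon entropy
#'     \eqn{H = -\frac{1}{\log K}\sum_j p_j \log p_j} computed on the row
#'     renormalized to sum 1, with \eqn{0 \log 0 := 0}. The log base
#'     cancels against the \eqn{\log K} normalizer; natural logs are used.}
#' }
#' P1/P2/delta/admixture are computed on the raw values (they drive
#' thresholding against raw annotator scores); entropy is always a proper
#' distribution entropy of the renormalized row, so the two conventions
#' coincide whenever the row already sums to 1.
#'
#' @param row numeric vector of length K >= 2 with at least one positive
#'   entry; names, if present, are used as label ids.
#' @return a list with `P1`, `P2`, `delta`, `admixture`, `entropy`,
#'   `top_label`, `second_label`. Ties break toward the lower column index.
#' @examples
#' compute_features(c(A = 0.9, B = 0.05, C = 0.05))
#' @export
compute_features <- function(row) {
  if (length(row) < 2L) stop_scoor("at least 2 labels are required (entropy normalizer log K)")
  if (any(!is.finite(row)) || any(row < 0)) stop_scoor("probabilities must be finite and >= 0")
  if (all(row == 0)) stop_scoor("all-zero probability row: no identity signal")
  labels <- names(row) %||% paste0("label", seq_along(row) - 1L)
  i1 <- which.max(row)                       # first occurrence: lower index wins
  rest <- row
  rest[i1] <- -Inf
  i2 <- which.max(rest)
  p1 <- row[[i1]]
  p2 <- row[[i2]]
  list(P1 = p1, P2 = p2, delta = p1 - p2, admixture = p2 / p1,
       entropy = normalized_entropy(row),
       top_label = labels[i1], second_label = labels[i2])
}

# H on the renormalized row; entries below 1e-300 are exact zeros in x log x
normalized_entropy <- function(row) {
  p <- row / sum(row)
  nz <- p >= 1e-300
  -sum(p[nz] * log(p[nz])) / log(length(row))
}

#' Feature table for a whole probability matrix
#'
#' Vectorized row-wise application of [compute_features()]; one row per
#' cell, in the input order.
#'
#' @param matrix probability matrix (cells x labels, rownames = cell ids).
#' @return data.frame with columns `cell_id`, `P1`, `P2`, `delta`,
#'   `admixture`, `entropy`, `top_label`, `second_label`.
#' @export
compute_feature_table <- function(matrix) {
  validate_probability_matrix(matrix)
  zero_rows <- which(rowSums(matrix) == 0)
  if (length(zero_rows)) {
    stop_scoor("all-zero probability row: no identity signal for cell '",
               rownames(matrix)[zero_rows[1L]], "'")
  }
  K <- ncol(matrix)
  labels <- colnames(matrix)
  i1 <- max.col(matrix, ties.method = "first")
  p1 <- matrix[cbind(seq_len(nrow(matrix)), i1)]
  masked <- matrix
  masked[cbind(seq_len(nrow(matrix)), i1)] <- -Inf
  i2 <- max.col(masked, ties.method = "first")
  p2 <- matrix[cbind(seq_len(nrow(matrix)), i2)]
  p <- matrix / rowSums(matrix)
  plogp <- ifelse(p >= 1e-300, p * log(pmax(p, 1e-300)), 0)
  h <- -rowSums(plogp) / log(K)
  data.frame(cell_id = rownames(matrix),
             P1 = p1, P2 = p2, delta = p1 - p2, admixture = p2 / p1,
             entropy = h,
             top_label = labels[i1], second_label = labels[i2],
             stringsAsFactors = FALSE)
}

# features actually usable for OOR scoring
oor_feature_names <- function() c("P1", "delta", "admixture", "entropy")
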