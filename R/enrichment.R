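#' Median OOR shift between conditions
#'
#' `median(query) - median(ref)`; medians use the midpoint-of-two-central-
#' values convention for even n (R's default).
#'
#' @param ref_scores,query_scores nonempty numeric vectors.
#' @return scalar shift.
#' @export
median_shift <- function(ref_scores, query_scores) {
  if (!length(ref_scores) || !length(query_scores)) {
    stop_scoor("median_shift needs nonempty score vectors")
  }
  stats::median(query_scores) - stats::median(ref_scores)
}

#' Tail enrichment of query scores over the reference distribution
#'
#' The tail threshold is the interpolated (type-7) `q`-quantile of the
#' reference scores; the tail fraction is the share of query scores
#' strictly exceeding it (strict `>`, so threshold ties are excluded).
#'
#' @param ref_scores nonempty reference score vector.
#' @param query_scores nonempty query score vector.
#' @param q tail quantile in (0,1), e.g. 0.9.
#' @return list with `tail_threshold`, `tail_fraction`, `k_exceed`,
#'   `n_query`.
#' @export
tail_enrichment <- function(ref_scores, query_scores, q) {
  if (!is_scalar_number(q) || q <= 0 || q >= 1) stop_scoor("q must be in (0,1)")
  if (!length(ref_scores)) stop_scoor("empty reference score vector")
  if (!length(query_scores)) stop_scoor("empty query score vector")
  thr <- stats::quantile(ref_scores, q, type = 7, names = FALSE)
  k <- sum(query_scores > thr)
  list(tail_threshold = thr, tail_fraction = k / length(query_scores),
       k_exceed = k, n_query = length(query_scores))
}

#' One-sided binomial test of tail exceedance
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, evaluated
#' through the stable survival form `pbinom(k - 1, n, p0, lower.tail =
#' FALSE)`. `p0` is the nominal reference exceedance rate `1 - q`.
#'
#' @param k_exceed observed exceedance count (0 <= k <= n).
#' @param n_query number of query cells.
#' @param p0 null exceedance probability in (0,1).
#' @return p-value in (0, 1\].
#' @export
binomial_tail_test <- function(k_exceed, n_query, p0) {
  if (!is_scalar_number(k_exceed) || !is_scalar_number(n_query) ||
      k_exceed < 0 || n_query < 1 || k_exceed > n_query) {
    stop_scoor("need 0 <= k_exceed <= n_query with n_query >= 1")
  }
  if (!is_scalar_number(p0) || p0 <= 0 || p0 >= 1) stop_scoor("p0 must be in (0,1)")
  # extreme counts underflow the survival function; keep p strictly positive
  max(stats::pbinom(k_exceed - 1, n_query, p0, lower.tail = FALSE),
      .Machine$double.xmin)
}

#' Permutation test of tail exceedance
#'
#' Pools reference and query scores, relabels them uniformly at random `B`
#' times preserving the two group sizes, recomputes the tail fraction for
#' each relabeling, and returns the add-one p-value
#' `(1 + #\{permuted >= observed\}) / (1 + B)` (never exactly zero).
#' Exchangeability of the pooled scores is the exact null, so the test is
#' valid even though the tail threshold is re-estimated from each permuted
#' reference.
#'
#' @inheritParams tail_enrichment
#' @param B number of permutations (>= 100).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return p-value in \[1/(1+B), 1\].
#' @export
permutation_tail_test <- function(ref_scores, query_scores, q, B = 1000L, seed = 1L) {
  if (B < 100L) stop_scoor("B must be >= 100")
  obs <- tail_enrichment(ref_scores, query_scores, q)$tail_fraction
  pooled <- c(ref_scores, query_scores)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled scores identical; permutation p-value set to 1", call. = FALSE)
    return(1)
  }
  n_ref <- length(ref_scores)
  n_tot <- length(pooled)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n_tot, n_ref)
      perm <- tail_enrichment(pooled[idx], pooled[-idx], q)$tail_fraction
      if (perm >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + B)
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up construction: sort p-values ascending, set
#' `q_(i) = min_{j >= i} m * p_(j) / j`, cap at 1, return in the original
#' order.
#'
#' @param p_values numeric vector with entries in (0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_scoor("p-values must lie in (0,1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  scaled <- m * p_values[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Per-cluster OOR summaries with enrichment tests
#'
#' For each cluster containing at least one reference and one query cell:
#' the median OOR shift (query minus reference), the fraction of query
#' cells beyond the reference `q`-quantile, a p-value from the configured
#' test (binomial against the nominal exceedance `1 - q`, or permutation),
#' and BH q-values computed across the reported clusters. Without a
#' cluster column all cells form one pseudo-cluster `"all"`. Clusters
#' lacking one of the conditions are skipped and listed in the
#' `"skipped_clusters"` attribute (surfaced in the run manifest).
#'
#' @param oor OOR result from [score_all()].
#' @param metadata aligned metadata with the condition (and optionally
#'   cluster) column.
#' @param config a [run_config()]; fields `condition_column`,
#'   `reference_level`, `cluster_column`, `quantile`, `test`,
#'   `n_permutations`, `seed` are used.
#' @param in_sample_p0 use the in-sample reference exceedance fraction as
#'   the binomial null instead of the nominal `1 - q`.
#' @return data.frame, one row per reported cluster (see `clusters.csv`
#'   columns in [write_results()]).
#' @export
summarize_clusters <- function(oor, metadata, config, in_sample_p0 = FALSE) {
  stopifnot(identical(oor$cell_id, metadata$cell_id))
  cond <- metadata[[config$condition_column]]
  if (is.null(cond)) {
    stop_scoor("metadata is missing required column(s): ", config$condition_column)
  }
  is_ref <- cond == config$reference_level
  cl <- if (is.null(config$cluster_column)) {
    rep("all", nrow(metadata))
  } else {
    as.character(metadata[[config$cluster_column]])
  }
  q <- config$quantile
  rows <- list()
  skipped <- character()
  for (c_id in sort(unique(cl))) {
    in_c <- cl == c_id
    ref_scores <- oor$oor[in_c & is_ref]
    query_scores <- oor$oor[in_c & !is_ref]
    if (!length(ref_scores) || !length(query_scores)) {
      skipped <- c(skipped, c_id)
      next
    }
    te <- tail_enrichment(ref_scores, query_scores, q)
    p <- if (config$test == "binomial") {
      p0 <- if (in_sample_p0) {
        max(mean(ref_scores > te$tail_threshold), 1 / (length(ref_scores) + 1))
      } else {
        1 - q
      }
      binomial_tail_test(te$k_exceed, te$n_query, p0)
    } else {
      permutation_tail_test(ref_scores, query_scores, q,
                            B = config$n_permutations,
                            seed = config$seed + match(c_id, sort(unique(cl))))
    }
    fb <- any(oor$fallback_used[in_c])
    rows[[c_id]] <- data.frame(
      cluster = c_id, n_ref = length(ref_scores), n_query = length(query_scores),
      median_ref = stats::median(ref_scores),
      median_query = stats::median(query_scores),
      median_shift = median_shift(ref_scores, query_scores),
      tail_quantile = q, tail_threshold = te$tail_threshold,
      tail_fraction = te$tail_fraction, expected_fraction = 1 - q,
      p_value = p, q_value = NA_real_, test = config$test,
      fallback_used = fb, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_scoor("no cluster contains both reference and query cells")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_value)
  attr(out, "skipped_clusters") <- skipped
  out
}
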