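# Seeded Dirichlet simulator for probability matrices with known truth.
# Rows are compositional, so Dirichlet mixtures are the natural generative
# family; the packaged concentrations put each regime well inside its
# group's decision region (see the methods vignette for the margins).

# regime -> Dirichlet concentration defaults (K labels)
regime_concentrations <- function(regime, K) {
  switch(regime,
    stable = c(50, rep(0.1, K - 1L)),                # one dominant identity
    diffuse = rep(10, K),                            # symmetric, no winner
    within_lineage_bimodal = ,
    cross_lineage_bimodal = c(60, 60, rep(0.1, K - 2L)),  # two co-dominant
    stop_scoor("unknown regime: ", regime)
  )
}

regime_truth_group <- function(regime) {
  c(stable = "G0", diffuse = "G1",
    within_lineage_bimodal = "G2", cross_lineage_bimodal = "G3")[[regime]]
}

#' Two-lineage example hierarchy
#'
#' Labels `L1..LK`; the first `ceiling(K/2)` labels share lineage
#' (tissue "tissueA", class "classA"), the rest share a second lineage.
#'
#' @param K number of labels (>= 2).
#' @return a `label_hierarchy`.
#' @export
example_hierarchy <- function(K = 5L) {
  labs <- paste0("L", seq_len(K))
  half <- ceiling(K / 2)
  as_label_hierarchy(stats::setNames(lapply(seq_len(K), function(i) {
    if (i <= half) list(tissue = "tissueA", cell_class = "classA")
    else list(tissue = "tissueB", cell_class = "classB")
  }), labs))
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate a probability matrix from a named uncertainty regime
#'
#' Rows are Dirichlet draws whose concentrations encode the regime:
#' `stable` (one dominant label, truth G0), `diffuse` (symmetric, truth
#' G1), `within_lineage_bimodal` / `cross_lineage_bimodal` (two
#' co-dominant labels chosen within or across hierarchy lineages, truth
#' G2 / G3). For each cell the pair of dominant labels (or the single
#' dominant label) is drawn uniformly from the eligible label positions.
#'
#' @param regime one of `"stable"`, `"diffuse"`,
#'   `"within_lineage_bimodal"`, `"cross_lineage_bimodal"`.
#' @param n_cells number of cells.
#' @param K number of candidate labels (>= 2).
#' @param hierarchy a `label_hierarchy` covering K labels; defaults to
#'   [example_hierarchy()]. Cross-lineage regimes need >= 2 lineages.
#' @param seed integer seed; identical calls are bit-reproducible.
#' @param concentrations optional length-K override of the regime
#'   concentrations (position 1 = dominant, 2 = co-dominant).
#' @return list with `matrix` (n_cells x K, rownames `cell1..`, colnames
#'   from the hierarchy), `truth` (expected group per cell) and `regime`.
#' @export
simulate_matrix <- function(regime, n_cells, K = 5L, hierarchy = example_hierarchy(K),
                            seed = 1L, concentrations = NULL) {
  if (n_cells < 1L || K < 2L) stop_scoor("need n_cells >= 1 and K >= 2")
  if (nrow(hierarchy) < K) stop_scoor("hierarchy must cover all K labels")
  labs <- hierarchy$label[seq_len(K)]
  lineage <- paste(hierarchy$tissue, hierarchy$cell_class)[seq_len(K)]
  alpha <- concentrations %||% regime_concentrations(regime, K)
  if (length(alpha) != K || any(alpha <= 0)) stop_scoor("concentrations must be K positive reals")

  pairs_within <- which(outer(lineage, lineage, "==") & upper.tri(diag(K)), arr.ind = TRUE)
  pairs_cross <- which(outer(lineage, lineage, "!=") & upper.tri(diag(K)), arr.ind = TRUE)
  if (regime == "cross_lineage_bimodal" && !nrow(pairs_cross)) {
    stop_scoor("cross-lineage regime needs a hierarchy with >= 2 lineages")
  }
  if (regime == "within_lineage_bimodal" && !nrow(pairs_within)) {
    stop_scoor("within-lineage regime needs >= 2 labels sharing a lineage")
  }

  mat <- with_seed(seed, {
    out <- matrix(0, n_cells, K)
    if (regime == "stable") {
      top <- sample.int(K, n_cells, replace = TRUE)
      draws <- rdirichlet(n_cells, alpha)
      for (i in seq_len(n_cells)) {
        perm <- c(top[i], setdiff(seq_len(K), top[i]))
        out[i, perm] <- draws[i, ]
      }
    } else if (regime == "diffuse") {
      out <- rdirichlet(n_cells, alpha)
    } else {
      pairs <- if (regime == "within_lineage_bimodal") pairs_within else pairs_cross
      pick <- sample.int(nrow(pairs), n_cells, replace = TRUE)
      draws <- rdirichlet(n_cells, alpha)
      for (i in seq_len(n_cells)) {
        pr <- pairs[pick[i], ]
        perm <- c(pr[1L], pr[2L], setdiff(seq_len(K), pr))
        out[i, perm] <- draws[i, ]
      }
    }
    out
  })
  dimnames(mat) <- list(paste0("cell", seq_len(n_cells)), labs)
  list(matrix = mat, truth = rep(regime_truth_group(regime), n_cells),
       regime = regime)
}

#' Simulate a two-condition dataset with a calibrated feature shift
#'
#' Reference cells come from the stable regime. Query cells start from the
#' same regime; an `affected_fraction` of them is blended toward the
#' uniform distribution, `row' = (1 - w) row + w / K`, with the blending
#' weight `w` calibrated by bisection (on an independent, seed-derived
#' calibration sample) so that the mean of the first target feature shifts
#' by `shift_sd` reference standard deviations. `shift_sd = 0` leaves the
#' two arms exchangeable.
#'
#' @param n_ref,n_query cells per arm.
#' @param clusters number of clusters; cells are assigned round-robin so
#'   cluster proportions are equal within each arm.
#' @param shift_features character subset of
#'   `c("P1","delta","admixture","entropy")`; calibration targets the
#'   first.
#' @param shift_sd requested mean shift magnitude in reference-SD units.
#' @param affected_fraction fraction of query cells perturbed, in \[0,1\].
#' @param K,seed as in [simulate_matrix()].
#' @return list with `matrix` (probability matrix over both arms),
#'   `metadata` (cell_id, condition in `"control"`/`"case"`, cluster),
#'   `hierarchy`, and the calibrated blending weight `w`.
#' @export
simulate_condition_dataset <- function(n_ref, n_query, clusters = 1L,
                                       shift_features = "entropy",
                                       shift_sd = 0, affected_fraction = 1,
                                       K = 5L, seed = 1L) {
  if (n_ref < 1L || n_query < 1L) stop_scoor("need n_ref >= 1 and n_query >= 1")
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop_scoor("affected_fraction must be in [0,1]")
  }
  bad <- setdiff(shift_features, oor_feature_names())
  if (length(bad)) {
    stop_scoor("shift target(s) not among the configured features: ",
               paste(bad, collapse = ", "))
  }
  hierarchy <- example_hierarchy(K)
  ref <- simulate_matrix("stable", n_ref, K, hierarchy, seed = seed)
  qry <- simulate_matrix("stable", n_query, K, hierarchy, seed = seed + 1L)
  w <- 0
  if (shift_sd != 0) {
    w <- calibrate_blend_weight(shift_features[1L], abs(shift_sd), K, seed + 2L)
  }
  mat_q <- qry$matrix
  if (w > 0 && affected_fraction > 0) {
    n_aff <- round(affected_fraction * n_query)
    aff <- with_seed(seed + 3L, sample.int(n_query, n_aff))
    mat_q[aff, ] <- (1 - w) * mat_q[aff, , drop = FALSE] + w / K
  }
  mat <- rbind(ref$matrix, mat_q)
  rownames(mat) <- c(paste0("ref", seq_len(n_ref)), paste0("query", seq_len(n_query)))
  metadata <- data.frame(
    cell_id = rownames(mat),
    condition = rep(c("control", "case"), c(n_ref, n_query)),
    cluster = paste0("c", c(seq_len(n_ref) %% clusters, seq_len(n_query) %% clusters) + 1L),
    stringsAsFactors = FALSE)
  list(matrix = mat, metadata = metadata, hierarchy = hierarchy, w = w)
}

# bisection on an independent stable calibration sample: find blend weight
# w such that the mean target feature moves by `target_sd` reference SDs
calibrate_blend_weight <- function(feature, target_sd, K, seed, n_cal = 2000L) {
  cal <- simulate_matrix("stable", n_cal, K, example_hierarchy(K), seed = seed)$matrix
  base <- compute_feature_table(cal)[[feature]]
  mu0 <- mean(base)
  sd0 <- stats::sd(base)
  shift_at <- function(w) {
    blended <- (1 - w) * cal + w / K
    abs(mean(compute_feature_table(blended)[[feature]]) - mu0) / sd0
  }
  if (shift_at(1) < target_sd) {
    stop_scoor("requested shift of ", target_sd, " SD on '", feature,
               "' is not attainable by blending toward uniform")
  }
  lo <- 0; hi <- 1
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    if (shift_at(mid) < target_sd) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Split a cell's top probability toward a donor label
#'
#' Counterfactual label-redundancy probe: the top label keeps `alpha * p`
#' of its probability `p` and the donor label gains `(1 - alpha) * p`;
#' every other entry — and the row total — is unchanged exactly.
#'
#' @param row named probability vector.
#' @param alpha retained fraction in (0, 1\]; `alpha = 1` is the identity.
#' @param donor_label donor label id; defaults to the label with the
#'   second-highest probability. Must differ from the top label.
#' @return the modified row.
#' @export
split_top_probability <- function(row, alpha, donor_label = NULL) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    stop_scoor("alpha must be in (0,1]")
  }
  labels <- names(row) %||% paste0("label", seq_along(row) - 1L)
  names(row) <- labels
  i_top <- which.max(row)
  if (is.null(donor_label)) {
    rest <- row; rest[i_top] <- -Inf
    donor_label <- labels[which.max(rest)]
  }
  i_donor <- match(donor_label, labels)
  if (is.na(i_donor)) stop_scoor("donor label '", donor_label, "' not found")
  if (i_donor == i_top) stop_scoor("donor label must differ from the top label")
  p <- row[[i_top]]
  row[[i_top]] <- alpha * p
  row[[i_donor]] <- row[[i_donor]] + (1 - alpha) * p
  row
}

#' Write simulated fixtures to disk
#'
#' Emits `probabilities.csv`, `metadata.csv` and `hierarchy.json` in the
#' package's on-disk formats, directly consumable by the pipeline.
#'
#' @param dataset a list from [simulate_condition_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_scoor("cannot create directory: ", dir)
  }
  paths <- c(probs = file.path(dir, "probabilities.csv"),
             metadata = file.path(dir, "metadata.csv"),
             hierarchy = file.path(dir, "hierarchy.json"))
  probs <- data.frame(cell_id = rownames(dataset$matrix),
                      dataset$matrix, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write_csv_precise(probs, paths[["probs"]])
  utils::write.csv(dataset$metadata, paths[["metadata"]], row.names = FALSE, quote = FALSE)
  h <- dataset$hierarchy
  entries <- stats::setNames(lapply(seq_len(nrow(h)), function(i) {
    list(tissue = h$tissue[i], cell_class = h$cell_class[i])
  }), h$label)
  jsonlite::write_json(entries, paths[["hierarchy"]], auto_unbox = TRUE)
  invisible(paths)
}
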