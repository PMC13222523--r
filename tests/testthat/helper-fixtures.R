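# Shared fixtures and independent oracles for the test suite.

make_prob_matrix <- function(values, cells = NULL, labels = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(values) / length(labels), byrow = TRUE)
  rownames(m) <- cells %||% paste0("cell", seq_len(nrow(m)))
  colnames(m) <- labels %||% paste0("L", seq_len(ncol(m)))
  m
}

write_prob_csv <- function(mat, path = tempfile(fileext = ".csv")) {
  df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_hierarchy_json <- function(entries, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(entries, path, auto_unbox = TRUE)
  path
}

two_lineage_hierarchy <- function() {
  as_label_hierarchy(list(
    L1 = list(tissue = "tA", cell_class = "cA"),
    L2 = list(tissue = "tA", cell_class = "cA"),
    L3 = list(tissue = "tB", cell_class = "cB"),
    L4 = list(tissue = "tB", cell_class = "cB")))
}

truth_table_path <- function() system.file("extdata", "truth_table.csv", package = "scoor")
truth_hierarchy_path <- function() system.file("extdata", "truth_hierarchy.json", package = "scoor")

# independent oracle: squared Mahalanobis by explicit matrix inversion
oracle_mahalanobis <- function(x, mu, sigma) {
  d <- x - mu
  as.numeric(t(d) %*% solve(sigma) %*% d)
}

# independent oracle: BH step-up by evaluating all m*p_(j)/j and suffix minima
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- m * p[ord] / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# independent oracle: normalized entropy by direct hand-style summation
oracle_entropy <- function(p) {
  K <- length(p)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(K)
}

# random SPD matrix of dimension d
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.05
}

# simulated dataset + YAML config on disk, ready for run_pipeline()
make_run_dir <- function(n = 120, clusters = 2, shift = 1, seed = 7, soft = 0.3) {
  dir <- tempfile()
  ds <- simulate_condition_dataset(n, n, clusters = clusters, shift_sd = shift,
                                   shift_features = "entropy", seed = seed)
  write_simulated_dataset(ds, dir)
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    prob_matrix = file.path(dir, "probabilities.csv"),
    metadata = file.path(dir, "metadata.csv"),
    hierarchy = file.path(dir, "hierarchy.json"),
    soft = soft,
    reference = list(condition_column = "condition", reference_level = "control",
                     cluster_column = "cluster", min_cells = 50),
    output_dir = file.path(dir, "out")), cfg)
  list(dir = dir, config = cfg)
}

# gaussian pseudo feature table (columns named like the real features)
gaussian_features <- function(n, L, prefix = "c") {
  X <- matrix(stats::rnorm(n * 4), ncol = 4) %*% L
  data.frame(cell_id = paste0(prefix, seq_len(n)),
             P1 = X[, 1], delta = X[, 2], admixture = X[, 3], entropy = X[, 4],
             stringsAsFactors = FALSE)
}
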