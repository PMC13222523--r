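Package: scoor
Title: Annotation-Uncertainty Features and Out-of-Reference Scoring for
    Single-Cell Label Transfer
Version: 0.1.0
Authors@R:
    person("scoor", "developers", email = "scoor@example.org", role = c("aut", "cre"))
Description: Post-processes probabilistic cell-type annotation output
    (e.g. per-class probability matrices from reference-based label
    transfer) into a multivariate uncertainty representation: assurance
    (top probability), confidence gap, admixture ratio and normalized
    entropy. Cells are classified into identity-stability groups
    (G0-G3, with soft variants) using threshold logic over a label
    hierarchy, and each cell's deviation from a control population is
    quantified as a covariance-aware out-of-reference (OOR) score, the
    squared Mahalanobis distance in uncertainty-feature space under a
    shrunk, cluster-conditional reference covariance. Cluster-level
    enrichment of high-OOR cells is tested against the reference
    empirical null with binomial or permutation tests and
    Benjamini-Hochberg correction. Includes a seeded Dirichlet
    simulator for probability matrices with known ground truth and a
    YAML-configured end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
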