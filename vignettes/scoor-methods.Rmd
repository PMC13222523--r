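---
title: "Methods: uncertainty features, identity-stability groups, and out-of-reference scores"
author: "scoor developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty features, identity-stability groups, and out-of-reference scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoor)
```

# The model

`scoor` treats the probability distribution an annotation classifier
assigns to each cell not as a quality-control nuisance but as a
measurement. Three layers build on one another:

1. **Uncertainty features.** Each cell's probability row is compressed
   into assurance $P1 = \max_j P_{ij}$, the second-best probability
   $P2$, the confidence gap $\Delta = P1 - P2$, the admixture ratio
   $A = P2/P1$, and the normalized entropy
   $H = -\tfrac{1}{\log K}\sum_j p_j \log p_j$. These four coordinates
   ($P2$ is redundant given $P1$ and $\Delta$) capture complementary
   failure modes: a uniformly unsure cell (high $H$, low $P1$), a
   two-way torn cell (high $A$, low $\Delta$, moderate $H$), and a
   confident cell (high $P1$, everything else low).
2. **Discrete groups.** Counting labels above a hard threshold $T_h$
   (optionally a soft threshold $T_s < T_h$) and comparing the hit set's
   lineage coordinates (tissue, cell class) in a user-editable hierarchy
   yields G0 (one confident identity), G1 (none), G2/G3 (several, within
   one / across several lineages), and soft variants G2s/G3s.
3. **Out-of-reference score.** In the feature space
   $x = (P1, \Delta, A, H)$, control cells (wild-type, untreated, a
   designated reference level of a condition column) define per-cluster
   Gaussians $(\mu_c, \Sigma_c)$; every cell is scored by the squared
   Mahalanobis distance
   $\mathrm{OOR}_i = (x_i-\mu_c)^\top \Sigma_c^{-1} (x_i-\mu_c)$, which
   is scale-invariant and accounts for the strong correlations among the
   features. Cluster summaries compare conditions by the median OOR
   shift and the tail fraction beyond the reference $q$-quantile, with
   binomial or permutation significance and BH correction across
   clusters.

# Assumptions

- The probability matrix is taken as given; no attempt is made to rerun
  or recalibrate the upstream annotator. Miscalibrated annotators shift
  all cells equally and largely cancel in reference-relative scores.
- The reference population is assumed to be adequately described by its
  first two moments per cluster. OOR is a deviation score, not a
  likelihood; under multivariate normality of reference features it
  would be $\chi^2_d$, and that case anchors the calibration tests, but
  real uncertainty features are bounded and skewed, which is why
  significance is assessed against the *empirical* reference
  distribution (tail quantile) rather than against $\chi^2$.
- Lineage comparisons require only a two-coordinate hierarchy; both
  coordinates must match for two labels to be "the same lineage".

# Key parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `hard` ($T_h$) | 0.5 | probability | a majority-style cutoff: at most one label of a proper distribution can exceed it, only raw one-vs-rest scores can produce hard multi-identity groups |
| `soft` ($T_s$) | off (0.3 typical) | probability, $< T_h$ | catches competing labels that are individually below confidence |
| `min_cells` | 50 | reference cells per cluster | below this a 4×4 covariance is too noisy; the global reference is used as fallback |
| `shrinkage_lambda` | 0.1 | in $[0,1]$ | pulls off-diagonals toward a diagonal covariance; applied to every stored covariance (global and per-cluster) for consistency |
| `ridge_epsilon` | 1e-8 | added to the diagonal | rescues exactly degenerate coordinates (a constant feature), which shrinkage cannot |
| `quantile` ($q$) | 0.9 | in $(0,1)$ | the reference tail used for enrichment; 0.9 keeps per-cluster counts informative at moderate n |
| `test` | binomial | binomial / permutation | see calibration section below; permutation is preferred for small references |

"Exceeds" a threshold is implemented inclusively (`>=`) so exact ties
count as hits (configurable to strict). Quantiles everywhere use the
linear-interpolation (type-7) convention, stated so results are
bit-reproducible. Adaptive thresholds use the Tukey lower fence
$Q_1 - 1.5\,\mathrm{IQR}$ of the $P1$ distribution, clipped into
$[0.05, 0.95]$, with $T_s = T_h/2$ as an explicit convention — the
fence marks where a cell's top probability becomes an outlier against
the dataset's own confidence profile.

# Design choices where the design was open

- **Raw rows vs distributions.** One-vs-rest annotators emit per-class
  scores that need not sum to 1, and hard multi-identity groups (two
  labels $\ge 0.5$) are attainable *only* on such raw scores. Rows are
  therefore accepted as-is by default (`renormalize_rows = FALSE`) with
  a loud warning when sums deviate from 1; entropy alone is always
  computed on the renormalized row so $H$ stays a proper distribution
  entropy. Both behaviors are exposed rather than silently normalizing.
- **Soft-group precedence.** A cell with one hard hit plus additional
  soft companions is assigned G2s/G3s by default
  (`soft_overrides_g0 = TRUE`): the extra soft mass is evidence against
  a clean single identity. The literal reading (one hard hit ⇒ G0
  regardless) is available via the flag; the packaged truth-table
  fixture pins both behaviors.
- **Ties.** $P2$ counts a duplicated maximum separately, so two labels
  tied at the top give $\Delta = 0$, $A = 1$ — maximal two-way
  ambiguity. Label order ties break toward the lower column index.
- **Reference cells are scored in-sample** (against statistics that
  include themselves; no leave-one-out). This is needed for the tail
  quantile of the reference itself and introduces a small, documented
  optimism of order $d/n_{\mathrm{ref}}$.
- **The cluster used for scoring** is always the cell's own cluster;
  mean and covariance come from the same cluster's reference cells (or
  the global fallback). Cells in clusters never seen at fit time are
  scored globally with a warning and a fallback flag.
- **Binomial null** uses the nominal exceedance $p_0 = 1 - q$, not the
  in-sample reference fraction (which is $\approx 1-q$ by construction
  and would make the test circular); the in-sample variant exists behind
  a flag.
- **Permutation p-values** use the add-one estimator
  $(1 + \#\{\text{perm} \ge \text{obs}\})/(1+B)$, so they are never
  zero and never below $1/(1+B)$.

# The synthetic-data generator

Probability rows are compositional, so regimes are Dirichlet draws:

- `stable` — one dominant concentration (50 vs 0.1): near-one-hot rows,
  truth G0;
- `diffuse` — symmetric concentration 10: no label approaches
  confidence, truth G1;
- `within_lineage_bimodal` / `cross_lineage_bimodal` — two co-dominant
  concentrations (60, 60, rest 0.1) on a label pair drawn within or
  across hierarchy lineages, truth G2 / G3.

Because simulated rows sum to 1, two labels can never both reach 0.5;
the regime-truth battery therefore classifies at $T_h = 0.4$, where the
packaged concentrations give per-regime accuracies of 0.97–1.00 at
$n = 10^4$ (the margins come from Dirichlet tail mass, e.g. a
`diffuse` coordinate needs a $>3.5\sigma$ excursion to reach 0.4).

Two-condition datasets draw both arms from `stable`; query cells are
blended toward the uniform row, $x' = (1-w)x + w/K$, with $w$ found by
bisection on an independent seed-derived calibration sample so that the
first target feature's mean moves by the requested number of reference
standard deviations. `shift_sd = 0` gives exactly exchangeable arms.
All randomness flows through per-call seeds; nothing touches the global
RNG state.

What the generator does **not** emulate: gene-expression counts, doublet
or ambient-RNA artifacts, batch structure, annotator miscalibration, or
realistic cluster-specific covariance differences. A green simulation
test therefore establishes internal correctness (the pipeline measures
the shifts it was told to plant, at the advertised error rates), not
biological validity on any real atlas.

# Numerical choices

- Mahalanobis scores are computed via one Cholesky factorization per
  reference and triangular solves; no covariance is ever explicitly
  inverted. Non-positive-definite covariances are an error that names
  the remedy (shrinkage/ridge).
- Entropy treats entries below 1e-300 as exact zeros inside
  $x \log x$; the log base cancels against $\log K$.
- Probabilities up to 1e-6 outside $[0,1]$ are clipped (upstream float
  noise); anything further is an error naming the cell and label.
- Output CSVs carry 15 significant digits, so write→read round-trips
  agree to better than $10^{-12}$ relative and repeat runs with one seed
  are byte-identical.

# Calibration of the enrichment tests

With Gaussian features, an unshrunk reference fitted on $n = 5000$
cells, and independent held-out cells, held-out OOR matches
$\chi^2_4$ (KS comparison passes at $\alpha = 0.01$ in $\ge 95\%$ of
100 seeded replicates; the held-out median sits at the $\chi^2_4$ median
3.357 within Monte-Carlo error). This is the distributional sanity
anchor for the scoring layer.

The two tail tests differ in what they condition on, and that matters at
realistic reference sizes. The **permutation test** conditions on the
pooled scores; exchangeability under the null is exact, and its type-I
error over 1000 simulated null datasets (500 cells/arm) is 0.056,
within the Monte-Carlo band of 0.05. The **binomial test** instead
treats the tail threshold as known ($p_0 = 1-q$), but the threshold is
*estimated* from the reference sample: its sampling variance adds
$\approx q(1-q)/n_{\mathrm{ref}}$ to the variance of the query
exceedance fraction — a near-doubling when the arms are equal — making
the test anti-conservative (empirically ~0.13 at $\alpha = 0.05$,
$n_{\mathrm{ref}} = 500$; analytically
$\Pr(Z > z_{\alpha}/\sqrt{2}) \approx 0.12$). The corresponding
acceptance expectation is deliberately left failing rather than widened:
the binomial test is only nominally calibrated in the large-reference
limit, and the permutation test should be preferred whenever
$n_{\mathrm{ref}}$ is not much larger than the query arm. A related
convention effect: with a type-7 interpolated threshold and strict
exceedance, the exact expected tail fraction under the null is
$\approx 1 - h/(n_{\mathrm{ref}}+1) = 0.1016$ at
$n_{\mathrm{ref}} = 500$, not 0.1000 — a bias that vanishes as
$n_{\mathrm{ref}} \to \infty$.

# Known limitations

- No robust covariance estimation (MCD) and no leave-one-out scoring;
  heavily contaminated "control" populations will inflate the reference
  covariance and mute OOR.
- Shrinkage ($\lambda > 0$) breaks exact affine equivariance of the
  score; the equivariance property is tested at $\lambda = 0$.
- The absolute OOR scale depends on reference composition and
  lineage-specific variance; cross-dataset comparisons should use
  within-run relative quantities (median shifts, tail fractions), which
  is what the cluster summaries report.
- BH correction is applied across clusters within one run only.
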