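hier <- two_lineage_hierarchy()

test_that("count_hits is inclusive, ordered, and respects the strict flag", {
  row <- c(L1 = 0.9, L2 = 0.6, L3 = 0.1)
  expect_identical(count_hits(row, 0.5), c("L1", "L2"))
  expect_identical(count_hits(c(L1 = 0.4, L2 = 0.3, L3 = 0.3), 0.5), character())
  # exact-threshold tie: both hit, lower column index first
  expect_identical(count_hits(c(L1 = 0.5, L2 = 0.5, L3 = 0), 0.5), c("L1", "L2"))
  expect_identical(count_hits(c(L1 = 0.5, L2 = 0.5, L3 = 0), 0.5, strict = TRUE),
                   character())
  expect_error(count_hits(row, 1.5), "threshold")
})

test_that("same_lineage requires both hierarchy coordinates to match", {
  expect_true(same_lineage(c("L1", "L2"), hier))
  expect_false(same_lineage(c("L1", "L3"), hier))
  h2 <- as_label_hierarchy(list(A = list(tissue = "t", cell_class = "c1"),
                                B = list(tissue = "t", cell_class = "c2")))
  expect_false(same_lineage(c("A", "B"), h2))
  # missing-label policies
  expect_error(same_lineage(c("L1", "nope"), hier), "nope")
  expect_false(same_lineage(c("L1", "nope"), hier, missing_policy = "own"))
  expect_false(same_lineage(c("nope", "nope2"), hier, missing_policy = "own"))
})

test_that("classify_cell follows the decision table", {
  th <- threshold_spec(0.5)
  expect_identical(classify_cell(c(L1 = 0.9, L2 = 0.05, L3 = 0.05), th, hier)$group, "G0")
  expect_identical(classify_cell(c(L1 = 0.3, L2 = 0.3, L3 = 0.2, L4 = 0.2), th, hier)$group, "G1")
  # raw multi-hit rows: lineage decides G2 vs G3
  expect_identical(classify_cell(c(L1 = 0.9, L2 = 0.6, L3 = 0.1), th, hier)$group, "G2")
  expect_identical(classify_cell(c(L1 = 0.9, L3 = 0.6, L2 = 0.1), th, hier)$group, "G3")
  # soft override: one hard hit plus a soft companion
  ths <- threshold_spec(0.5, 0.3)
  a <- classify_cell(c(L1 = 0.55, L2 = 0.40, L3 = 0.05), ths, hier)
  expect_identical(a$group, "G2s")
  expect_identical(a$hard_hits, "L1")
  expect_identical(a$soft_hits, c("L1", "L2"))
  # literal-G0 alternative via the flag
  thl <- threshold_spec(0.5, 0.3, soft_overrides_g0 = FALSE)
  expect_identical(classify_cell(c(L1 = 0.55, L2 = 0.40, L3 = 0.05), thl, hier)$group, "G0")
})

test_that("classify_all recovers engineered group fractions", {
  mat <- make_prob_matrix(rbind(
    c(0.9, 0.05, 0.03, 0.02),   # G0
    c(0.3, 0.3, 0.2, 0.2),      # G1 (soft off)
    c(0.6, 0.55, 0.05, 0),      # G2
    c(0.6, 0.05, 0.55, 0)),     # G3
    labels = hier$label)
  cls <- classify_all(mat, threshold_spec(0.5), hier)
  expect_identical(unname(cls$groups), c("G0", "G1", "G2", "G3"))
  expect_equal(unname(cls$fractions[c("G0", "G1", "G2", "G3")]), rep(0.25, 4))
  expect_equal(sum(cls$fractions), 1)

  onehot <- make_prob_matrix(diag(4), labels = hier$label)
  expect_equal(unname(classify_all(onehot, threshold_spec(0.5), hier)$fractions[["G0"]]), 1)
})

test_that("partition, threshold monotonicity and soft-off reduction hold", {
  set.seed(3)
  g <- matrix(rgamma(500 * 4, 0.7), 500)
  mat <- make_prob_matrix(g / rowSums(g), labels = hier$label)

  soft_on <- classify_all(mat, threshold_spec(0.45, 0.25), hier)
  soft_off <- classify_all(mat, threshold_spec(0.45), hier)
  expect_equal(sum(soft_on$fractions), 1)
  expect_true(all(soft_off$groups %in% c("G0", "G1", "G2", "G3")))
  # soft-off equals soft-on wherever the soft path was not taken
  plain <- !soft_on$groups %in% c("G2s", "G3s")
  expect_identical(soft_off$groups[plain], soft_on$groups[plain])

  # raising T_h never turns a G1 cell into a hard or soft-hard group
  lo <- classify_all(mat, threshold_spec(0.35), hier)$groups
  hi <- classify_all(mat, threshold_spec(0.55), hier)$groups
  expect_true(all(hi[lo == "G1"] == "G1"))
})

test_that("coarsening the hierarchy only converts cross- to within-lineage groups", {
  set.seed(4)
  g <- matrix(rgamma(400 * 4, 0.5), 400)
  mat <- make_prob_matrix(g / rowSums(g), labels = hier$label)
  merged <- as_label_hierarchy(lapply(setNames(nm = hier$label), function(l)
    list(tissue = "t", cell_class = "c")))
  th <- threshold_spec(0.4, 0.2)
  fine <- classify_all(mat, th, hier)$groups
  coarse <- classify_all(mat, th, merged)$groups
  changed <- fine != coarse
  expect_true(all(fine[changed] %in% c("G3", "G3s")))
  expect_identical(unname(coarse[fine == "G3"]), rep("G2", sum(fine == "G3")))
  expect_identical(unname(coarse[fine == "G3s"]), rep("G2s", sum(fine == "G3s")))
})

test_that("adaptive thresholds follow the Tukey lower fence with clipping", {
  # hand-computed interpolated quartiles: Q1 = 0.85, Q3 = 0.92, IQR = 0.07
  th <- suggest_thresholds(c(0.5, 0.85, 0.9, 0.92, 0.95))
  expect_equal(th$hard, 0.745)
  expect_equal(th$soft, 0.3725)
  expect_true(th$adaptive)

  # zero spread: fence = Q1 = 0.9
  th2 <- suggest_thresholds(rep(0.9, 10))
  expect_equal(th2$hard, 0.9)
  expect_equal(th2$soft, 0.45)

  # negative fence clips to the floor: 0.35 - 1.5*0.3 = -0.1 -> 0.05
  th3 <- suggest_thresholds(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(th3$hard, 0.05)
  expect_equal(th3$soft, 0.025)

  expect_error(suggest_thresholds(c(0.1, 0.2, 0.3)), ">= 4")
})
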