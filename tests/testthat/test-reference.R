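ref_config <- function(...) {
  run_config(condition_column = "condition", reference_level = "control", ...)
}

test_that("shrink_covariance matches the closed form and its limits", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(shrink_covariance(S, 0.1), matrix(c(1, 0.72, 0.72, 1), 2))
  expect_equal(shrink_covariance(S, 0), S)
  expect_equal(shrink_covariance(S, 1), diag(2))
  # ridge only touches the diagonal
  expect_equal(shrink_covariance(S, 0.1, 1e-3) - shrink_covariance(S, 0.1),
               diag(1e-3, 2))
  asym <- S; asym[1, 2] <- 0.8 + 1e-6
  expect_error(shrink_covariance(asym, 0.1), "symmetric")
  expect_error(shrink_covariance(S, 1.5), "lambda")
})

test_that("oor_score matches hand values and a brute-force inverse oracle", {
  expect_equal(oor_score(c(1, 2, 3), c(1, 2, 3), diag(3)), 0)
  expect_equal(oor_score(c(1, 0, 0, 0), rep(0, 4), diag(4)), 1)
  # explicit diagonal inverse by hand: 4/2 + 1/0.5
  expect_equal(oor_score(c(2, 1), c(0, 0), diag(c(2, 0.5))), 4)

  set.seed(21)
  for (i in 1:100) {
    S <- random_spd(4)
    x <- rnorm(4); mu <- rnorm(4)
    expect_equal(oor_score(x, mu, S), oracle_mahalanobis(x, mu, S),
                 tolerance = 1e-8)
  }
  expect_error(oor_score(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("oor_score is invariant to consistent feature rescaling", {
  set.seed(22)
  S <- random_spd(4); x <- rnorm(4); mu <- rnorm(4)
  sc <- c(10, 0.1, 3, 1)
  D <- diag(sc)
  expect_equal(oor_score(sc * x, sc * mu, D %*% S %*% D), oor_score(x, mu, S),
               tolerance = 1e-10)
})

test_that("fit_reference flips to the global fallback below min_cells exactly", {
  set.seed(30)
  n_a <- 49; n_b <- 120
  feats <- gaussian_features(n_a + n_b, diag(4))
  meta <- data.frame(cell_id = feats$cell_id, condition = "control",
                     cluster = rep(c("A", "B"), c(n_a, n_b)),
                     stringsAsFactors = FALSE)
  cfg <- ref_config(cluster_column = "cluster")
  model <- fit_reference(feats, meta, cfg)
  expect_true(model$per_cluster[["A"]]$fallback_used)   # 49 < 50
  expect_false(model$per_cluster[["B"]]$fallback_used)  # 120 >= 50
  expect_equal(model$per_cluster[["A"]]$mean, model$global$mean)
  expect_equal(model$per_cluster[["A"]]$cov, model$global$cov)

  # exactly 50 reference cells: boundary complement
  meta50 <- meta; meta50$cluster[n_a + 1] <- "A"
  model50 <- fit_reference(feats, meta50, cfg)
  expect_false(model50$per_cluster[["A"]]$fallback_used)
  expect_equal(model50$per_cluster[["A"]]$n_ref, 50)
})

test_that("fit_reference recovers known Gaussian parameters", {
  set.seed(31)
  Sigma <- matrix(0.5, 4, 4) + diag(4) * 0.5
  mu <- c(1, -2, 0.5, 3)
  L <- chol(Sigma)
  n <- 5000
  feats <- gaussian_features(n, L)
  for (nm in c("P1", "delta", "admixture", "entropy")) {
    feats[[nm]] <- feats[[nm]] + mu[match(nm, c("P1", "delta", "admixture", "entropy"))]
  }
  meta <- data.frame(cell_id = feats$cell_id, condition = "control",
                     stringsAsFactors = FALSE)
  model <- fit_reference(feats, meta, ref_config(shrinkage_lambda = 0, ridge_epsilon = 0))
  se <- sqrt(diag(Sigma) / n)
  expect_true(all(abs(model$global$mean - mu) < 3 * se))
  expect_true(all(abs(model$global$cov - Sigma) < 0.1 * max(abs(Sigma))))
})

test_that("fit_reference error paths", {
  feats <- gaussian_features(10, diag(4))
  meta <- data.frame(cell_id = feats$cell_id, condition = "case",
                     stringsAsFactors = FALSE)
  expect_error(fit_reference(feats, meta, ref_config()), "no reference cells")
  meta$condition <- "control"
  expect_error(fit_reference(feats, meta[, "cell_id", drop = FALSE],
                             ref_config()), "condition")
  # constant feature: singular without ridge, rescued by the default ridge
  feats$entropy <- 0
  cfg0 <- ref_config(shrinkage_lambda = 0, ridge_epsilon = 0)
  expect_error(fit_reference(feats, meta, cfg0), "ridge_epsilon")
  model <- fit_reference(feats, meta, ref_config())
  expect_true(is.finite(oor_score(rep(0, 4), model$global$mean, model$global$cov)))
})

test_that("score_all strata: zero at mean, single cluster equals global, fallbacks", {
  set.seed(33)
  feats <- gaussian_features(200, chol(random_spd(4)))
  meta <- data.frame(cell_id = feats$cell_id,
                     condition = rep(c("control", "case"), 100),
                     cluster = "c1", stringsAsFactors = FALSE)
  cfg_glob <- ref_config()
  cfg_clus <- ref_config(cluster_column = "cluster")
  model_g <- fit_reference(feats, meta, cfg_glob)
  model_c <- fit_reference(feats, meta, cfg_clus)

  # stratification with one stratum is vacuous
  expect_equal(score_all(feats, model_g)$oor,
               score_all(feats, model_c, meta)$oor)

  # all cells at the reference mean score zero
  at_mean <- feats
  for (j in seq_along(model_g$feature_names)) {
    at_mean[[model_g$feature_names[j]]] <- model_g$global$mean[j]
  }
  expect_equal(score_all(at_mean, model_g)$oor, rep(0, 200))

  # unknown cluster: scored globally with fallback flag and warning
  meta2 <- meta; meta2$cluster[1:5] <- "mystery"
  expect_warning(res <- score_all(feats, model_c, meta2), "mystery")
  expect_true(all(res$fallback_used[1:5]))
  expect_identical(res$cluster_used[1:5], rep("global", 5))
  expect_equal(res$oor[1:5], score_all(feats, model_g)$oor[1:5])
})

test_that("toggling one cluster across the min_cells boundary only moves that cluster", {
  set.seed(34)
  feats <- gaussian_features(260, chol(random_spd(4)))
  meta <- data.frame(cell_id = feats$cell_id, condition = "control",
                     cluster = rep(c("A", "B", "C"), c(50, 110, 100)),
                     stringsAsFactors = FALSE)
  cfg <- ref_config(cluster_column = "cluster")
  s_above <- score_all(feats, fit_reference(feats, meta, cfg), meta)
  meta_b <- meta; meta_b$condition[50] <- "case"   # A's reference count drops to 49
  s_below <- score_all(feats, fit_reference(feats, meta_b, cfg), meta)
  in_c <- meta$cluster == "C"
  expect_equal(s_below$oor[in_c], s_above$oor[in_c])
  in_a <- meta$cluster == "A"
  expect_true(any(s_below$oor[in_a] != s_above$oor[in_a]))
  expect_true(all(s_below$fallback_used[in_a]))
})

test_that("OOR is affine-equivariant when unshrunk", {
  set.seed(35)
  feats <- gaussian_features(300, chol(random_spd(4)))
  meta <- data.frame(cell_id = feats$cell_id, condition = "control",
                     stringsAsFactors = FALSE)
  cfg <- ref_config(shrinkage_lambda = 0, ridge_epsilon = 0)
  base <- score_all(feats, fit_reference(feats, meta, cfg))$oor
  A <- matrix(c(2, 0.3, 0, 0, 0.1, 1, 0, 0.5, 0, 0, 3, 0, 0.2, 0, 0, 1), 4)
  X <- as.matrix(feats[, c("P1", "delta", "admixture", "entropy")]) %*% t(A)
  tf <- feats; tf[, c("P1", "delta", "admixture", "entropy")] <- X
  mapped <- score_all(tf, fit_reference(tf, meta, cfg))$oor
  expect_equal(mapped, base, tolerance = 1e-8)
})
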