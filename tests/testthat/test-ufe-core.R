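test_that("compute_pca matches a dense Gram-matrix eigendecomposition", {
  for (seed in 1:5) {
    x <- rand_norm_matrix(10, 4, seed = seed)
    pc <- compute_pca(x)
    # independent oracle: dense eigenproblem of the 10 x 10 Gram matrix
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    L <- length(pc$eigenvalues)
    expect_equal(pc$eigenvalues, eg$values[1:L], tolerance = 1e-8)
    for (l in 1:L) {
      dot <- abs(sum(pc$scores[, l] * eg$vectors[, l]))
      expect_equal(dot, 1, tolerance = 1e-8)
    }
    # orthonormal scores
    expect_equal(crossprod(pc$scores), diag(L), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # energy identity with full rank retained
    expect_equal(sum(pc$eigenvalues), nrow(x) * ncol(x),
                 tolerance = 1e-6 * nrow(x) * ncol(x))
    # sign convention: largest-|u| entry positive
    for (l in 1:L)
      expect_gt(pc$scores[which.max(abs(pc$scores[, l])), l], 0)
  }
})

test_that("compute_pca rejects unnormalized input", {
  expect_error(compute_pca(rand_matrix(10, 4, seed = 1)),
               class = "ufe_not_normalized")
})

test_that("loadings equal the printed contraction and carry the eigenvalues", {
  x <- rand_norm_matrix(12, 5, seed = 21)
  pc <- compute_pca(x)
  # direct contraction oracle
  v_manual <- matrix(0, length(pc$eigenvalues), ncol(x))
  for (l in seq_along(pc$eigenvalues))
    for (j in seq_len(ncol(x)))
      v_manual[l, j] <- sum(x[, j] * pc$scores[, l])
  expect_equal(unname(pc$loadings), v_manual, tolerance = 1e-8)
  expect_equal(unname(compute_loadings(x, pc$scores)), v_manual,
               tolerance = 1e-12)
  # sum_j v^2 = lambda
  expect_equal(rowSums(pc$loadings^2), pc$eigenvalues, tolerance = 1e-8)
  # zero matrix -> zero loadings
  expect_true(all(compute_loadings(matrix(0, 12, 5), pc$scores) == 0))
  expect_error(compute_loadings(x, pc$scores[1:5, ]),
               class = "ufe_dim_mismatch")
})

test_that("association test equals the two-sample t-test and handles degeneracy", {
  # no between-class signal
  a <- balanced_annot(paste0("s", 1:4))
  r <- test_component_association(matrix(c(1, -1, 1, -1), 1),
                                  sample_annotation(paste0("s", 1:4),
                                                    c("A", "A", "B", "B")))
  expect_equal(r$f_stat, 0)
  expect_equal(r$p_raw, 1)

  # zero within-class variance, distinct means
  expect_warning(
    r2 <- test_component_association(matrix(c(2, 2, -2, -2), 1),
                                     sample_annotation(paste0("s", 1:4),
                                                       c("A", "A", "B", "B"))),
    class = "ufe_degenerate_test")
  expect_equal(r2$p_raw, 0)

  # oracle: squared-t two-sample test, 50 random components at once
  set.seed(77)
  for (m in c(8, 13, 30)) {
    lab <- sample(rep(c("A", "B"), length.out = m))
    ann <- sample_annotation(paste0("s", 1:m), lab)
    v <- matrix(rnorm(50 * m), 50, m)
    res <- test_component_association(v, ann)
    for (l in seq_len(nrow(v))) {
      tt <- t.test(v[l, lab == "A"], v[l, lab == "B"], var.equal = TRUE)
      expect_equal(res$p_raw[l], tt$p.value, tolerance = 1e-12)
      expect_equal(res$f_stat[l], unname(tt$statistic^2), tolerance = 1e-9)
    }
    # sum-to-zero coding reconstructs the class means
    expect_equal(res$a + res$b1,
                 rowMeans(v[, lab == "A", drop = FALSE]), tolerance = 1e-12)
    expect_equal(res$b1, -res$b2, tolerance = 1e-12)
  }
})

test_that("benjamini_hochberg reproduces the step-up definition", {
  # frozen worked example: q = p * m / k = (.04, .04, .04, .04)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))

  set.seed(123)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-14)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "ufe_bad_pvalues")
  expect_error(benjamini_hochberg(c(-0.1)), class = "ufe_bad_pvalues")
})

test_that("select_components thresholds strictly and honors overrides", {
  assocs <- data.frame(component = 1:3,
                       p_adjusted = c(0.01, 0.20, 0.04))
  expect_identical(select_components(assocs, alpha = 0.05), c(1L, 3L))
  # strict <: exactly-alpha p is not selected
  assocs$p_adjusted[3] <- 0.05
  expect_identical(select_components(assocs, alpha = 0.05), 1L)
  expect_message(om <- select_components(assocs, override = 5L), "manual")
  expect_identical(om, 5L)
  assocs$p_adjusted <- rep(0.9, 3)
  expect_error(select_components(assocs), class = "ufe_empty_components")
})

test_that("chi-squared feature scores follow the stated distribution", {
  # all-zero scores on omega -> T = 0 -> P = 1
  sc <- matrix(0, 5, 2)
  r <- score_features(sc, score_sd = c(1, 1), omega = 1:2)
  expect_equal(r$statistic, rep(0, 5))
  expect_equal(r$p_raw, rep(1, 5))

  # |Omega| = 1: P equals the two-sided normal tail of |z|
  z <- c(-2.5, -0.3, 0, 1.1, 3.2)
  r1 <- score_features(matrix(z, 5, 1), score_sd = 1, omega = 1L)
  expect_equal(r1$p_raw, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  expect_error(score_features(sc, score_sd = c(0, 1), omega = 1:2),
               class = "ufe_degenerate_test")
  expect_error(score_features(sc, score_sd = c(1, 1), omega = 3L),
               class = "ufe_bad_config")
})

test_that("select_features is strict, monotone in alpha, and errors when empty", {
  p <- c(0.00005, 0.5, 0.00009, 0.9, 0.04)
  s <- select_features(p, alpha = 0.01)
  expect_identical(which(s$selected), c(1L, 3L))
  expect_equal(s$p_adjusted, benjamini_hochberg(p))

  set.seed(4)
  for (i in 1:20) {
    pr <- runif(100)^4
    lo <- tryCatch(select_features(pr, alpha = 0.01)$selected,
                   pcaufe_error = function(e) rep(FALSE, 100))
    hi <- tryCatch(select_features(pr, alpha = 0.10)$selected,
                   pcaufe_error = function(e) rep(FALSE, 100))
    expect_true(all(hi[lo]))  # selection(alpha) subset of selection(alpha')
  }
  expect_error(select_features(runif(20, 0.5, 1), alpha = 0.01),
               class = "ufe_empty_features")
})

test_that("stage-2 restriction behaves as documented", {
  co <- small_cohort(seed = 31)
  nm <- prep_cohort(co)
  annot <- co$annot

  # selecting every feature reproduces stage 1 exactly
  pc1 <- compute_pca(nm)
  s2 <- suppressMessages(
    recompute_stage2(nm, rownames(nm), annot = annot))
  expect_equal(s2$pca$eigenvalues, pc1$eigenvalues, tolerance = 1e-8)
  expect_equal(s2$pca$scores, pc1$scores, tolerance = 1e-8)

  # override honored and logged
  sel <- rownames(nm)[1:10]
  expect_message(
    s2o <- recompute_stage2(nm, sel, omega_override = c(2L, 4L)),
    "Omega = \\{2,4\\}")
  expect_identical(s2o$omega, c(2L, 4L))

  # contraction identity on the submatrix
  sub <- nm[sel, , drop = FALSE]
  expect_equal(unname(s2o$pca$loadings),
               unname(crossprod(s2o$pca$scores, sub)), tolerance = 1e-10)

  expect_error(recompute_stage2(nm, sel[1]), class = "ufe_too_small")
})

test_that("run_ufe recovers planted structure and is equivariant", {
  co <- small_cohort(seed = 8)
  nm <- prep_cohort(co)
  res <- suppressMessages(run_ufe(nm, co$annot))
  expect_gt(mean(co$truth %in% res$selected_features), 0.7)
  expect_identical(res$feature_stats$feature_id, rownames(nm))

  # permuting samples permutes loadings identically
  set.seed(99)
  pj <- sample(ncol(nm))
  ann_p <- sample_annotation(co$annot$sample_id[pj],
                             as.character(co$annot$class_label)[pj])
  res_p <- suppressMessages(run_ufe(nm[, pj], ann_p))
  expect_identical(res_p$selected_features, res$selected_features)
  expect_equal(res_p$stage1$pca$loadings,
               res$stage1$pca$loadings[, pj], tolerance = 1e-8,
               ignore_attr = TRUE)

  # permuting features permutes scores/selection identically
  pi_ <- sample(nrow(nm))
  res_f <- suppressMessages(run_ufe(nm[pi_, ], co$annot))
  expect_setequal(res_f$selected_features, res$selected_features)
  expect_equal(res_f$feature_stats$statistic,
               res$feature_stats$statistic[pi_], tolerance = 1e-8)

  # determinism: identical rerun gives identical serialization
  res2 <- suppressMessages(run_ufe(nm, co$annot))
  expect_identical(serialize(res2, NULL), serialize(res, NULL))
})
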