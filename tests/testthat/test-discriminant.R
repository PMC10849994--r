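test_that("1-D symmetric LDA reduces to the midpoint threshold", {
  set.seed(1)
  v <- matrix(c(rnorm(20, -1, 0.3), rnorm(20, 1, 0.3)))
  ann <- sample_annotation(paste0("s", 1:40), rep(c("A", "B"), each = 20))
  # symmetrize exactly: class B = -class A
  v[21:40, 1] <- -v[1:20, 1]
  m <- fit_lda(v, ann)
  expect_equal(m$threshold, 0, tolerance = 1e-10)
  pred <- predict(m, v)
  expect_identical(as.character(pred$predicted),
                   ifelse(v[, 1] > 0, "B", "A"))
})

test_that("duplicating samples leaves direction and threshold unchanged", {
  set.seed(2)
  v <- matrix(rnorm(60), 30, 2)
  v[16:30, ] <- v[16:30, ] + 1.5
  ann <- sample_annotation(paste0("s", 1:30), rep(c("A", "B"), each = 15))
  m1 <- fit_lda(v, ann)
  ann2 <- sample_annotation(paste0("s", 1:60),
                            rep(rep(c("A", "B"), each = 15), 2))
  m2 <- fit_lda(rbind(v, v), ann2)
  expect_equal(m2$weights / sqrt(sum(m2$weights^2)),
               m1$weights / sqrt(sum(m1$weights^2)), tolerance = 1e-6)
  expect_equal(m2$threshold / sqrt(sum(m2$weights^2)),
               m1$threshold / sqrt(sum(m1$weights^2)), tolerance = 1e-6)
})

test_that("discriminant direction matches the dense-solve oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1); d <- sample(2:5, 1)
    v <- rbind(matrix(rnorm(n1 * d), n1),
               matrix(rnorm(n2 * d, mean = 1), n2))
    ann <- sample_annotation(paste0("s", seq_len(n1 + n2)),
                             rep(c("A", "B"), c(n1, n2)))
    m <- fit_lda(v, ann)
    g <- rep(1:2, c(n1, n2))
    mu1 <- colMeans(v[g == 1, , drop = FALSE])
    mu2 <- colMeans(v[g == 2, , drop = FALSE])
    sw <- (cov(v[g == 1, , drop = FALSE]) * (n1 - 1) +
           cov(v[g == 2, , drop = FALSE]) * (n2 - 1)) / (n1 + n2 - 2)
    w_oracle <- solve(sw) %*% (mu2 - mu1)
    cosang <- sum(m$weights * w_oracle) /
      sqrt(sum(m$weights^2) * sum(w_oracle^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }
})

test_that("prediction ties and mismatches are handled", {
  ann <- sample_annotation(paste0("s", 1:8), rep(c("A", "B"), each = 4))
  v <- matrix(c(-(4:1), 1:4))
  m <- fit_lda(v, ann)
  # perfectly separated training data: zero errors
  pred <- predict(m, v)
  expect_identical(as.character(pred$predicted),
                   as.character(ann$class_label))
  # score exactly 0 -> class 1
  v0 <- matrix((m$threshold) / m$weights[1], 1, 1)
  expect_identical(as.character(predict(m, v0)$predicted), "A")
  expect_error(predict(m, matrix(0, 2, 3)), class = "ufe_dim_mismatch")
})

test_that("refitting after a constant shift leaves predictions unchanged", {
  set.seed(3)
  v <- matrix(rnorm(80), 40, 2); v[21:40, ] <- v[21:40, ] + 2
  ann <- sample_annotation(paste0("s", 1:40), rep(c("A", "B"), each = 20))
  p1 <- predict(fit_lda(v, ann), v)
  v2 <- sweep(v, 2, c(13.7, -4.2), `+`)
  p2 <- predict(fit_lda(v2, ann), v2)
  expect_identical(p1$predicted, p2$predicted)
  expect_equal(p1$score, p2$score, tolerance = 1e-8)
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  # degenerate anchors
  expect_equal(confusion_and_auc(c(-2, -1, 1, 2),
                                 factor(c("A", "A", "B", "B")))$auc, 1)
  expect_equal(confusion_and_auc(rep(0, 6),
                                 factor(rep(c("A", "B"), 3)))$auc, 0.5)

  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    lab <- factor(sample(c("A", "B"), n, replace = TRUE,
                         prob = c(0.5, 0.5)))
    if (length(unique(lab)) < 2) next
    sc <- sample(round(rnorm(n), 1))  # rounding induces ties
    r <- confusion_and_auc(sc, lab)
    expect_equal(r$auc, auc_oracle(sc, lab == "B"), tolerance = 1e-12)
    # ROC endpoints and monotonicity
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(tail(r$roc$fpr, 1), 1); expect_equal(tail(r$roc$tpr, 1), 1)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    # label swap: AUC -> 1 - AUC (ties keep the identity exact)
    r2 <- confusion_and_auc(sc, factor(as.character(lab),
                                       levels = rev(levels(lab))))
    expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)
    # monotone transform invariance
    r3 <- confusion_and_auc(exp(sc), lab)
    expect_equal(r3$auc, r$auc, tolerance = 1e-12)
    # confusion counts sum to n
    expect_equal(sum(r$confusion), n)
  }
})

test_that("LOOCV separates a strong synthetic cohort without leakage", {
  co <- small_cohort(seed = 55)
  nm <- prep_cohort(co)
  r <- suppressMessages(loocv_evaluate(nm, co$annot))
  expect_identical(r$mode, "loocv")
  expect_gt(r$auc, 0.9)
  expect_true(all(r$folds[, "n_selected"] >= 2))
  expect_error(loocv_evaluate(nm[, 1:3], co$annot[1:3, ]),
               class = "ufe_too_small")
})
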