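#' Fit a two-class Fisher linear discriminant
#'
#' Weight vector \eqn{w = S_w^{-1} (\mu_2 - \mu_1)} with \eqn{S_w} the
#' pooled within-class covariance, and decision threshold at the midpoint
#' of the projected class means shifted by the log prior ratio (priors =
#' empirical class frequencies). A sample with discriminant score
#' \eqn{w \cdot v - c > 0} is assigned class 2 (the lexicographically
#' larger label); a score of exactly 0 goes to class 1.
#'
#' If the pooled covariance is numerically singular a ridge
#' \eqn{\epsilon I} with \eqn{\epsilon = 10^{-8} \, \mathrm{tr}(S_w)/d}
#' is added, with a warning.
#'
#' @param v samples x components matrix (rows = samples). Loading matrices
#'   from \code{\link{compute_pca}} are components x samples; transpose
#'   them first, or use \code{\link{discriminate_loadings}}.
#' @param annot \code{\link{sample_annotation}} aligned with rows of
#'   \code{v}.
#' @return object of class \code{"lda_model"}: \code{weights},
#'   \code{threshold}, \code{levels}, \code{priors}.
#' @export
fit_lda <- function(v, annot) {
  v <- as.matrix(v)
  if (nrow(v) != nrow(annot))
    ufe_error("rows of v do not match annotation samples", "ufe_dim_mismatch")
  g <- as.integer(annot$class_label)
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  if (n1 < 2L || n2 < 2L)
    ufe_error("LDA needs >= 2 samples per class", "ufe_bad_annotation")
  d <- ncol(v)
  mu1 <- colMeans(v[g == 1L, , drop = FALSE])
  mu2 <- colMeans(v[g == 2L, , drop = FALSE])
  c1 <- sweep(v[g == 1L, , drop = FALSE], 2L, mu1, `-`)
  c2 <- sweep(v[g == 2L, , drop = FALSE], 2L, mu2, `-`)
  sw <- (crossprod(c1) + crossprod(c2)) / (n1 + n2 - 2L)
  w <- tryCatch(solve(sw, mu2 - mu1), error = function(e) NULL)
  if (is.null(w)) {
    eps <- 1e-8 * sum(diag(sw)) / d
    if (eps <= 0) eps <- 1e-8
    ufe_warning("singular pooled covariance; adding ridge", "ufe_ridge_lda")
    w <- solve(sw + diag(eps, d), mu2 - mu1)
  }
  pri <- c(n1, n2) / (n1 + n2)
  threshold <- sum(w * (mu1 + mu2)) / 2 - log(pri[2L] / pri[1L])
  structure(list(weights = as.numeric(w), threshold = threshold,
                 levels = levels(annot$class_label), priors = pri),
            class = "lda_model")
}

#' Score and classify samples with a fitted discriminant
#'
#' @param object an \code{"lda_model"}.
#' @param v samples x components matrix.
#' @param ... unused.
#' @return data frame with \code{score} (\eqn{w \cdot v - c}) and
#'   \code{predicted} (factor on the model's class levels; ties at score 0
#'   go to class 1).
#' @export
predict.lda_model <- function(object, v, ...) {
  v <- as.matrix(v)
  if (ncol(v) != length(object$weights))
    ufe_error(paste0("model expects ", length(object$weights),
                     " components, got ", ncol(v)), "ufe_dim_mismatch")
  score <- as.numeric(v %*% object$weights) - object$threshold
  predicted <- factor(object$levels[ifelse(score > 0, 2L, 1L)],
                      levels = object$levels)
  data.frame(score = score, predicted = predicted,
             row.names = rownames(v) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion matrix, ROC curve and AUC from discriminant scores
#'
#' The confusion matrix counts predicted x true labels at the model's
#' threshold (score 0). The ROC sweeps the score threshold over all
#' distinct values with class 2 as positive; the AUC is the trapezoidal
#' area, identical to the Mann-Whitney U statistic divided by
#' \eqn{n_1 n_2} with ties counted 1/2.
#'
#' @param scores numeric discriminant scores (larger = more class-2-like).
#' @param truth factor of true labels (two levels, class order = level
#'   order).
#' @param predicted optional factor of predicted labels; defaults to
#'   thresholding \code{scores} at 0.
#' @param mode evaluation mode tag recorded in the result
#'   (\code{"in_sample"} or \code{"loocv"}).
#' @return object of class \code{"discrimination_result"}: \code{scores},
#'   \code{predicted}, \code{confusion} (2 x 2, predicted x true),
#'   \code{roc} (threshold, fpr, tpr), \code{auc}, \code{mode}.
#' @export
confusion_and_auc <- function(scores, truth, predicted = NULL,
                              mode = "in_sample") {
  truth <- as.factor(truth)
  lev <- levels(truth)
  if (length(lev) != 2L || any(table(truth) < 1L))
    ufe_error("need both classes present in truth", "ufe_bad_annotation")
  if (is.null(predicted))
    predicted <- factor(lev[ifelse(scores > 0, 2L, 1L)], levels = lev)
  confusion <- table(predicted = predicted, truth = truth)

  pos <- truth == lev[2L]
  n1 <- sum(!pos); n2 <- sum(pos)
  # threshold sweep: descending unique scores; prepend +Inf for (0,0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n2, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n1, 0)
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1L) +
                                utils::tail(roc$tpr, -1L)) / 2)
  structure(list(scores = scores, predicted = predicted,
                 confusion = confusion, roc = roc, auc = auc, mode = mode),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("discrimination_result (", x$mode, ")\n", sep = "")
  print(x$confusion)
  cat("AUC:", signif(x$auc, 4L), "\n")
  invisible(x)
}

#' In-sample discrimination on stage-2 loadings
#'
#' Convenience wrapper: takes a \code{\link{run_ufe}} result, fits the LDA
#' on the stage-2 loadings restricted to the stage-2 Omega set, and
#' evaluates it on the training samples.
#'
#' @param ufe a \code{"ufe_result"}.
#' @param annot the aligned annotation used to produce it.
#' @return a \code{"discrimination_result"} with mode \code{"in_sample"}.
#' @export
discriminate_loadings <- function(ufe, annot) {
  v <- t(ufe$stage2$pca$loadings[ufe$stage2$omega, , drop = FALSE])
  model <- fit_lda(v, annot)
  pred <- predict(model, v)
  confusion_and_auc(pred$score, annot$class_label, pred$predicted,
                    mode = "in_sample")
}

#' Leave-one-out cross-validated discrimination
#'
#' For each sample in turn, the entire procedure — PCA, component
#' association, chi-squared feature selection, stage-2 decomposition and
#' LDA fit — is rerun on the remaining M-1 samples, so feature selection
#' happens inside the fold and cannot leak the held-out label. The
#' held-out sample's stage-2 loading is the contraction of its normalized
#' expression vector with the fold's stage-2 scores. Fold scores are
#' centred at the fold threshold and aggregated into one ROC/AUC.
#'
#' Folds whose training set degenerates (single class, empty component or
#' feature selection) are skipped with a warning; if every fold fails, an
#' error is raised.
#'
#' @param x normalized expression matrix.
#' @param annot aligned annotation.
#' @param ... passed to \code{\link{run_ufe}} (alphas, omega overrides).
#' @return a \code{"discrimination_result"} with mode \code{"loocv"} and an
#'   extra element \code{folds} (per-fold Omega sizes and feature counts).
#' @export
loocv_evaluate <- function(x, annot, ...) {
  m <- ncol(x)
  if (m < 4L)
    ufe_error("LOOCV needs at least 4 samples", "ufe_too_small")
  scores <- rep(NA_real_, m)
  fold_info <- vector("list", m)
  for (j in seq_len(m)) {
    train_ids <- annot$sample_id[-j]
    train_annot <- tryCatch(
      sample_annotation(train_ids, as.character(annot$class_label)[-j]),
      pcaufe_error = function(e) NULL)
    if (is.null(train_annot)) {
      ufe_warning(paste0("fold ", j, ": degenerate training classes; skipped"),
                  "ufe_fold_skipped")
      next
    }
    fit <- tryCatch(
      run_ufe(x[, -j, drop = FALSE], train_annot, ...),
      pcaufe_error = function(e) NULL)
    if (is.null(fit)) {
      ufe_warning(paste0("fold ", j, ": selection failed; skipped"),
                  "ufe_fold_skipped")
      next
    }
    omega2 <- fit$stage2$omega
    u2 <- fit$stage2$pca$scores[, omega2, drop = FALSE]
    feats <- fit$stage2$pca$feature_ids   # all features under fallback
    v_train <- t(fit$stage2$pca$loadings[omega2, , drop = FALSE])
    model <- fit_lda(v_train, train_annot)
    v_test <- matrix(crossprod(u2, x[feats, j]), nrow = 1L)
    sel <- fit$selected_features
    scores[j] <- predict(model, v_test)$score
    fold_info[[j]] <- c(n_omega1 = length(fit$stage1$omega),
                        n_selected = length(sel),
                        n_omega2 = length(omega2))
  }
  ok <- !is.na(scores)
  if (!any(ok))
    ufe_error("every LOOCV fold failed", "ufe_loocv_failed")
  res <- confusion_and_auc(scores[ok], droplevels(annot$class_label[ok]),
                           mode = "loocv")
  res$folds <- do.call(rbind, fold_info[ok])
  res
}
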