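#' Principal component scores and loadings of a normalized matrix
#'
#' Solves the feature-space eigenproblem of the Gram matrix
#' \eqn{G_{i i'} = \sum_j x_{ij} x_{i'j}}: per component l the score vector
#' \eqn{u_{l}} (length N, unit norm over features) satisfies
#' \eqn{G u_l = \lambda_l u_l}, and the loading is the contraction
#' \eqn{v_{lj} = \sum_i x_{ij} u_{li}}. Computation goes through the thin
#' SVD of the N x M matrix, which is algebraically identical and avoids
#' forming the N x N Gram matrix. Components with
#' \eqn{\lambda_l / \lambda_1 < 10^{-12}} are discarded.
#'
#' Sign convention: within each score vector the entry of largest magnitude
#' is made positive (ties broken by lowest feature index). All downstream
#' statistics are sign-invariant; the convention only fixes serialized
#' output.
#'
#' @param x normalized expression matrix (see
#'   \code{\link{normalize_samples}}); the constraints are checked.
#' @param check_normalized set \code{FALSE} to skip the constraint check
#'   (used by stage 2, whose submatrix is intentionally not re-normalized).
#' @return an object of class \code{"pc_decomposition"}: list with
#'   \code{scores} (N x L, columns \eqn{u_l}), \code{eigenvalues}
#'   (\eqn{\lambda_l}, nonincreasing), \code{loadings} (L x M,
#'   \eqn{v_{lj}}), \code{score_sd} (\eqn{\sigma_l}, population SD of the
#'   score entries), \code{feature_ids}, \code{sample_ids}.
#' @export
compute_pca <- function(x, check_normalized = TRUE) {
  validate_expression_matrix(x)
  if (check_normalized && !is_normalized(x))
    ufe_error("matrix does not satisfy the normalization constraints; run normalize_samples() first",
              "ufe_not_normalized")
  sv <- svd(x)
  lambda <- sv$d^2
  keep <- lambda / lambda[1L] >= 1e-12
  lambda <- lambda[keep]
  u <- sv$u[, keep, drop = FALSE]
  L <- ncol(u)
  # sign fix: largest-|u| entry positive, first index on ties
  for (l in seq_len(L)) {
    i <- which.max(abs(u[, l]))
    if (u[i, l] < 0) u[, l] <- -u[, l]
  }
  v <- crossprod(u, x)                       # L x M contraction
  n <- nrow(x)
  sigma <- sqrt(colSums(sweep(u, 2L, colMeans(u), `-`)^2) / n)
  structure(list(
    scores = u,
    eigenvalues = lambda,
    loadings = v,
    score_sd = sigma,
    feature_ids = rownames(x),
    sample_ids = colnames(x)
  ), class = "pc_decomposition")
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat("pc_decomposition:", length(x$feature_ids), "features x",
      length(x$sample_ids), "samples,", length(x$eigenvalues),
      "components\n")
  cat("  top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5L), 4L), collapse = ", "),
      "\n")
  invisible(x)
}

#' Loadings by direct contraction
#'
#' \eqn{v_{lj} = \sum_i x_{ij} u_{li}} for arbitrary score vectors. For
#' scores from \code{\link{compute_pca}} this reproduces the stored
#' loadings.
#'
#' @param x expression matrix (N x M).
#' @param scores N x L matrix of per-feature score vectors.
#' @return L x M loading matrix.
#' @export
compute_loadings <- function(x, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(x))
    ufe_error(paste0("score rows (", nrow(scores),
                     ") do not match matrix features (", nrow(x), ")"),
              "ufe_dim_mismatch")
  crossprod(scores, x)
}

#' Test each component's loading for class association
#'
#' The printed model \eqn{v_{lj} = a_l + \sum_s b_{ls} \delta_{js}} with
#' both class indicators plus an intercept is rank-deficient; its
#' identifiable equivalent is a one-way two-group comparison, so per
#' component an equal-variance two-sample F test (F = t^2) is applied to
#' the loadings split by class. Coefficients are reported under sum-to-zero
#' coding: \code{a} is the midpoint of the class means and \code{b1 = -b2}
#' their half-difference. P-values are Benjamini-Hochberg corrected across
#' the component family.
#'
#' Degenerate branches: zero pooled within-class variance yields p = 1 when
#' the class means also agree (no evidence) and p = 0 with a warning when
#' they differ (infinite separation).
#'
#' @param loadings L x M loading matrix (rows = components).
#' @param annot \code{\link{sample_annotation}} aligned with the loading
#'   columns.
#' @return data frame with one row per component: \code{component},
#'   \code{a}, \code{b1}, \code{b2}, \code{f_stat}, \code{p_raw},
#'   \code{p_adjusted}.
#' @export
test_component_association <- function(loadings, annot) {
  loadings <- as.matrix(loadings)
  m <- ncol(loadings)
  if (m != nrow(annot))
    ufe_error("loading columns do not match annotation samples",
              "ufe_dim_mismatch")
  g <- as.integer(annot$class_label)      # 1 / 2, lexicographic order
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  if (n1 < 2L || n2 < 2L)
    ufe_error("association test needs >= 2 samples per class",
              "ufe_bad_annotation")
  L <- nrow(loadings)
  res <- data.frame(component = seq_len(L), a = NA_real_, b1 = NA_real_,
                    b2 = NA_real_, f_stat = NA_real_, p_raw = NA_real_)
  for (l in seq_len(L)) {
    v <- loadings[l, ]
    m1 <- mean(v[g == 1L]); m2 <- mean(v[g == 2L])
    ss_within <- sum((v[g == 1L] - m1)^2) + sum((v[g == 2L] - m2)^2)
    res$a[l] <- (m1 + m2) / 2
    res$b1[l] <- m1 - res$a[l]
    res$b2[l] <- m2 - res$a[l]
    if (ss_within <= 0) {
      if (isTRUE(all.equal(m1, m2))) {
        res$f_stat[l] <- 0; res$p_raw[l] <- 1
      } else {
        ufe_warning(paste0("component ", l,
                           ": zero within-class variance with distinct means"),
                    "ufe_degenerate_test")
        res$f_stat[l] <- Inf; res$p_raw[l] <- 0
      }
    } else {
      s2 <- ss_within / (m - 2L)
      f <- (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2))
      res$f_stat[l] <- f
      res$p_raw[l] <- stats::pf(f, 1L, m - 2L, lower.tail = FALSE)
    }
  }
  res$p_adjusted <- benjamini_hochberg(res$p_raw)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort the m raw p-values ascending, set \eqn{q_{(k)} = p_{(k)} m / k},
#' enforce monotonicity by a cumulative minimum from the largest rank, cap
#' at 1, and return the adjusted values in the original order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    ufe_error("p-values must be numbers in [0, 1]", "ufe_bad_pvalues")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Select class-associated components
#'
#' Retains the components whose BH-adjusted association p-value is strictly
#' below \code{alpha} (default .05). An explicit \code{override} set (as
#' used in the original analyses, e.g. a fixed Omega = \{5\}) takes
#' precedence and is reported via \code{message}.
#'
#' @param assocs result of \code{\link{test_component_association}}.
#' @param alpha significance level; strict \code{<}.
#' @param override optional integer vector of 1-based component indices.
#' @return sorted integer vector Omega of retained component indices.
#' @export
select_components <- function(assocs, alpha = 0.05, override = NULL) {
  if (!is.null(override)) {
    override <- sort(unique(as.integer(override)))
    if (any(override < 1L))
      ufe_error("component override indices must be >= 1", "ufe_bad_config")
    message("component set overridden manually: Omega = {",
            paste(override, collapse = ","), "}")
    return(override)
  }
  omega <- assocs$component[assocs$p_adjusted < alpha]
  if (!length(omega))
    ufe_error(paste0("no component passes BH-adjusted p < ", alpha,
                     "; supply an Omega override or raise alpha"),
              c("ufe_empty_components", "ufe_empty_selection"))
  sort(omega)
}

#' Chi-squared feature scoring on the retained components
#'
#' Each feature i gets the statistic
#' \eqn{T_i = \sum_{l \in \Omega} (u_{li} / \sigma_l)^2} and the p-value
#' \eqn{P_i = P[\chi^2_{|\Omega|} > T_i]}, the upper tail of the
#' chi-squared distribution with degrees of freedom equal to the number of
#' components actually summed.
#'
#' @param scores N x L score matrix.
#' @param score_sd per-component score dispersions \eqn{\sigma_l}.
#' @param omega integer vector of retained component indices.
#' @return data frame with \code{statistic} and \code{p_raw} per feature.
#' @export
score_features <- function(scores, score_sd, omega) {
  omega <- as.integer(omega)
  if (!length(omega))
    ufe_error("omega is empty", "ufe_bad_config")
  if (any(omega < 1L | omega > ncol(scores)))
    ufe_error("omega indexes a nonexistent component", "ufe_bad_config")
  if (any(score_sd[omega] <= 0))
    ufe_error("sigma_l = 0 for a component in omega", "ufe_degenerate_test")
  z <- sweep(scores[, omega, drop = FALSE], 2L, score_sd[omega], `/`)
  t_stat <- rowSums(z^2)
  data.frame(statistic = t_stat,
             p_raw = stats::pchisq(t_stat, df = length(omega),
                                   lower.tail = FALSE))
}

#' BH-select features from chi-squared p-values
#'
#' @param p_raw per-feature raw p-values.
#' @param alpha significance level (default .01); strict \code{<} on the
#'   BH-adjusted values.
#' @return list with \code{p_adjusted} and logical \code{selected}.
#' @export
select_features <- function(p_raw, alpha = 0.01) {
  p_adj <- benjamini_hochberg(p_raw)
  sel <- p_adj < alpha
  if (!any(sel))
    ufe_error(paste0("no feature passes BH-adjusted P < ", alpha,
                     "; raise alpha or adjust the Omega set"),
              c("ufe_empty_features", "ufe_empty_selection"))
  list(p_adjusted = p_adj, selected = sel)
}

#' Stage-2 decomposition on the selected features
#'
#' Restricts the stage-1 normalized matrix to the selected features and
#' recomputes scores and loadings there. By default the submatrix is
#' \emph{not} re-normalized: the procedure recomputes the loadings v, not
#' the normalized data x (set \code{renormalize = TRUE} for the
#' alternative). The stage-2 component set comes from \code{omega_override}
#' when given, otherwise from the association test and BH selection on the
#' new loadings.
#'
#' @param x stage-1 normalized expression matrix.
#' @param selected character vector (feature IDs) or logical mask of
#'   selected features; at least 2.
#' @param annot sample annotation (needed unless \code{omega_override}
#'   covers the selection).
#' @param omega_override optional fixed stage-2 component set.
#' @param alpha component-selection level when testing (default .05).
#' @param renormalize re-apply \code{\link{normalize_samples}} to the
#'   submatrix first.
#' @return list with \code{pca}, \code{associations} (NULL under an
#'   override without testing), and \code{omega}.
#' @export
recompute_stage2 <- function(x, selected, annot = NULL, omega_override = NULL,
                             alpha = 0.05, renormalize = FALSE) {
  if (is.logical(selected)) selected <- rownames(x)[selected]
  selected <- intersect(rownames(x), selected)
  if (length(selected) < 2L)
    ufe_error("stage 2 needs at least 2 selected features",
              "ufe_too_small")
  sub <- x[selected, , drop = FALSE]
  if (renormalize) sub <- normalize_samples(sub)
  pca <- compute_pca(sub, check_normalized = FALSE)
  assoc <- if (!is.null(annot))
    test_component_association(pca$loadings, annot) else NULL
  omega <- if (!is.null(omega_override)) {
    select_components(assocs = NULL, override = omega_override)
  } else {
    if (is.null(assoc))
      ufe_error("stage 2 needs an annotation or an omega override",
                "ufe_bad_config")
    select_components(assoc, alpha = alpha)
  }
  if (any(omega > length(pca$eigenvalues)))
    ufe_error("stage-2 omega override exceeds available components",
              "ufe_bad_config")
  list(pca = pca, associations = assoc, omega = omega)
}

#' Run the full unsupervised feature-extraction procedure
#'
#' Executes, in order: normalization check, PCA scores and loadings,
#' per-component class-association F tests with BH correction, component
#' selection (adjusted p < \code{alpha_components}, or a manual override),
#' chi-squared feature scoring on the retained components, BH feature
#' selection (adjusted P < \code{alpha_features}), and the stage-2
#' decomposition restricted to the selected features. Deterministic given
#' its inputs.
#'
#' @param x normalized expression matrix.
#' @param annot aligned \code{\link{sample_annotation}}.
#' @param alpha_components component-level BH threshold (default .05).
#' @param alpha_features feature-level BH threshold (default .01).
#' @param omega1,omega2 optional manual component sets for stage 1 / 2.
#' @param renormalize_stage2 re-normalize the stage-2 submatrix.
#' @param fallback_stage1 when feature selection comes up empty, do not
#'   error: return a result with zero selected features whose \code{stage2}
#'   is the stage-1 decomposition and Omega set (flagged
#'   \code{fallback = TRUE}), so discrimination can still proceed on the
#'   stage-1 loadings. Off by default; the pipeline front end enables it.
#' @return object of class \code{"ufe_result"}: list with \code{stage1}
#'   (pca, associations, omega), \code{feature_stats} (per-feature
#'   statistic, raw and adjusted P, selected flag), \code{selected_features}
#'   and \code{stage2} (pca, associations, omega).
#' @export
run_ufe <- function(x, annot, alpha_components = 0.05, alpha_features = 0.01,
                    omega1 = NULL, omega2 = NULL, renormalize_stage2 = FALSE,
                    fallback_stage1 = FALSE) {
  if (!identical(colnames(x), annot$sample_id))
    ufe_error("matrix and annotation are not aligned; call align_samples()",
              "ufe_dim_mismatch")
  if (!is_normalized(x))
    ufe_error("run_ufe expects a normalized matrix", "ufe_not_normalized")

  pca <- compute_pca(x)
  assoc <- test_component_association(pca$loadings, annot)
  omega_1 <- if (fallback_stage1) {
    tryCatch(
      select_components(assoc, alpha = alpha_components, override = omega1),
      ufe_empty_components = function(e) {
        best <- assoc$component[which.min(assoc$p_raw)]
        ufe_warning(paste0("no component passed BH selection; retaining the ",
                           "best-associated component ", best,
                           " (exploratory)"),
                    "ufe_component_fallback")
        best
      })
  } else {
    select_components(assoc, alpha = alpha_components, override = omega1)
  }
  if (any(omega_1 > length(pca$eigenvalues)))
    ufe_error("stage-1 omega override exceeds available components",
              "ufe_bad_config")

  fstat <- score_features(pca$scores, pca$score_sd, omega_1)
  fsel <- if (fallback_stage1) {
    tryCatch(select_features(fstat$p_raw, alpha = alpha_features),
             ufe_empty_features = function(e) NULL)
  } else {
    select_features(fstat$p_raw, alpha = alpha_features)
  }
  if (is.null(fsel))
    fsel <- list(p_adjusted = benjamini_hochberg(fstat$p_raw),
                 selected = rep(FALSE, length(fstat$p_raw)),
                 fallback = TRUE)
  feature_stats <- data.frame(
    feature_id = pca$feature_ids,
    statistic = fstat$statistic,
    p_raw = fstat$p_raw,
    p_adjusted = fsel$p_adjusted,
    selected = fsel$selected,
    stringsAsFactors = FALSE
  )
  selected <- feature_stats$feature_id[feature_stats$selected]

  if (!isTRUE(fsel$fallback) && fallback_stage1 && length(selected) < 2L)
    fsel$fallback <- TRUE                  # stage 2 needs >= 2 features
  stage2 <- if (isTRUE(fsel$fallback)) {
    ufe_warning("feature selection too small for stage 2; falling back to the stage-1 decomposition",
                "ufe_stage1_fallback")
    list(pca = pca, associations = assoc, omega = omega_1, fallback = TRUE)
  } else {
    recompute_stage2(x, selected, annot = annot,
                     omega_override = omega2,
                     alpha = alpha_components,
                     renormalize = renormalize_stage2)
  }

  structure(list(
    stage1 = list(pca = pca, associations = assoc, omega = omega_1),
    feature_stats = feature_stats,
    selected_features = selected,
    stage2 = stage2
  ), class = "ufe_result")
}

#' @export
print.ufe_result <- function(x, ...) {
  cat("ufe_result\n")
  cat("  stage 1: Omega = {", paste(x$stage1$omega, collapse = ","), "}\n")
  cat("  selected features:", length(x$selected_features), "of",
      nrow(x$feature_stats), "\n")
  cat("  stage 2: Omega = {", paste(x$stage2$omega, collapse = ","), "}",
      if (isTRUE(x$stage2$fallback)) "(stage-1 fallback)", "\n")
  invisible(x)
}
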