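#' Log2-transform raw intensities
#'
#' Microarray intensities behave multiplicatively; when enabled this step
#' precedes sample normalization. Values become
#' \code{log2(value + pseudocount)}.
#'
#' @param x expression matrix with non-negative values.
#' @param pseudocount positive offset guarding \code{log2(0)}; default 1.
#' @return transformed expression matrix.
#' @export
log_transform <- function(x, pseudocount = 1) {
  validate_expression_matrix(x)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    ufe_error("pseudocount must be a single positive number", "ufe_bad_config")
  if (any(x < 0))
    ufe_error("log transform requires non-negative values", "ufe_bad_matrix")
  out <- log2(x + pseudocount)
  dimnames(out) <- dimnames(x)
  out
}

#' Normalize each sample to zero mean and fixed energy
#'
#' For every sample column j the values across features are centred and
#' scaled so that \eqn{\sum_i x_{ij} = 0} and \eqn{\sum_i x_{ij}^2 = N},
#' where N is the number of features. The scale uses the population
#' (N-denominator) standard deviation so the energy constraint holds
#' exactly. Note the direction: normalization runs across features within
#' each sample, not across samples within a feature.
#'
#' The map is idempotent, preserves within-sample rank order, and is
#' invariant to positive affine rescalings applied per sample.
#'
#' @param x expression matrix; every column must have nonzero variance
#'   across features.
#' @return normalized expression matrix.
#' @export
normalize_samples <- function(x) {
  validate_expression_matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  ctr <- sweep(x, 2L, mu, `-`)
  s <- sqrt(colSums(ctr^2) / n)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero))
    ufe_error(paste0("constant sample column(s): ",
                     paste(colnames(x)[zero], collapse = ", ")),
              "ufe_constant_column")
  out <- sweep(ctr, 2L, s, `/`)
  dimnames(out) <- dimnames(x)
  out
}

# TRUE when every column satisfies the centering and energy constraints.
is_normalized <- function(x, tol = 1e-6) {
  n <- nrow(x)
  all(abs(colSums(x)) <= tol * n) &&
    all(abs(colSums(x^2) - n) <= tol * n)
}
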