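#' Generate a two-class synthetic expression cohort with planted features
#'
#' Emulates a two-class circulating-miRNA microarray cohort: each feature i
#' draws a baseline log2 mean \eqn{m_i} uniformly from
#' \code{baseline_range}; a planted subset of \code{n_informative} features
#' receives an additive log2 shift of \eqn{\pm}\code{effect_size} (random
#' sign) in class 2; Gaussian noise with SD \code{noise_sd} (log2 units) is
#' added per cell; intensities are \eqn{2^{(\cdot)}}, i.e. multiplicative
#' log-normal noise on the raw scale. Features are independent — no
#' correlation structure is emulated.
#'
#' Defaults mirror a miRNA-array-scale design: 2000 features, 30 + 30
#' samples, 20 informative features, effect 1.5 log2 units, noise SD 1.0.
#'
#' @param n_features total number of features.
#' @param n_class1,n_class2 samples per class (class 1 carries the
#'   lexicographically smaller label).
#' @param n_informative number of planted differential features.
#' @param effect_size class-2 log2 shift magnitude for planted features.
#' @param noise_sd log2-scale noise SD, > 0.
#' @param baseline_range range of baseline log2 means.
#' @param labels two class label strings.
#' @param seed integer RNG seed; identical seed + params reproduce the
#'   cohort exactly.
#' @return object of class \code{"synthetic_cohort"}: \code{matrix} (raw
#'   intensity expression matrix), \code{annot}
#'   (\code{\link{sample_annotation}}), \code{truth} (planted feature IDs),
#'   \code{params}.
#' @export
generate_two_class_cohort <- function(n_features = 2000L,
                                      n_class1 = 30L, n_class2 = 30L,
                                      n_informative = 20L,
                                      effect_size = 1.5,
                                      noise_sd = 1.0,
                                      baseline_range = c(4, 14),
                                      labels = c("classA", "classB"),
                                      seed = 1L) {
  if (n_informative < 0L || n_features < n_informative)
    ufe_error("need n_features >= n_informative >= 0", "ufe_bad_config")
  if (n_class1 < 2L || n_class2 < 2L)
    ufe_error("both class sizes must be >= 2", "ufe_bad_config")
  if (noise_sd <= 0)
    ufe_error("noise_sd must be > 0", "ufe_bad_config")
  if (length(labels) != 2L || labels[1L] == labels[2L])
    ufe_error("labels must be two distinct strings", "ufe_bad_config")
  labels <- sort(trimws(labels), method = "radix")

  params <- list(n_features = n_features, n_class1 = n_class1,
                 n_class2 = n_class2, n_informative = n_informative,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_range = baseline_range, labels = labels,
                 seed = as.integer(seed))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)

  n_samp <- n_class1 + n_class2
  feature_ids <- sprintf("synth-miR-%04d", seq_len(n_features))
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  class_labels <- rep(labels, c(n_class1, n_class2))

  m_i <- stats::runif(n_features, baseline_range[1L], baseline_range[2L])
  truth_idx <- if (n_informative > 0L)
    sort(sample.int(n_features, n_informative)) else integer(0)
  delta <- numeric(n_features)
  if (n_informative > 0L)
    delta[truth_idx] <- effect_size *
      sample(c(-1, 1), n_informative, replace = TRUE)

  log2_val <- matrix(m_i, n_features, n_samp) +
    outer(delta, as.numeric(class_labels == labels[2L])) +
    matrix(stats::rnorm(n_features * n_samp, sd = noise_sd),
           n_features, n_samp)
  mat <- 2^log2_val
  dimnames(mat) <- list(feature_ids, sample_ids)

  structure(list(
    matrix = mat,
    annot = sample_annotation(sample_ids, class_labels),
    truth = feature_ids[truth_idx],
    params = params
  ), class = "synthetic_cohort")
}

#' Generate an exact-null cohort (no planted features)
#'
#' \code{\link{generate_two_class_cohort}} with \code{n_informative} forced
#' to 0; class labels are exchangeable by construction.
#'
#' @param ... passed through; any \code{n_informative} given is overridden.
#' @return a \code{"synthetic_cohort"} with empty \code{truth}.
#' @export
generate_null_cohort <- function(...) {
  args <- list(...)
  args$n_informative <- 0L
  do.call(generate_two_class_cohort, args)
}

#' Cohort-design presets for realistic imbalance regimes
#'
#' Returns generator parameters whose class sizes reproduce the clinical
#' cohort designs this generator emulates: 36 HCV-HCC vs 9 SVR-HCC on the miRBase-v20 chip (2555
#' features), 68 vs 22 on the v21 chip (2588 features), and 177 HCC vs 43
#' BTC on the v21 chip.
#'
#' @param name one of \code{"v20_hcv_svr"}, \code{"v21_hcv_svr"},
#'   \code{"v21_hcc_btc"}.
#' @return a named list of arguments for
#'   \code{\link{generate_two_class_cohort}}.
#' @export
imbalance_preset <- function(name) {
  presets <- list(
    v20_hcv_svr = list(n_features = 2555L, n_class1 = 36L, n_class2 = 9L,
                       labels = c("HCV_HCC", "SVR_HCC")),
    v21_hcv_svr = list(n_features = 2588L, n_class1 = 68L, n_class2 = 22L,
                       labels = c("HCV_HCC", "SVR_HCC")),
    v21_hcc_btc = list(n_features = 2588L, n_class1 = 43L, n_class2 = 177L,
                       labels = c("BTC", "HCC"))
  )
  if (!name %in% names(presets))
    ufe_error(paste0("unknown preset '", name, "'; available: ",
                     paste(names(presets), collapse = ", ")),
              "ufe_bad_config")
  presets[[name]]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat("synthetic_cohort:", p$n_features, "features x",
      p$n_class1 + p$n_class2, "samples (",
      p$n_class1, "+", p$n_class2, "),",
      length(x$truth), "planted, effect", p$effect_size,
      ", noise sd", p$noise_sd, ", seed", p$seed, "\n")
  invisible(x)
}
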