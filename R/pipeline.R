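#' Build and validate a pipeline configuration
#'
#' @param matrix_path,annot_path input files (ignored when
#'   \code{simulate} is a preset name or parameter list).
#' @param out_dir output directory for result tables.
#' @param alpha_components,alpha_features BH thresholds in (0, 1).
#' @param omega1,omega2 optional manual component sets (positive integers).
#' @param log2 apply \code{\link{log_transform}} before normalization.
#' @param pseudocount log-transform offset.
#' @param mode evaluation mode, \code{"in_sample"} or \code{"loocv"}.
#' @param simulate \code{NULL}, a preset name (see
#'   \code{\link{imbalance_preset}}), or a list of generator arguments.
#' @param seed integer seed for all randomness.
#' @param renormalize_stage2 see \code{\link{recompute_stage2}}.
#' @param fallback_stage1 complete the run on the stage-1 loadings when
#'   feature selection is empty (see \code{\link{run_ufe}}); on by
#'   default so weak cohorts still yield a report.
#' @return validated config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(matrix_path = NULL, annot_path = NULL,
                            out_dir = "results",
                            alpha_components = 0.05, alpha_features = 0.01,
                            omega1 = NULL, omega2 = NULL,
                            log2 = FALSE, pseudocount = 1,
                            mode = c("in_sample", "loocv"),
                            simulate = NULL, seed = 1L,
                            renormalize_stage2 = FALSE,
                            fallback_stage1 = TRUE) {
  mode <- match.arg(mode)
  for (a in c(alpha_components, alpha_features))
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
      ufe_error("alpha thresholds must lie strictly in (0, 1)",
                "ufe_bad_config")
  for (om in list(omega1, omega2))
    if (!is.null(om) && (anyNA(om) || any(om < 1) || any(om != floor(om))))
      ufe_error("omega overrides must be positive integers", "ufe_bad_config")
  if (is.null(simulate) && is.null(matrix_path))
    ufe_error("need matrix_path + annot_path, or simulate", "ufe_bad_config")
  structure(list(
    matrix_path = matrix_path, annot_path = annot_path, out_dir = out_dir,
    alpha_components = alpha_components, alpha_features = alpha_features,
    omega1 = omega1, omega2 = omega2, log2 = log2,
    pseudocount = pseudocount, mode = mode, simulate = simulate,
    seed = as.integer(seed), renormalize_stage2 = renormalize_stage2,
    fallback_stage1 = fallback_stage1
  ), class = c("pipeline_config", "list"))
}

# config echo for the JSON summary: drop NULLs, keep scalars unboxed
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$simulate <- if (is.character(cfg$simulate)) cfg$simulate
    else if (is.list(cfg$simulate)) cfg$simulate
    else NULL
  Filter(Negate(is.null), cfg)
}

#' Run the full pipeline: (simulate |form read) -> normalize -> extract ->
#' discriminate -> write
#'
#' Stages: obtain the cohort (synthetic generator or files), optional log2
#' transform, per-sample normalization, \code{\link{run_ufe}}, then either
#' in-sample discrimination on the stage-2 loadings or
#' \code{\link{loocv_evaluate}}, and finally
#' \code{\link{write_result_tables}}. Fully deterministic given config and
#' seed. Stage failures are re-raised with the stage name prefixed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with \code{ufe}, \code{disc}, \code{truth}
#'   (synthetic runs only) and \code{files}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  stage <- function(name, expr) {
    tryCatch(expr, pcaufe_error = function(e) {
      ufe_error(paste0("[stage ", name, "] ", conditionMessage(e)),
                class(e)[1L])
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    args <- if (is.character(config$simulate))
      imbalance_preset(config$simulate) else config$simulate
    args$seed <- args$seed %||% config$seed
    cohort <- stage("simulate", do.call(generate_two_class_cohort, args))
    mat <- cohort$matrix
    annot <- cohort$annot
    truth <- cohort$truth
  } else {
    mat <- stage("read", read_expression_matrix(config$matrix_path))
    annot <- stage("read", read_sample_annotation(config$annot_path))
  }

  aligned <- stage("align", align_samples(mat, annot))
  mat <- aligned$matrix
  annot <- aligned$annot

  if (isTRUE(config$log2))
    mat <- stage("log2", log_transform(mat, config$pseudocount))
  norm <- stage("normalize", normalize_samples(mat))

  ufe <- stage("ufe", run_ufe(
    norm, annot,
    alpha_components = config$alpha_components,
    alpha_features = config$alpha_features,
    omega1 = config$omega1, omega2 = config$omega2,
    renormalize_stage2 = config$renormalize_stage2,
    fallback_stage1 = config$fallback_stage1))

  disc <- if (config$mode == "loocv") {
    stage("evaluate", loocv_evaluate(
      norm, annot,
      alpha_components = config$alpha_components,
      alpha_features = config$alpha_features,
      omega1 = config$omega1, omega2 = config$omega2,
      renormalize_stage2 = config$renormalize_stage2,
      fallback_stage1 = config$fallback_stage1))
  } else {
    stage("evaluate", discriminate_loadings(ufe, annot))
  }

  cfg_echo <- config_echo(config)
  files <- stage("write",
                 write_result_tables(ufe, disc, config$out_dir, cfg_echo))
  invisible(list(ufe = ufe, disc = disc, truth = truth, files = files))
}

#' Command-line entry point
#'
#' Thin argument parser around the pipeline, used by
#' \code{inst/cli/ufe.R}. Subcommands: \code{simulate} (write a synthetic
#' cohort to TSV/CSV), \code{run} (full pipeline on files or a preset).
#'
#' @param args character vector, e.g. \code{commandArgs(TRUE)}.
#' @return exit status (0 on success), invisibly.
#' @export
ufe_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  ufe simulate --preset NAME --seed N --out DIR",
    "  ufe run [--matrix F --annot F | --preset NAME] [--seed N]",
    "          [--log2] [--mode in_sample|loocv] [--omega1 a,b] [--omega2 a,b]",
    "          [--alpha-components X] [--alpha-features X] --out DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    args[i[1L] + 1L]
  }
  has <- function(flag) flag %in% args
  parse_ints <- function(s) if (is.null(s)) NULL
    else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])

  status <- tryCatch({
    if (cmd == "simulate") {
      preset <- opt("--preset")
      gen <- if (!is.null(preset)) imbalance_preset(preset) else list()
      gen$seed <- as.integer(opt("--seed", "1"))
      cohort <- do.call(generate_two_class_cohort, gen)
      out <- opt("--out", "cohort")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_expression_matrix(cohort$matrix, file.path(out, "matrix.tsv"))
      write_sample_annotation(cohort$annot, file.path(out, "annotation.csv"))
      writeLines(c("feature_id", cohort$truth), file.path(out, "truth.tsv"))
      message("cohort written to ", out)
      0L
    } else if (cmd == "run") {
      config <- pipeline_config(
        matrix_path = opt("--matrix"), annot_path = opt("--annot"),
        out_dir = opt("--out", "results"),
        alpha_components = as.numeric(opt("--alpha-components", "0.05")),
        alpha_features = as.numeric(opt("--alpha-features", "0.01")),
        omega1 = parse_ints(opt("--omega1")),
        omega2 = parse_ints(opt("--omega2")),
        log2 = has("--log2"),
        mode = opt("--mode", "in_sample"),
        simulate = opt("--preset"),
        seed = as.integer(opt("--seed", "1")))
      run_pipeline(config)
      message("results written to ", config$out_dir)
      0L
    } else {
      message(usage)
      1L
    }
  }, pcaufe_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
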