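#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix whose rows are features
#' (e.g. miRNAs, identified by their platform names) and whose columns are
#' samples. \code{x[i, j]} is the expression of feature \code{i} in sample
#' \code{j}, either on the raw intensity scale or after preprocessing.
#' Identifiers live in \code{dimnames} and must be unique; downstream
#' analysis requires at least two features and two samples.
#'
#' @param values numeric matrix, or something coercible to one.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of \code{values}.
#' @return a validated numeric matrix with feature row names and sample
#'   column names.
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

validate_expression_matrix <- function(x, require_finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    ufe_error("expression matrix must be a numeric matrix", "ufe_bad_matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    ufe_error("expression matrix needs feature row names and sample column names",
              "ufe_bad_matrix")
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f))
    ufe_error(paste0("duplicate feature IDs: ", paste(dup_f, collapse = ", ")),
              "ufe_duplicate_ids")
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    ufe_error(paste0("duplicate sample IDs: ", paste(dup_s, collapse = ", ")),
              "ufe_duplicate_ids")
  if (nrow(x) < 2L)
    ufe_error("expression matrix needs at least 2 features", "ufe_too_small")
  if (ncol(x) < 2L)
    ufe_error("expression matrix needs at least 2 samples", "ufe_too_small")
  if (require_finite && !all(is.finite(x)))
    ufe_error("expression matrix contains non-finite values", "ufe_bad_matrix")
  invisible(x)
}

#' Construct a two-class sample annotation
#'
#' Maps sample IDs to exactly two distinct class labels. Labels are
#' whitespace-trimmed; class index 1 is assigned to the lexicographically
#' smaller label (C collation) and class 2 to the larger, so the indicator
#' coding is reproducible regardless of file order.
#'
#' @param sample_ids character vector of unique sample IDs.
#' @param class_labels character vector, one label per sample; exactly two
#'   distinct values, each carried by at least two samples.
#' @return a data frame of class \code{"sample_annotation"} with columns
#'   \code{sample_id} and \code{class_label} (a two-level factor; level
#'   order = class index order).
#' @export
sample_annotation <- function(sample_ids, class_labels) {
  sample_ids <- as.character(sample_ids)
  class_labels <- trimws(as.character(class_labels))
  if (length(sample_ids) != length(class_labels))
    ufe_error("sample_ids and class_labels differ in length", "ufe_bad_annotation")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    ufe_error(paste0("duplicate sample IDs in annotation: ",
                     paste(dup, collapse = ", ")), "ufe_duplicate_ids")
  lev <- sort(unique(class_labels), method = "radix")
  if (length(lev) != 2L)
    ufe_error(paste0("annotation must have exactly 2 class labels, found ",
                     length(lev), ": ", paste(lev, collapse = ", ")),
              "ufe_bad_annotation")
  cls <- factor(class_labels, levels = lev)
  if (any(table(cls) < 2L))
    ufe_error("each class needs at least 2 samples for association testing",
              "ufe_bad_annotation")
  structure(
    data.frame(sample_id = sample_ids, class_label = cls,
               stringsAsFactors = FALSE),
    class = c("sample_annotation", "data.frame")
  )
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects the layout exported from feature-by-sample array tables: row 1 is
#' a header \code{feature_id<TAB>sample1<TAB>...}, each subsequent row is one
#' feature. Cells must parse as numbers or equal the missing token; features
#' containing any missing value are dropped (with a message reporting the
#' count), since every downstream stage requires a complete matrix.
#'
#' @param path file path.
#' @param missing_token string regarded as missing (default \code{"NA"}).
#' @return an expression matrix (see \code{\link{expression_matrix}}).
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  if (!file.exists(path))
    ufe_error(paste0("file not found: ", path), "ufe_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    ufe_error("expression file needs a header plus at least one feature row",
              "ufe_io_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 3L)
    ufe_error("expression file needs at least 2 sample columns", "ufe_too_small")
  ncol_exp <- length(header)
  bad <- which(vapply(fields[-1L], length, 1L) != ncol_exp)
  if (length(bad))
    ufe_error(paste0("ragged row at line ", bad[1L] + 1L, ": expected ",
                     ncol_exp, " fields"), "ufe_io_error")
  feature_ids <- vapply(fields[-1L], `[[`, "", 1L)
  body <- vapply(fields[-1L], function(f) f[-1L], character(ncol_exp - 1L))
  body <- if (is.null(dim(body))) matrix(body, nrow = 1L) else t(body)
  is_missing <- body == missing_token
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  unparsed <- !is.finite(num) & !is_missing
  if (any(unparsed)) {
    idx <- which(unparsed, arr.ind = TRUE)[1L, ]
    ufe_error(paste0("cannot parse cell at line ", idx[1L] + 1L, ", column ",
                     idx[2L] + 1L, ": '", body[idx[1L], idx[2L]], "'"),
              "ufe_io_error")
  }
  drop <- rowSums(is_missing) > 0L
  if (any(drop)) {
    message(sum(drop), " feature(s) dropped for missing values")
    num <- num[!drop, , drop = FALSE]
    feature_ids <- feature_ids[!drop]
  }
  rownames(num) <- feature_ids
  colnames(num) <- header[-1L]
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to a tab-delimited file
#'
#' Values are serialized in scientific notation with 12 significant digits so
#' read/write round trips are stable to that precision.
#'
#' @param x expression matrix.
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r)
    paste(sprintf("%.11e", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a two-column sample annotation file
#'
#' @param path delimited file with columns \code{sample_id},
#'   \code{class_label}; tab or comma delimited (sniffed from the first
#'   line).
#' @param header logical; does the file carry a header row?
#' @return a \code{\link{sample_annotation}}.
#' @export
read_sample_annotation <- function(path, header = TRUE) {
  if (!file.exists(path))
    ufe_error(paste0("file not found: ", path), "ufe_io_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    ufe_error("annotation needs two columns: sample_id, class_label",
              "ufe_io_error")
  sample_annotation(df[[1L]], df[[2L]])
}

#' Write a sample annotation to CSV
#' @param annot a \code{\link{sample_annotation}}.
#' @param path output file path.
#' @export
write_sample_annotation <- function(annot, path) {
  utils::write.table(
    data.frame(sample_id = annot$sample_id,
               class_label = as.character(annot$class_label)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with a sample annotation
#'
#' Both objects are restricted to the samples present in both, in the order
#' of the matrix columns. Dropped samples are reported via \code{message}.
#'
#' @param x expression matrix.
#' @param annot a \code{\link{sample_annotation}}.
#' @return a list with elements \code{matrix} and \code{annot}.
#' @export
align_samples <- function(x, annot) {
  validate_expression_matrix(x)
  common <- intersect(colnames(x), annot$sample_id)
  if (!length(common))
    ufe_error("no samples shared between matrix and annotation",
              "ufe_empty_intersection")
  keep <- colnames(x)[colnames(x) %in% common]
  drop_m <- setdiff(colnames(x), keep)
  drop_a <- setdiff(annot$sample_id, keep)
  if (length(drop_m))
    message("dropping ", length(drop_m), " unannotated matrix sample(s)")
  if (length(drop_a))
    message("dropping ", length(drop_a), " annotation-only sample(s)")
  x2 <- x[, keep, drop = FALSE]
  idx <- match(keep, annot$sample_id)
  annot2 <- sample_annotation(annot$sample_id[idx],
                              as.character(annot$class_label)[idx])
  list(matrix = x2, annot = annot2)
}

# Deterministic 12-significant-digit serialization used by all result tables.
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.11e", x))

#' Write pipeline result tables
#'
#' Writes three files under \code{out_dir}:
#' \itemize{
#'   \item \code{features.tsv}: per-feature chi-squared statistic, raw and
#'     BH-adjusted p-value, selected flag;
#'   \item \code{components.tsv}: per-component eigenvalue, association
#'     p-values, membership in the retained set Omega;
#'   \item \code{summary.json}: Omega per stage, selected-feature count,
#'     confusion matrix, AUC, evaluation mode, config echo and seed.
#' }
#'
#' @param ufe a \code{\link{run_ufe}} result.
#' @param disc a discrimination result (may be \code{NULL} when
#'   discrimination was impossible, e.g. empty selection).
#' @param out_dir output directory, created if needed.
#' @param config list echoed verbatim into the JSON summary.
#' @return invisibly, the paths written.
#' @export
write_result_tables <- function(ufe, disc, out_dir, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    ufe_error(paste0("cannot create output directory: ", out_dir),
              "ufe_io_error")

  fs <- ufe$feature_stats
  ftab <- file.path(out_dir, "features.tsv")
  utils::write.table(
    data.frame(feature_id = fs$feature_id,
               chisq = fmt_num(fs$statistic),
               p_raw = fmt_num(fs$p_raw),
               p_adjusted = fmt_num(fs$p_adjusted),
               selected = as.integer(fs$selected)),
    ftab, sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- ufe$stage1$associations
  ctab <- file.path(out_dir, "components.tsv")
  utils::write.table(
    data.frame(component = assoc$component,
               eigenvalue = fmt_num(ufe$stage1$pca$eigenvalues[assoc$component]),
               p_raw = fmt_num(assoc$p_raw),
               p_adjusted = fmt_num(assoc$p_adjusted),
               in_omega = as.integer(assoc$component %in% ufe$stage1$omega)),
    ctab, sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    omega_stage1 = as.integer(ufe$stage1$omega),
    omega_stage2 = as.integer(ufe$stage2$omega),
    stage1_fallback = isTRUE(ufe$stage2$fallback),
    n_selected_features = sum(fs$selected),
    selected_features = fs$feature_id[fs$selected],
    config = config
  )
  if (!is.null(disc)) {
    summary$evaluation_mode <- disc$mode
    summary$auc <- disc$auc
    summary$confusion <- as.list(as.data.frame(disc$confusion))
    summary$confusion_layout <- "predicted x true"
  }
  jpath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  if (!is.null(disc)) {
    rtab <- file.path(out_dir, "roc.tsv")
    utils::write.table(
      data.frame(threshold = fmt_num(disc$roc$threshold),
                 fpr = fmt_num(disc$roc$fpr),
                 tpr = fmt_num(disc$roc$tpr)),
      rtab, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list.files(out_dir, full.names = TRUE))
}
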