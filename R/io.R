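sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a gene-by-sample expression table
#'
#' Expects a delimited text file with gene ids in the first column and a
#' header row of sample ids; the delimiter (tab or comma) is sniffed from
#' the header unless forced. Non-numeric or missing cells and duplicate ids
#' are reported with their coordinates.
#'
#' @param path File path.
#' @param sep Optional delimiter override.
#' @return A validated expression matrix.
#' @export
read_expression <- function(path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    bfx_error(sprintf("duplicate gene id(s) in %s: %s", path,
                      paste(dup, collapse = ", ")),
              "duplicate_id_error", list(ids = dup))
  }
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (length(gene_ids) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    bfx_error(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                      gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
              "parse_error",
              list(gene = gene_ids[bad[1L, 1L]],
                   sample = sample_ids[bad[1L, 2L]]))
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix as TSV
#'
#' Values are formatted at full double precision by default (`%.17g`), so a
#' write/read round trip is exact and unchanged values re-serialize to
#' identical bytes (the reference-batch bit-identity guarantee survives file
#' I/O).
#'
#' @param Y Gene-by-sample matrix.
#' @param path Output path.
#' @param digits Significant digits (NA = full precision).
#' @param sep Field delimiter.
#' @export
write_expression <- function(Y, path, digits = NA, sep = "\t") {
  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  chr <- matrix(sprintf(fmt, Y), nrow(Y))
  lines <- c(paste(c("gene_id", colnames(Y)), collapse = sep),
             paste(rownames(Y), apply(chr, 1, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample metadata into a study design
#'
#' Samples are matched to the expression matrix by id (never by row order);
#' the returned design is aligned to `sample_ids`. Categorical covariate
#' columns are expanded to treatment-coded indicators.
#'
#' @param path Metadata file (TSV/CSV), one row per sample. The sample-id
#'   column is `id_col` (default: first column).
#' @param batch_col Name of the batch column.
#' @param covariate_cols Character vector of covariate column names (may be
#'   empty).
#' @param sample_ids Sample ids of the expression matrix, defining order.
#' @param reference_batch Optional reference batch label.
#' @param id_col Optional sample-id column name.
#' @param sep Optional delimiter override.
#' @return A [study_design()] aligned to `sample_ids`.
#' @export
read_metadata <- function(path, batch_col, covariate_cols = character(),
                          sample_ids, reference_batch = NULL, id_col = NULL,
                          sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- colnames(df)[1L]
  for (col in c(id_col, batch_col, covariate_cols)) {
    if (!col %in% colnames(df)) {
      bfx_error(sprintf("column '%s' not found in %s", col, path),
                "missing_column_error", list(column = col))
    }
  }
  ids <- as.character(df[[id_col]])
  extra <- setdiff(ids, sample_ids)
  missing <- setdiff(sample_ids, ids)
  if (length(extra) || length(missing)) {
    bfx_error(sprintf(
      "sample ids disagree between metadata and expression%s%s",
      if (length(missing)) paste0("; missing from metadata: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; only in metadata: ",
                                paste(extra, collapse = ", ")) else ""),
      "missing_sample_error", list(missing = missing, extra = extra))
  }
  df <- df[match(sample_ids, ids), , drop = FALSE]
  covariates <- if (length(covariate_cols)) {
    expand_covariates(df[covariate_cols])
  } else NULL
  study_design(batch = df[[batch_col]], covariates = covariates,
               reference_batch = reference_batch)
}
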