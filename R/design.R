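#' Validate a gene-by-sample expression matrix
#'
#' Expression values are modeled on a continuous (log) scale with genes in
#' rows and samples in columns. The matrix must be fully numeric and finite:
#' the location-scale model has no missing-data path, so missing values must
#' be imputed or filtered upstream.
#'
#' @param values Numeric matrix (or object coercible to one), genes in rows,
#'   samples in columns.
#' @param gene_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @return The validated numeric matrix with gene ids as rownames and sample
#'   ids as colnames.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    bfx_error("expression values must be numeric", "parse_error")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene_%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    bfx_error("need at least 2 genes and 2 samples", "dimension_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    bfx_error(sprintf("duplicate gene ids: %s", paste(dup, collapse = ", ")),
              "duplicate_id_error", list(ids = dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    bfx_error(sprintf("duplicate sample ids: %s", paste(dup, collapse = ", ")),
              "duplicate_id_error", list(ids = dup))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    bfx_error(sprintf("non-finite expression value at gene '%s', sample '%s'",
                      rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
              "parse_error",
              list(gene = rownames(values)[bad[1L]],
                   sample = colnames(values)[bad[2L]]))
  }
  values
}

#' Describe the study layout: batches, covariates, optional reference batch
#'
#' @param batch Per-sample batch labels (coerced to factor).
#' @param covariates Optional numeric matrix of biological covariates, one
#'   row per sample (use [expand_covariates()] for categorical variables).
#' @param reference_batch Optional batch label designating the batch that
#'   reference-mode adjustment leaves unchanged.
#' @return An object of class `study_design`.
#' @export
study_design <- function(batch, covariates = NULL, reference_batch = NULL) {
  batch <- as.factor(batch)
  if (anyNA(batch)) bfx_error("missing batch labels", "parse_error")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates)) {
      bfx_error("covariates must be numeric; expand categoricals first",
                "parse_error")
    }
    if (nrow(covariates) != length(batch)) {
      bfx_error(sprintf("covariate rows (%d) do not match samples (%d)",
                        nrow(covariates), length(batch)), "dimension_error")
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- sprintf("cov_%d", seq_len(ncol(covariates)))
    }
    if (ncol(covariates) == 0L) covariates <- NULL
  }
  if (!is.null(reference_batch)) {
    reference_batch <- as.character(reference_batch)
    if (!reference_batch %in% levels(batch)) {
      bfx_error(sprintf("reference batch '%s' is not a batch level",
                        reference_batch), "parse_error")
    }
  }
  structure(list(batch = batch, covariates = covariates,
                 reference_batch = reference_batch),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d batches (%s)\n",
              length(x$batch), nlevels(x$batch),
              paste(sprintf("%s: n=%d", levels(x$batch), tabulate(x$batch)),
                    collapse = ", ")))
  cat(sprintf("  covariates: %s\n",
              if (is.null(x$covariates)) "none"
              else paste(colnames(x$covariates), collapse = ", ")))
  if (!is.null(x$reference_batch)) {
    cat(sprintf("  reference batch: %s\n", x$reference_batch))
  }
  invisible(x)
}

#' Expand categorical covariates to treatment-coded indicators
#'
#' Each factor/character column is expanded to indicator columns dropping the
#' first level; numeric columns pass through unchanged. This keeps the model
#' core free of formula-language semantics.
#'
#' @param df A data frame of covariates, one row per sample.
#' @return A numeric matrix.
#' @export
expand_covariates <- function(df) {
  df <- as.data.frame(df)
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
    } else {
      x <- as.factor(x)
      m <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, "_", levels(x)[-1])
    }
    m
  })
  do.call(cbind, cols)
}

#' Build the full design matrix: batch indicators then covariates
#'
#' @param design A [study_design()].
#' @param n_samples Expected number of samples (consistency check).
#' @return Numeric matrix with one indicator column per batch followed by
#'   covariate columns; verified to have full column rank.
#' @export
build_design_matrix <- function(design, n_samples = length(design$batch)) {
  stopifnot(inherits(design, "study_design"))
  if (length(design$batch) != n_samples) {
    bfx_error(sprintf("design has %d samples, expected %d",
                      length(design$batch), n_samples), "dimension_error")
  }
  batch <- design$batch
  X <- vapply(levels(batch), function(l) as.numeric(batch == l),
              numeric(length(batch)))
  if (!is.matrix(X)) X <- matrix(X, nrow = length(batch))
  colnames(X) <- levels(batch)
  if (!is.null(design$covariates)) X <- cbind(X, design$covariates)
  if (qr(X)$rank < ncol(X)) {
    bfx_error(paste("design matrix is rank deficient: batch is confounded",
                    "with the covariates (or covariates are collinear)"),
              "confounded_design_error")
  }
  X
}
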