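#' Validate a genes x samples expression matrix
#'
#' The package-wide input convention is a numeric matrix with genes in rows
#' and samples in columns, log-scale values (log2 microarray intensities or
#' log-CPM), unique row and column names, and no missing or non-finite
#' entries.
#'
#' @param x A numeric matrix, genes in rows, samples in columns.
#' @param arg Name used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
check_expression <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort(sprintf("`%s` must have at least 2 genes and 2 samples", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry gene ids as rownames and sample ids as colnames", arg))
  }
  dup_g <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_g) > 0L) {
    abort(sprintf("duplicate gene id(s) in `%s`: %s", arg,
                  paste(unique(dup_g), collapse = ", ")))
  }
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s) > 0L) {
    abort(sprintf("duplicate sample id(s) in `%s`: %s", arg,
                  paste(unique(dup_s), collapse = ", ")))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite value in `%s` at gene '%s', sample '%s'",
                  arg, rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and a
#' numeric body. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric genes x samples matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 3L) abort("expression TSV needs a gene-id column and >= 2 samples")
  genes <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(vals), arr.ind = TRUE)
    abort(sprintf(
      "non-numeric value '%s' at row %d (gene '%s'), column '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], genes[bad[1L, 1L]],
      colnames(df)[-1L][bad[1L, 2L]]))
  }
  rownames(vals) <- genes
  colnames(vals) <- colnames(df)[-1L]
  check_expression(vals, "expression file")
  vals
}

#' Write an expression matrix to TSV
#'
#' @param x Genes x samples numeric matrix.
#' @param path Output path.
#' @param id_column Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  check_expression(x)
  df <- tibble::as_tibble(x, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample annotation table
#'
#' Annotations are a tibble with columns `sample_id`, `study_id`, `phenotype`
#' and `platform`. Phenotype and platform may be missing (`NA`); on disk a
#' missing value is an empty string.
#'
#' @param path TSV path.
#' @return A tibble with one row per sample.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  needed <- c("sample_id", "study_id")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("annotation file lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!("phenotype" %in% names(df))) df$phenotype <- NA_character_
  if (!("platform" %in% names(df))) df$platform <- NA_character_
  df <- dplyr::mutate(df, dplyr::across(c("phenotype", "platform"),
                                        ~ dplyr::na_if(.x, "")))
  check_annotations(df)
  dplyr::select(df, "sample_id", "study_id", "phenotype", "platform")
}

#' @rdname read_annotations
#' @param ann Annotation tibble.
#' @export
write_annotations <- function(ann, path) {
  check_annotations(ann)
  out <- dplyr::mutate(ann, dplyr::across(c("phenotype", "platform"),
                                          ~ dplyr::coalesce(.x, "")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

check_annotations <- function(ann) {
  if (!is.data.frame(ann)) abort("annotations must be a data frame")
  if (anyDuplicated(ann$sample_id)) {
    abort(sprintf("duplicate sample_id in annotations: %s",
                  ann$sample_id[duplicated(ann$sample_id)][1L]))
  }
  if (any(is.na(ann$study_id) | ann$study_id == "")) {
    abort("every sample needs a non-empty study_id")
  }
  invisible(ann)
}

# align an annotation tibble to the column order of an expression matrix
align_annotations <- function(x, ann) {
  check_annotations(ann)
  missing <- setdiff(colnames(x), ann$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("samples missing from annotations: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  ann[match(colnames(x), ann$sample_id), , drop = FALSE]
}
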