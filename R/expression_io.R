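#' Expression matrices and sample annotations
#'
#' An expression matrix in this package is a base numeric matrix of log2
#' expression values with genes in rows (unique rownames) and samples in
#' columns (unique colnames); all values must be finite. A sample annotation
#' is a data frame with columns `sample`, `cell_type`, `treatment`, `batch`
#' and `is_control` (logical). `validate_expression_matrix()` and
#' `validate_sample_annotation()` enforce these contracts and are called by
#' every function that consumes the objects.
#'
#' @param x object to validate.
#' @return The validated object, invisibly.
#' @name expression-data
NULL

#' @rdname expression-data
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    lmi_data_error("expression matrix must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L)
    lmi_data_error("expression matrix is empty", "lmi_empty_input")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    lmi_data_error("expression matrix must have gene rownames and sample colnames")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    lmi_data_error(
      sprintf("duplicate gene identifier(s): %s",
              paste(utils::head(dup_g, 5), collapse = ", ")),
      "lmi_identifier_collision")
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    lmi_data_error(
      sprintf("duplicate sample identifier(s): %s",
              paste(utils::head(dup_s, 5), collapse = ", ")),
      "lmi_identifier_collision")
  if (!all(is.finite(x)))
    lmi_data_error("expression matrix contains non-finite values")
  invisible(x)
}

#' @rdname expression-data
#' @export
validate_sample_annotation <- function(x) {
  needed <- c("sample", "cell_type", "treatment", "batch", "is_control")
  if (!is.data.frame(x) || !all(needed %in% names(x)))
    lmi_data_error(sprintf("annotation must be a data frame with columns %s",
                           paste(needed, collapse = ", ")))
  if (anyDuplicated(x$sample))
    lmi_data_error("duplicate sample identifier(s) in annotation",
                   "lmi_identifier_collision")
  if (!is.logical(x$is_control) || anyNA(x$is_control))
    lmi_data_error("is_control must be TRUE/FALSE for every sample")
  invisible(x)
}

dialect_sep <- function(dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' The file must carry sample identifiers in a header row and gene
#' identifiers in the first column; the body holds log2 expression values.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  sep <- dialect_sep(dialect)
  if (!file.exists(path))
    lmi_data_error(sprintf("file not found: %s", path), "lmi_file_not_found")
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    lmi_data_error(sprintf("empty expression matrix in %s", path),
                   "lmi_empty_input")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    lmi_data_error(
      sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
              body[bad[1], bad[2]], genes[bad[1]], samples[bad[2]]),
      "lmi_parse_error")
  }
  dimnames(vals) <- list(genes, samples)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to delimited text
#'
#' Produces a file that [read_expression_matrix()] reads back with identical
#' identifiers and values equal to within 1e-6 (15 significant digits are
#' written, so round trips are lossless in practice).
#'
#' @param matrix validated expression matrix.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param id_column header for the gene-identifier column.
#' @export
write_expression_matrix <- function(matrix, path, dialect = c("tsv", "csv"),
                                    id_column = "gene") {
  validate_expression_matrix(matrix)
  sep <- dialect_sep(dialect)
  df <- data.frame(gene = rownames(matrix),
                   format(matrix, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    lmi_data_error(sprintf("cannot write to %s", path), "lmi_io_error")
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' @param path path to a TSV/CSV with columns sample, cell_type, treatment,
#'   batch, is_control. `is_control` accepts TRUE/FALSE, 1/0, yes/no.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated annotation data frame.
#' @export
read_sample_annotation <- function(path, dialect = c("tsv", "csv")) {
  sep <- dialect_sep(dialect)
  if (!file.exists(path))
    lmi_data_error(sprintf("file not found: %s", path), "lmi_file_not_found")
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  for (col in c("cell_type", "treatment", "batch"))
    if (is.null(df[[col]])) df[[col]] <- ""
  flag <- tolower(trimws(df$is_control))
  is_control <- rep(NA, nrow(df))
  is_control[flag %in% c("true", "t", "1", "yes")] <- TRUE
  is_control[flag %in% c("false", "f", "0", "no", "")] <- FALSE
  ann <- data.frame(sample = df$sample, cell_type = df$cell_type,
                    treatment = df$treatment, batch = df$batch,
                    is_control = is_control, stringsAsFactors = FALSE)
  validate_sample_annotation(ann)
  ann
}

#' @rdname read_sample_annotation
#' @param annotation validated annotation data frame.
#' @export
write_sample_annotation <- function(annotation, path, dialect = c("tsv", "csv")) {
  validate_sample_annotation(annotation)
  utils::write.table(annotation, path, sep = dialect_sep(dialect),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce expression matrices to a shared gene space
#'
#' All matrices are re-expressed on the intersection of their (optionally
#' mapped) gene sets, ordered as in the first matrix. A many-to-one mapping
#' table collapses source identifiers onto canonical identifiers by the
#' arithmetic mean of their log2 values, the same convention used for
#' replicate averaging.
#'
#' @param matrices list of expression matrices.
#' @param mapping optional data frame with columns `source_id`,
#'   `canonical_id`; must be many-to-one.
#' @return List of matrices sharing one ordered gene list; sample columns
#'   unchanged.
#' @export
harmonize_gene_space <- function(matrices, mapping = NULL) {
  if (!is.list(matrices) || length(matrices) == 0L)
    lmi_data_error("harmonize_gene_space needs at least one matrix",
                   "lmi_empty_input")
  lapply(matrices, validate_expression_matrix)
  if (!is.null(mapping)) {
    if (!all(c("source_id", "canonical_id") %in% names(mapping)))
      lmi_data_error("mapping needs columns source_id, canonical_id",
                     "lmi_mapping_error")
    conflict <- tapply(mapping$canonical_id, mapping$source_id,
                       function(v) length(unique(v)) > 1L)
    if (any(conflict))
      lmi_data_error(
        sprintf("source id(s) mapped to multiple canonical ids: %s",
                paste(utils::head(names(conflict)[conflict], 5), collapse = ", ")),
        "lmi_mapping_error")
    map <- stats::setNames(mapping$canonical_id, mapping$source_id)
    matrices <- lapply(matrices, function(m) {
      ids <- rownames(m)
      hit <- ids %in% names(map)
      ids[hit] <- unname(map[ids[hit]])
      # collapse rows that now share a canonical id by their mean
      collapsed <- rowsum(m, group = ids, reorder = FALSE)
      counts <- as.vector(table(factor(ids, levels = rownames(collapsed))))
      collapsed / counts
    })
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L)
    lmi_data_error("no genes shared by all matrices", "lmi_no_common_genes")
  common <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% common]
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Collapse replicate samples into per-group profiles
#'
#' Each output column is the per-gene arithmetic mean of the group's sample
#' columns, the convention used to form cell-type endpoint profiles (e.g.
#' averaging HSC replicates before building a lineage vector).
#'
#' @param matrix expression matrix.
#' @param groups named list mapping group labels to sample identifiers.
#' @return Expression matrix with one column per group, gene order preserved.
#' @export
average_replicates <- function(matrix, groups) {
  validate_expression_matrix(matrix)
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)))
    lmi_data_error("groups must be a non-empty named list", "lmi_empty_group")
  out <- vapply(names(groups), function(label) {
    ids <- groups[[label]]
    if (length(ids) == 0L)
      lmi_data_error(sprintf("group '%s' is empty", label), "lmi_empty_group")
    missing <- setdiff(ids, colnames(matrix))
    if (length(missing))
      lmi_data_error(
        sprintf("group '%s' references unknown sample(s): %s",
                label, paste(missing, collapse = ", ")),
        "lmi_unknown_sample")
    rowMeans(matrix[, ids, drop = FALSE])
  }, numeric(nrow(matrix)))
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix), names(groups)))
  out
}
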