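#' Lineage Maturation Index of a single profile
#'
#' The LMI of a profile `c` is the scalar projection of `c - a` onto the
#' lineage direction `b - a`:
#' \deqn{LMI(c) = \sum_i (b_i - a_i)(c_i - a_i) / \sqrt{\sum_i (b_i - a_i)^2}}
#' evaluated over the lineage vector's gene list. The score is in log2
#' expression units: 0 at the immature endpoint, `vector$norm` at the mature
#' endpoint, and linear in between; larger means more differentiated.
#'
#' By default every lineage gene must be present in the profile. With
#' `min_coverage < 1`, missing genes are dropped and the projection (norm
#' included) is recomputed on the covered subspace, which keeps the score a
#' true scalar projection rather than an imputed one.
#'
#' @param vector a `LineageVector`.
#' @param sample named numeric vector of log2 expression covering the
#'   lineage genes (extra genes are ignored).
#' @param min_coverage minimum fraction of lineage genes the sample must
#'   cover, in (0, 1]; default 1.
#' @return A single finite numeric LMI value.
#' @examples
#' v <- build_lineage_vector(c(g1 = 0, g2 = 0), c(g1 = 3, g2 = 4))
#' compute_lmi(v, c(g1 = 3, g2 = 0))  # 1.8
#' @export
compute_lmi <- function(vector, sample, min_coverage = 1.0) {
  stopifnot(inherits(vector, "LineageVector"))
  if (!is.numeric(sample) || is.null(names(sample)))
    lmi_data_error("sample must be a named numeric vector")
  if (!is.numeric(min_coverage) || length(min_coverage) != 1L ||
      min_coverage <= 0 || min_coverage > 1)
    lmi_config_error("min_coverage must be in (0, 1]")
  covered <- vector$genes[vector$genes %in% names(sample)]
  missing <- setdiff(vector$genes, covered)
  if (length(covered) / length(vector$genes) < min_coverage)
    lmi_data_error(
      sprintf("sample covers %d/%d lineage genes (< %.3g); missing: %s",
              length(covered), length(vector$genes), min_coverage,
              paste(utils::head(missing, 10), collapse = ", ")),
      "lmi_coverage_error")
  a <- vector$a[covered]
  d <- vector$b[covered] - a
  nrm <- if (length(missing)) sqrt(sum(d^2)) else vector$norm
  if (nrm == 0)
    lmi_data_error("lineage direction vanishes on the covered gene set",
                   "lmi_empty_signature")
  sum(d * (sample[covered] - a)) / nrm
}

#' LMI of every sample in an expression matrix
#'
#' @inheritParams compute_lmi
#' @param matrix expression matrix whose rows cover the lineage genes (up to
#'   the coverage tolerance).
#' @return A data frame (an LMI table) with columns `sample` and `lmi`, one
#'   row per matrix column, in column order.
#' @export
compute_lmi_table <- function(vector, matrix, min_coverage = 1.0) {
  stopifnot(inherits(vector, "LineageVector"))
  validate_expression_matrix(matrix)
  covered <- vector$genes[vector$genes %in% rownames(matrix)]
  missing <- setdiff(vector$genes, covered)
  if (length(covered) / length(vector$genes) < min_coverage)
    lmi_data_error(
      sprintf("matrix covers %d/%d lineage genes (< %.3g); missing: %s",
              length(covered), length(vector$genes), min_coverage,
              paste(utils::head(missing, 10), collapse = ", ")),
      "lmi_coverage_error")
  a <- vector$a[covered]
  d <- vector$b[covered] - a
  nrm <- if (length(missing)) sqrt(sum(d^2)) else vector$norm
  if (nrm == 0)
    lmi_data_error("lineage direction vanishes on the covered gene set",
                   "lmi_empty_signature")
  lmi <- as.vector(crossprod(matrix[covered, , drop = FALSE] - a, d)) / nrm
  data.frame(sample = colnames(matrix), lmi = lmi, stringsAsFactors = FALSE)
}

#' Relative maturity
#'
#' Convenience rescaling of LMIs to units of the lineage norm (0 = immature
#' endpoint, 1 = mature endpoint). Never used in screening decisions.
#'
#' @inheritParams compute_lmi
#' @param lmi numeric vector of LMI values from `vector`.
#' @return `lmi / vector$norm`.
#' @export
relative_maturity <- function(vector, lmi) {
  stopifnot(inherits(vector, "LineageVector"))
  lmi / vector$norm
}

#' Read / write an LMI table
#'
#' TSV with columns `sample`, `lmi` and optionally `delta_lmi`, `batch`.
#'
#' @param lmis LMI table data frame.
#' @param path file path.
#' @export
write_lmi_table <- function(lmis, path) {
  stopifnot(is.data.frame(lmis), all(c("sample", "lmi") %in% names(lmis)))
  utils::write.table(lmis, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lmi_table
#' @export
read_lmi_table <- function(path) {
  if (!file.exists(path))
    lmi_data_error(sprintf("file not found: %s", path), "lmi_file_not_found")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "lmi") %in% names(df)))
    lmi_data_error(sprintf("%s lacks sample/lmi columns", path),
                   "lmi_parse_error")
  df
}
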