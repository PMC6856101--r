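#' Select lineage-informative genes by endpoint fold change
#'
#' Keeps the genes whose log2 expression differs between the immature and
#' mature endpoint profiles by at least `min_log2_diff` in absolute value.
#' The default of 2.0 log2 units corresponds to a 4-fold expression change;
#' the comparison is inclusive at the threshold. Both up- and down-regulated
#' genes are kept: the projection uses signed differences, so genes silenced
#' during maturation carry as much signal as genes induced.
#'
#' @param immature,mature named numeric vectors of log2 expression on the
#'   same gene set (endpoint profiles, typically replicate-averaged).
#' @param min_log2_diff positive filter threshold in log2 units.
#' @return Character vector of selected gene identifiers, in input order.
#' @export
select_lineage_genes <- function(immature, mature, min_log2_diff = 2.0) {
  check_profiles(immature, mature)
  if (!is.numeric(min_log2_diff) || length(min_log2_diff) != 1L ||
      min_log2_diff <= 0)
    lmi_config_error("min_log2_diff must be a single positive number")
  mature <- mature[names(immature)]
  keep <- abs(mature - immature) >= min_log2_diff
  genes <- names(immature)[keep]
  if (length(genes) == 0L)
    lmi_data_error(
      sprintf("no gene reaches a %.3g log2 endpoint difference", min_log2_diff),
      "lmi_empty_signature")
  genes
}

check_profiles <- function(immature, mature) {
  if (!is.numeric(immature) || !is.numeric(mature) ||
      is.null(names(immature)) || is.null(names(mature)))
    lmi_data_error("endpoint profiles must be named numeric vectors")
  if (length(immature) != length(mature) ||
      !setequal(names(immature), names(mature)))
    lmi_data_error("endpoint profiles are defined on different gene sets",
                   "lmi_gene_set_mismatch")
  invisible(NULL)
}

#' Build a reference lineage vector
#'
#' A lineage vector is the geometric object the maturation score projects
#' onto: the filtered immature endpoint `a`, mature endpoint `b`, and the
#' Euclidean norm of `b - a`. Endpoints are restricted to the genes passing
#' [select_lineage_genes()].
#'
#' @inheritParams select_lineage_genes
#' @return An object of class `LineageVector`: a list with `genes`, `a`, `b`,
#'   `norm` and `threshold`.
#' @examples
#' imm <- c(g1 = 0, g2 = 0, g3 = 0)
#' mat <- c(g1 = 2, g2 = 0, g3 = 3)
#' v <- build_lineage_vector(imm, mat)
#' v$norm  # sqrt(13)
#' @export
build_lineage_vector <- function(immature, mature, min_log2_diff = 2.0) {
  genes <- select_lineage_genes(immature, mature, min_log2_diff)
  a <- immature[genes]
  b <- mature[names(a)]
  nrm <- sqrt(sum((b - a)^2))
  structure(list(genes = genes, a = a, b = b, norm = nrm,
                 threshold = min_log2_diff),
            class = "LineageVector")
}

#' @export
print.LineageVector <- function(x, ...) {
  cat(sprintf("LineageVector: %d genes, |b - a| = %.4g (threshold %.3g log2)\n",
              length(x$genes), x$norm, x$threshold))
  invisible(x)
}

#' Serialize a lineage vector
#'
#' Written as TSV with commented header lines recording the filter threshold
#' and the norm, then columns gene, a, b — enough to reproduce the gene
#' universe of a run exactly.
#'
#' @param vector a `LineageVector`.
#' @param path output path.
#' @export
write_lineage_vector <- function(vector, path) {
  stopifnot(inherits(vector, "LineageVector"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# threshold=%.17g", vector$threshold),
               sprintf("# norm=%.17g", vector$norm),
               "gene\ta\tb"), con)
  utils::write.table(
    data.frame(gene = vector$genes,
               a = sprintf("%.17g", vector$a),
               b = sprintf("%.17g", vector$b)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage_vector
#' @return `read_lineage_vector()` returns the reconstructed `LineageVector`.
#' @export
read_lineage_vector <- function(path) {
  if (!file.exists(path))
    lmi_data_error(sprintf("file not found: %s", path), "lmi_file_not_found")
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  thr <- sub("^# threshold=", "", grep("^# threshold=", hdr, value = TRUE))
  if (length(thr) != 1L)
    lmi_data_error(sprintf("%s lacks a '# threshold=' header", path),
                   "lmi_parse_error")
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "a", "b") %in% names(body)))
    lmi_data_error(sprintf("%s lacks gene/a/b columns", path),
                   "lmi_parse_error")
  build_lineage_vector(stats::setNames(body$a, body$gene),
                       stats::setNames(body$b, body$gene),
                       as.numeric(thr))
}
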