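#' Assemble a pipeline run configuration
#'
#' Settings may come from a YAML file, from direct arguments, or from the
#' defaults, with precedence direct arguments > config file > defaults.
#' Recognized keys: `matrix`, `annotation`, `vector`, `immature`, `mature`,
#' `threshold`, `min_coverage`, `variant`, `alpha`, `adjust`, `controls`,
#' `top_k`, `seed`, `out_dir`, `dialect`, `log_level`.
#'
#' @param config_file optional path to a YAML configuration file.
#' @param ... individual settings overriding the file.
#' @return A `RunConfig` list.
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(matrix = NULL, annotation = NULL, vector = NULL,
                   immature = NULL, mature = NULL,
                   threshold = 2.0, min_coverage = 1.0,
                   variant = "welch", alpha = 0.05, adjust = "none",
                   controls = "batch-matched", top_k = 20L, seed = 1L,
                   out_dir = ".", dialect = "tsv", log_level = "info")
  from_file <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      lmi_config_error(sprintf("config file not found: %s", config_file))
    from_file <- yaml::read_yaml(config_file)
  }
  override <- Filter(Negate(is.null), list(...))
  unknown <- setdiff(c(names(from_file), names(override)), names(defaults))
  if (length(unknown))
    lmi_config_error(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), override)
  structure(cfg, class = "RunConfig")
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_paths <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]]))
      lmi_config_error(sprintf("config is missing required path '%s'", k))
    if (!file.exists(cfg[[k]]))
      lmi_data_error(sprintf("input file not found: %s", cfg[[k]]),
                     "lmi_file_not_found")
  }
}

#' Build and serialize a reference lineage vector
#'
#' Reads the expression matrix and annotation named in `config`, averages
#' replicates of the immature and mature cell types (given by the
#' `immature` / `mature` config keys; each must match exactly one cell-type
#' group), applies the fold-change filter at `threshold`, and writes the
#' vector to `out_dir/lineage_vector.tsv`. Gene counts before/after
#' filtering and the norm are logged.
#'
#' @param config a [run_config()].
#' @return Path to the written vector file, invisibly.
#' @export
run_build_vector <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  require_paths(config, c("matrix", "annotation"))
  for (k in c("immature", "mature"))
    if (is.null(config[[k]]))
      lmi_config_error(sprintf("config must name the '%s' cell type", k))
  mat <- read_expression_matrix(config$matrix, config$dialect)
  ann <- read_sample_annotation(config$annotation, config$dialect)
  groups <- lapply(c(config$immature, config$mature), function(ct) {
    ids <- ann$sample[ann$cell_type == ct]
    ids <- intersect(ids, colnames(mat))
    if (length(ids) == 0L)
      lmi_config_error(sprintf("cell type '%s' matches no sample", ct))
    ids
  })
  names(groups) <- c("immature", "mature")
  prof <- average_replicates(mat, groups)
  log_msg(config, "info", "endpoints averaged over %d + %d replicates",
          length(groups$immature), length(groups$mature))
  vec <- build_lineage_vector(prof[, "immature"], prof[, "mature"],
                              config$threshold)
  log_msg(config, "info",
          "filter kept %d / %d genes at threshold %.3g; norm %.4g",
          length(vec$genes), nrow(mat), config$threshold, vec$norm)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$out_dir, "lineage_vector.tsv")
  write_lineage_vector(vec, out)
  invisible(out)
}

#' Score a matrix and run the full drug screen
#'
#' Composes the pipeline: read vector + matrix + annotation, score every
#' sample, compute batch-controlled delta-LMIs, test and rank treatments.
#' Writes `lmi_table.tsv` and `screen_result.tsv` into `out_dir` and logs a
#' top-k summary. Per-treatment test failures are downgraded to warnings.
#'
#' @param config a [run_config()] naming `vector`, `matrix`, `annotation`.
#' @return List with `lmis` and `result`, invisibly.
#' @export
run_full_screen <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  require_paths(config, c("vector", "matrix", "annotation"))
  vec <- read_lineage_vector(config$vector)
  mat <- read_expression_matrix(config$matrix, config$dialect)
  ann <- read_sample_annotation(config$annotation, config$dialect)
  lmis <- compute_lmi_table(vec, mat, config$min_coverage)
  lmis <- compute_delta_lmi(lmis, ann)
  res <- screen(lmis, ann, alpha = config$alpha, adjust = config$adjust,
                variant = config$variant, controls = config$controls)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_lmi_table(lmis, file.path(config$out_dir, "lmi_table.tsv"))
  write_screen_result(res, file.path(config$out_dir, "screen_result.tsv"))
  log_msg(config, "info", "%d treatments screened; %d significant at alpha %.3g",
          nrow(res), sum(res$significant, na.rm = TRUE), config$alpha)
  top <- top_k(res, config$top_k)
  log_msg(config, "info", "top %d by mean delta-LMI: %s", nrow(top),
          paste(sprintf("%s (%.3g)", top$treatment, top$mean_delta_lmi),
                collapse = ", "))
  invisible(list(lmis = lmis, result = res))
}

#' Simulate data sets from a config and write them to disk
#'
#' @param kind `"lineage"` or `"screen"`.
#' @param config a [run_config()]; for `"screen"` it must name a `vector`
#'   file. Generator settings beyond `seed` use the generator defaults.
#' @param sim_args named list passed on to [lineage_sim_config()] or
#'   [screen_sim_config()] (seed defaults to the run config's seed).
#' @return Paths of the written matrix/annotation/truth files, invisibly.
#' @export
run_simulate <- function(kind = c("lineage", "screen"), config,
                         sim_args = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "lineage") {
    sim <- simulate_lineage(do.call(lineage_sim_config, sim_args))
    truth <- data.frame(sample = names(sim$truth$maturity),
                        maturity = unname(sim$truth$maturity))
  } else {
    require_paths(config, "vector")
    vec <- read_lineage_vector(config$vector)
    sim <- simulate_screen(do.call(screen_sim_config, sim_args), vec)
    truth <- data.frame(positive_drug = sim$truth$positives)
  }
  paths <- file.path(config$out_dir,
                     c("matrix.tsv", "annotation.tsv", "truth.tsv"))
  write_expression_matrix(sim$matrix, paths[1], config$dialect)
  write_sample_annotation(sim$annotation, paths[2], config$dialect)
  utils::write.table(truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_msg(config, "info", "simulated %s data written to %s", kind,
          config$out_dir)
  invisible(paths)
}
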