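#' Configuration for a simulated differentiation lineage
#'
#' The generator emulates a staged hematopoietic lineage: an immature and a
#' mature endpoint separated by >= the fold-change filter threshold on
#' exactly `n_signature_genes`, with intermediate stages interpolating
#' linearly between them plus additive Gaussian noise in log2 units.
#'
#' @param n_genes total genes.
#' @param n_signature_genes genes given a true endpoint separation (log2
#'   magnitudes uniform in \[2, 4\], random signs); the remaining genes drift
#'   by less than 2 log2 units.
#' @param n_stages number of developmental stages (>= 2), stage s having
#'   true maturity s/(n_stages - 1).
#' @param noise_sd additive Gaussian noise, log2 units.
#' @param seed integer RNG seed; identical configs reproduce bit-identical
#'   data.
#' @return A `LineageSimConfig` list.
#' @export
lineage_sim_config <- function(n_genes = 1000, n_signature_genes = 200,
                               n_stages = 8, noise_sd = 0.2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              n_stages = as.integer(n_stages),
              noise_sd = noise_sd, seed = as.integer(seed))
  if (anyNA(cfg) || cfg$n_genes < 1L || cfg$n_signature_genes < 1L ||
      cfg$n_signature_genes > cfg$n_genes || cfg$n_stages < 2L ||
      cfg$noise_sd < 0)
    lmi_config_error("invalid lineage simulation config")
  structure(cfg, class = "LineageSimConfig")
}

#' Simulate a staged differentiation lineage
#'
#' @param config a [lineage_sim_config()].
#' @return List with `matrix` (genes x stages expression matrix),
#'   `annotation` (stages annotated by cell type, no batches or treatments)
#'   and `truth`: the generating endpoints `a_star`, `b_star`, the planted
#'   `signature_genes`, and per-sample true `maturity` in \[0, 1\].
#' @examples
#' sim <- simulate_lineage(lineage_sim_config(n_stages = 5, noise_sd = 0))
#' v <- build_lineage_vector(sim$truth$a_star, sim$truth$b_star)
#' compute_lmi_table(v, sim$matrix)$lmi / v$norm  # 0, .25, .5, .75, 1
#' @export
simulate_lineage <- function(config) {
  if (!inherits(config, "LineageSimConfig"))
    config <- do.call(lineage_sim_config, as.list(config))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  # baseline log2 intensities in the usual normalized-microarray range
  a_star <- stats::setNames(stats::runif(config$n_genes, 4, 10), genes)
  sig <- sort(sample.int(config$n_genes, config$n_signature_genes))
  shift <- stats::runif(config$n_genes, -1, 1)          # sub-threshold drift
  shift[sig] <- stats::runif(config$n_signature_genes, 2, 4) *
    sample(c(-1, 1), config$n_signature_genes, replace = TRUE)
  b_star <- a_star + shift
  t_s <- seq(0, 1, length.out = config$n_stages)
  samples <- sprintf("stage_%02d", seq_len(config$n_stages))
  mat <- vapply(t_s, function(t) a_star + t * (b_star - a_star),
                numeric(config$n_genes))
  if (config$noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), sd = config$noise_sd)
  dimnames(mat) <- list(genes, samples)
  ann <- data.frame(sample = samples,
                    cell_type = sprintf("stage_%02d", seq_len(config$n_stages)),
                    treatment = "", batch = "", is_control = FALSE,
                    stringsAsFactors = FALSE)
  list(matrix = mat, annotation = ann,
       truth = list(a_star = a_star, b_star = b_star,
                    signature_genes = genes[sig],
                    maturity = stats::setNames(t_s, samples)))
}

#' Configuration for a simulated batched drug screen
#'
#' Emulates a vehicle-controlled repurposing screen: every array sits at a
#' baseline maturity of 0.2 along the lineage (a differentiation block near
#' the immature end), a planted subset of drugs shifts their arrays toward
#' the mature endpoint by `effect_size` lineage norms, arrays are assigned
#' round-robin to batches, and each batch carries its own DMSO controls.
#'
#' @param n_drugs number of distinct treatments.
#' @param n_positives number of drugs given a true maturation shift.
#' @param effect_size true LMI shift in units of the lineage norm
#'   (0.3 = 30% of the immature-to-mature distance).
#' @param replicates_per_drug treated arrays per drug.
#' @param batches number of experimental batches.
#' @param controls_per_batch DMSO arrays per batch (>= 1).
#' @param noise_sd additive Gaussian noise, log2 units.
#' @param seed integer RNG seed.
#' @return A `ScreenSimConfig` list.
#' @export
screen_sim_config <- function(n_drugs = 50, n_positives = 5,
                              effect_size = 0.3, replicates_per_drug = 3,
                              batches = 10, controls_per_batch = 2,
                              noise_sd = 0.1, seed = 1) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_positives = as.integer(n_positives),
              effect_size = effect_size,
              replicates_per_drug = as.integer(replicates_per_drug),
              batches = as.integer(batches),
              controls_per_batch = as.integer(controls_per_batch),
              noise_sd = noise_sd, seed = as.integer(seed))
  if (anyNA(cfg) || cfg$n_drugs < 1L || cfg$n_positives < 0L ||
      cfg$n_positives > cfg$n_drugs || cfg$replicates_per_drug < 1L ||
      cfg$batches < 1L || cfg$controls_per_batch < 1L || cfg$noise_sd < 0)
    lmi_config_error("invalid screen simulation config")
  structure(cfg, class = "ScreenSimConfig")
}

#' Simulate a batched, vehicle-controlled drug screen
#'
#' Profiles are generated on the lineage vector's gene set: every array is
#' `a + t0 (b - a) + noise` with baseline maturity `t0 = 0.2`; arrays of
#' planted positive drugs get an extra `effect_size * (b - a)`.
#'
#' @param config a [screen_sim_config()].
#' @param vector the `LineageVector` defining the geometry (norm > 0).
#' @return List with `matrix`, `annotation` (treatments, batches, is_control)
#'   and `truth` (`positives`: planted drug names; `baseline_maturity`;
#'   `effect_size`).
#' @export
simulate_screen <- function(config, vector) {
  if (!inherits(config, "ScreenSimConfig"))
    config <- do.call(screen_sim_config, as.list(config))
  stopifnot(inherits(vector, "LineageVector"))
  if (vector$norm <= 0)
    lmi_config_error("lineage vector must have positive norm")
  set.seed(config$seed)
  t0 <- 0.2
  drugs <- sprintf("drug_%03d", seq_len(config$n_drugs))
  positives <- sort(sample(drugs, config$n_positives))
  n_treat <- config$n_drugs * config$replicates_per_drug
  treat_drug <- rep(drugs, each = config$replicates_per_drug)
  treat_batch <- sprintf("batch_%02d",
                         rep_len(seq_len(config$batches), n_treat))
  n_ctrl <- config$batches * config$controls_per_batch
  ctrl_batch <- sprintf("batch_%02d",
                        rep(seq_len(config$batches),
                            each = config$controls_per_batch))
  samples <- c(sprintf("%s_rep%d", treat_drug,
                       rep(seq_len(config$replicates_per_drug),
                           times = config$n_drugs)),
               sprintf("DMSO_%s_c%d", ctrl_batch,
                       rep(seq_len(config$controls_per_batch),
                           times = config$batches)))
  maturity <- c(t0 + config$effect_size * (treat_drug %in% positives),
                rep(t0, n_ctrl))
  d <- vector$b - vector$a
  mat <- vapply(maturity, function(t) vector$a + t * d,
                numeric(length(vector$genes)))
  if (config$noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), sd = config$noise_sd)
  dimnames(mat) <- list(vector$genes, samples)
  ann <- data.frame(sample = samples,
                    cell_type = "",
                    treatment = c(treat_drug, rep("DMSO", n_ctrl)),
                    batch = c(treat_batch, ctrl_batch),
                    is_control = c(rep(FALSE, n_treat), rep(TRUE, n_ctrl)),
                    stringsAsFactors = FALSE)
  list(matrix = mat, annotation = ann,
       truth = list(positives = positives, baseline_maturity = t0,
                    effect_size = config$effect_size))
}
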