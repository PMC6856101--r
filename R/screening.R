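#' Batch-controlled change in LMI
#'
#' For every scored sample, `delta_lmi` is its LMI minus the mean LMI of the
#' vehicle-control samples in its experimental batch — the screen's unit of
#' effect. Controls are scored against their own batch too, so a batch with a
#' single control gives that control a delta of exactly zero.
#'
#' @param lmis LMI table (`sample`, `lmi`) from [compute_lmi_table()].
#' @param annotation sample annotation with `batch` and `is_control` set for
#'   every scored sample.
#' @return The LMI table with `delta_lmi` and `batch` columns added.
#' @export
compute_delta_lmi <- function(lmis, annotation) {
  stopifnot(is.data.frame(lmis), all(c("sample", "lmi") %in% names(lmis)))
  validate_sample_annotation(annotation)
  unknown <- setdiff(lmis$sample, annotation$sample)
  if (length(unknown))
    lmi_data_error(sprintf("sample(s) not in annotation: %s",
                           paste(utils::head(unknown, 5), collapse = ", ")),
                   "lmi_unknown_sample")
  ann <- annotation[match(lmis$sample, annotation$sample), ]
  ctrl <- ann$is_control
  batches <- unique(ann$batch)
  no_ctrl <- batches[!batches %in% unique(ann$batch[ctrl])]
  if (length(no_ctrl))
    lmi_data_error(sprintf("batch(es) without a control sample: %s",
                           paste(utils::head(no_ctrl, 5), collapse = ", ")),
                   "lmi_missing_control")
  ctrl_mean <- tapply(lmis$lmi[ctrl], ann$batch[ctrl], mean)
  out <- lmis
  out$delta_lmi <- lmis$lmi - as.vector(ctrl_mean[ann$batch])
  out$batch <- ann$batch
  out
}

#' Two-sample t-test of a treatment against vehicle controls
#'
#' Two-sided comparison of treated vs control LMIs. `"welch"` (default) uses
#' the unequal-variance Welch t-test; `"pooled"` the classical equal-variance
#' Student t-test. Identical constant groups return `t = 0, p = 1`; constant
#' groups with different means admit no finite statistic and raise a
#' degenerate-test error.
#'
#' @param treated_lmis,control_lmis numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return List with `t_statistic` and `p_value`.
#' @export
test_treatment <- function(treated_lmis, control_lmis,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(treated_lmis) < 2L || length(control_lmis) < 2L)
    lmi_data_error("each group needs at least 2 values",
                   "lmi_insufficient_replicates")
  v1 <- stats::var(treated_lmis)
  v2 <- stats::var(control_lmis)
  if (v1 == 0 && v2 == 0) {
    if (mean(treated_lmis) == mean(control_lmis))
      return(list(t_statistic = 0, p_value = 1))
    lmi_data_error("both groups have zero variance but different means",
                   "lmi_degenerate_test")
  }
  fit <- stats::t.test(treated_lmis, control_lmis,
                       var.equal = (variant == "pooled"),
                       alternative = "two.sided")
  list(t_statistic = unname(fit$statistic), p_value = unname(fit$p.value))
}

#' Rank treatments by their batch-controlled LMI shift
#'
#' One row per distinct treatment: the mean `delta_lmi` over its treated
#' samples, a t-test of its per-sample LMIs against control LMIs, and a rank
#' by descending mean shift (ties broken lexicographically by treatment
#' name). By default a treatment is tested against the pooled controls of
#' the batches containing its samples, mirroring the delta-LMI definition;
#' `controls = "pooled-all"` tests against every control. Treatments whose
#' group sizes do not permit the test (< 2 on either side) keep their shift
#' and rank with `NA` statistics.
#'
#' @param lmis LMI table with `delta_lmi` populated
#'   (see [compute_delta_lmi()]).
#' @param annotation sample annotation table.
#' @param alpha significance level applied to the (adjusted) p-value.
#' @param adjust `"none"` (default, raw p at `alpha`) or `"bh"`
#'   (Benjamini-Hochberg).
#' @param variant t-test variant, see [test_treatment()].
#' @param controls `"batch-matched"` (default) or `"pooled-all"`.
#' @return A `ScreenResult` data frame with columns treatment, n_treated,
#'   n_control, mean_delta_lmi, t_statistic, p_value, adjusted_p,
#'   significant, rank; rows ordered by rank.
#' @export
screen <- function(lmis, annotation, alpha = 0.05,
                   adjust = c("none", "bh"), variant = c("welch", "pooled"),
                   controls = c("batch-matched", "pooled-all")) {
  adjust <- match.arg(adjust)
  variant <- match.arg(variant)
  controls <- match.arg(controls)
  stopifnot(is.data.frame(lmis),
            all(c("sample", "lmi", "delta_lmi") %in% names(lmis)))
  validate_sample_annotation(annotation)
  ann <- annotation[match(lmis$sample, annotation$sample), ]
  treated <- !ann$is_control & !is.na(ann$treatment) & ann$treatment != ""
  if (!any(treated))
    lmi_data_error("no treatment groups to screen", "lmi_empty_input")
  treatments <- sort(unique(ann$treatment[treated]))
  ctrl_idx <- which(ann$is_control)

  rows <- lapply(treatments, function(tr) {
    idx <- which(treated & ann$treatment == tr)
    cidx <- if (controls == "batch-matched")
      ctrl_idx[ann$batch[ctrl_idx] %in% ann$batch[idx]]
    else ctrl_idx
    tt <- if (length(idx) >= 2L && length(cidx) >= 2L) {
      tryCatch(test_treatment(lmis$lmi[idx], lmis$lmi[cidx], variant),
               lmi_error = function(e) {
                 warning(sprintf("treatment '%s': %s", tr, conditionMessage(e)),
                         call. = FALSE)
                 list(t_statistic = NA_real_, p_value = NA_real_)
               })
    } else list(t_statistic = NA_real_, p_value = NA_real_)
    data.frame(treatment = tr, n_treated = length(idx),
               n_control = length(cidx),
               mean_delta_lmi = mean(lmis$delta_lmi[idx]),
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- if (adjust == "bh")
    stats::p.adjust(res$p_value, method = "BH") else NA_real_
  p_eff <- if (adjust == "bh") res$adjusted_p else res$p_value
  res$significant <- !is.na(p_eff) & p_eff < alpha
  # descending mean shift; res is already in lexicographic treatment order,
  # so a stable sort realizes the tie rule
  ord <- order(-res$mean_delta_lmi)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("ScreenResult", "data.frame")
  res
}

#' Leading rows of a screen result
#'
#' @param result a `ScreenResult`.
#' @param k number of top-ranked treatments to keep (clamped to the table).
#' @return The first `min(k, nrow)` rows by rank.
#' @export
top_k <- function(result, k) {
  stopifnot(is.data.frame(result), "rank" %in% names(result))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    lmi_config_error("k must be a positive count")
  result[result$rank <= k, , drop = FALSE]
}

#' Read / write a screen result table
#'
#' @param result `ScreenResult` data frame.
#' @param path file path.
#' @export
write_screen_result <- function(result, path) {
  stopifnot(is.data.frame(result))
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_result
#' @export
read_screen_result <- function(path) {
  if (!file.exists(path))
    lmi_data_error(sprintf("file not found: %s", path), "lmi_file_not_found")
  res <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(res) <- c("ScreenResult", "data.frame")
  res
}
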