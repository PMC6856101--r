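make_ann <- function(sample, treatment, batch, is_control) {
  data.frame(sample = sample, cell_type = "", treatment = treatment,
             batch = batch, is_control = is_control, stringsAsFactors = FALSE)
}

test_that("delta-LMI subtracts the mean control LMI of the sample's batch", {
  ann <- make_ann(c("t1", "c1", "c2"), c("drug", "DMSO", "DMSO"),
                  rep("b1", 3), c(FALSE, TRUE, TRUE))
  lmis <- data.frame(sample = c("t1", "c1", "c2"), lmi = c(5, 1, 3))
  out <- compute_delta_lmi(lmis, ann)
  expect_equal(out$delta_lmi, c(3, -1, 1))
  expect_equal(out$batch, rep("b1", 3))

  # a lone control in its batch has delta 0 by self-reference
  ann1 <- make_ann("c1", "DMSO", "b1", TRUE)
  out1 <- compute_delta_lmi(data.frame(sample = "c1", lmi = 7.5), ann1)
  expect_equal(out1$delta_lmi, 0)

  expect_error(
    compute_delta_lmi(lmis, make_ann(c("t1", "c1", "c2"), "d",
                                     c("b1", "b2", "b2"),
                                     c(FALSE, TRUE, TRUE))),
    class = "lmi_missing_control")
  expect_error(compute_delta_lmi(data.frame(sample = "zz", lmi = 1), ann),
               class = "lmi_unknown_sample")
})

test_that("delta-LMI matches a per-batch oracle and is translation invariant", {
  set.seed(31)
  n_batches <- 10
  rows <- do.call(rbind, lapply(seq_len(n_batches), function(b) {
    k_t <- sample(1:4, 1); k_c <- sample(1:3, 1)
    make_ann(sprintf("b%d_s%d", b, seq_len(k_t + k_c)),
             c(rep("drug", k_t), rep("DMSO", k_c)),
             sprintf("batch%d", b),
             c(rep(FALSE, k_t), rep(TRUE, k_c)))
  }))
  lmis <- data.frame(sample = rows$sample, lmi = rnorm(nrow(rows), sd = 3))
  out <- compute_delta_lmi(lmis, rows)
  # explicit per-batch loop oracle
  for (i in seq_len(nrow(out))) {
    b <- rows$batch[i]
    ctrl <- lmis$lmi[rows$batch == b & rows$is_control]
    expect_equal(out$delta_lmi[i], lmis$lmi[i] - mean(ctrl))
  }
  # shifting every LMI in one batch by a constant leaves its deltas unchanged
  shifted <- lmis
  shifted$lmi[rows$batch == "batch3"] <- shifted$lmi[rows$batch == "batch3"] + 17
  out2 <- compute_delta_lmi(shifted, rows)
  expect_equal(out2$delta_lmi, out$delta_lmi)
})

test_that("treatment test reproduces the Welch formula and its edge cases", {
  set.seed(32)
  x <- rnorm(5, 1); y <- rnorm(5, 0)
  got <- test_treatment(x, y, "welch")
  want <- oracle_welch(x, y)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-9)
  expect_equal(got$p_value, want$p, tolerance = 1e-9)

  # pooled variant agrees with the classical Student test
  pooled <- test_treatment(x, y, "pooled")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t_statistic, unname(ref$statistic))
  expect_equal(pooled$p_value, ref$p.value)

  # identical groups: no evidence at all
  same <- test_treatment(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # p shrinks monotonically as within-group jitter vanishes
  ps <- vapply(c(1e-2, 1e-6, 1e-12), function(eps)
    test_treatment(c(2, 2, 2 + eps), c(0, 0, eps))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3], 1e-10)

  expect_error(test_treatment(1, c(1, 2)),
               class = "lmi_insufficient_replicates")
  expect_error(test_treatment(c(2, 2), c(0, 0)),
               class = "lmi_degenerate_test")
})

test_that("screen ranks by descending mean shift with lexicographic ties", {
  ann <- make_ann(
    c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    c("drugB", "drugB", "drugC", "drugC", "drugA", "drugA", "DMSO", "DMSO"),
    "b1", c(rep(FALSE, 6), TRUE, TRUE))
  lmis <- data.frame(sample = ann$sample,
                     lmi = c(2, 2, -1, -1, 2, 2, 0.1, -0.1))
  res <- screen(compute_delta_lmi(lmis, ann), ann)
  expect_s3_class(res, "ScreenResult")
  expect_identical(res$treatment, c("drugA", "drugB", "drugC"))
  expect_identical(res$rank, 1:3)
  expect_equal(res$mean_delta_lmi, c(2, 2, -1))
  expect_identical(sort(res$rank), seq_len(nrow(res)))

  # controls only -> no treatment groups
  ann0 <- make_ann(c("d1", "d2"), "DMSO", "b1", TRUE)
  lmis0 <- compute_delta_lmi(data.frame(sample = c("d1", "d2"), lmi = 0:1), ann0)
  expect_error(screen(lmis0, ann0), class = "lmi_empty_input")
})

test_that("singleton treatments keep their rank but get no p-value", {
  ann <- make_ann(c("t1", "u1", "u2", "d1", "d2"),
                  c("solo", "duo", "duo", "DMSO", "DMSO"),
                  "b1", c(FALSE, FALSE, FALSE, TRUE, TRUE))
  lmis <- data.frame(sample = ann$sample, lmi = c(9, 1, 1.5, 0, 0.5))
  res <- screen(compute_delta_lmi(lmis, ann), ann)
  solo <- res[res$treatment == "solo", ]
  expect_equal(solo$rank, 1L)
  expect_true(is.na(solo$p_value))
  expect_false(solo$significant)
  expect_false(is.na(res$p_value[res$treatment == "duo"]))
})

test_that("BH adjustment is conservative and flags a subset", {
  set.seed(33)
  sim <- simulate_screen(screen_sim_config(n_drugs = 20, n_positives = 3,
                                           seed = 33), toy_vector())
  lmis <- compute_delta_lmi(compute_lmi_table(toy_vector(), sim$matrix),
                            sim$annotation)
  raw <- screen(lmis, sim$annotation, adjust = "none")
  bh <- screen(lmis, sim$annotation, adjust = "bh")
  m <- match(raw$treatment, bh$treatment)
  ok <- !is.na(bh$adjusted_p[m])
  expect_true(all(bh$adjusted_p[m][ok] >= raw$p_value[ok]))
  expect_true(all(bh$treatment[bh$significant] %in% raw$treatment[raw$significant]))
})

test_that("batch-matched vs pooled-all control groups differ as configured", {
  ann <- make_ann(c("t1", "t2", "d1", "d2", "d3", "d4"),
                  c("drug", "drug", "DMSO", "DMSO", "DMSO", "DMSO"),
                  c("b1", "b1", "b1", "b1", "b2", "b2"),
                  c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  lmis <- compute_delta_lmi(
    data.frame(sample = ann$sample, lmi = c(4, 5, 0, 1, 10, 11)), ann)
  matched <- screen(lmis, ann, controls = "batch-matched")
  pooled <- screen(lmis, ann, controls = "pooled-all")
  expect_equal(matched$n_control, 2L)  # only batch b1 controls
  expect_equal(pooled$n_control, 4L)
  expect_gt(matched$t_statistic, pooled$t_statistic)
})

test_that("top_k clamps to the table and respects rank order", {
  ann <- make_ann(c("a1", "a2", "b1", "b2", "d1", "d2"),
                  c("x", "x", "y", "y", "DMSO", "DMSO"),
                  "b1", c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  lmis <- compute_delta_lmi(
    data.frame(sample = ann$sample, lmi = c(1, 2, 5, 6, 0, 0)), ann)
  res <- screen(lmis, ann)
  expect_identical(top_k(res, 1)$treatment, "y")
  expect_identical(nrow(top_k(res, 99)), 2L)
  expect_error(top_k(res, 0), class = "lmi_config_error")
})

test_that("screen results round-trip through TSV", {
  ann <- make_ann(c("a1", "a2", "d1", "d2"), c("x", "x", "DMSO", "DMSO"),
                  "b1", c(FALSE, FALSE, TRUE, TRUE))
  lmis <- compute_delta_lmi(
    data.frame(sample = ann$sample, lmi = c(3, 4, 0, 1)), ann)
  res <- screen(lmis, ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_result(res, path)
  back <- read_screen_result(path)
  expect_equal(back$treatment, res$treatment)
  expect_equal(back$mean_delta_lmi, res$mean_delta_lmi)
  expect_equal(back$p_value, res$p_value)
})
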