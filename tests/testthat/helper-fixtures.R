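# Fixture builders shared across test files.

random_expression_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(round(runif(n_genes * n_samples, 2, 14), 6),
         nrow = n_genes,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

# independent explicit-loop evaluation of the projection formula
oracle_lmi <- function(a, b, c) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + (b[i] - a[i]) * (c[i] - a[i])
    den <- den + (b[i] - a[i])^2
  }
  unname(num / sqrt(den))
}

# textbook Welch formula, independent of stats::t.test
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = unname(t), p = unname(2 * pt(-abs(t), df)))
}

toy_vector <- function() build_lineage_vector(c(g1 = 0, g2 = 0),
                                              c(g1 = 3, g2 = 4))
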