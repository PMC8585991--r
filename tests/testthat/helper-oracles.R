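# Independent oracles and small fixtures shared across test files.
# These deliberately do not reuse package internals for the quantities
# they check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j)*m/j
# on the sorted p-values, mapped back to input order, clipped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Area under the ROC curve from the rank-sum formula.
rank_auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A random standardized region x gene matrix with ids.
random_standardized_X <- function(R, G, seed) {
  withr_seed <- seed  # plain set.seed; tests own their RNG state
  set.seed(withr_seed)
  X <- matrix(rnorm(R * G), R, G,
              dimnames = list(sprintf("R%04d", seq_len(R)),
                              sprintf("G%05d", seq_len(G))))
  standardize_genes(X)
}

# A small well-formed thickness TSV on disk; returns the path.
write_tiny_thickness <- function(path,
                                 groups = c("MCI_S", "MCI_S", "MCI_AD"),
                                 values = matrix(c(2.1, 2.3, 2.0,
                                                   2.2, 2.4, 2.1),
                                                 nrow = 3)) {
  df <- data.frame(subject_id = sprintf("S%d", seq_along(groups)),
                   group = groups, values)
  names(df)[-(1:2)] <- sprintf("R%04d", seq_len(ncol(values)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
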