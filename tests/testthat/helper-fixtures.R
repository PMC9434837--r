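# Shared fixtures and small oracles, all built in code at test time.

# A small cohort for module tests: 4 groups x 2 participants x 250 cells.
small_cohort <- function(seed = 7, n_per_group = 2, cells = 250, ...) {
  generate_cohort(synthetic_config(n_per_group = n_per_group,
                                   cells_per_participant = cells,
                                   seed = seed, ...))
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table); independent of any clustering code under test.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# CLR oracle: per-marker ratio to the geometric mean of (x + 1), then log2.
clr_oracle <- function(counts) {
  out <- apply(counts + 1, 2, function(col) log2(col / exp(mean(log(col)))))
  dimnames(out) <- dimnames(counts)
  out
}

# Two-component Gaussian-mixture log-likelihood at given parameters.
mix_loglik <- function(x, pi1, mu1, s1, mu2, s2)
  sum(log(pi1 * dnorm(x, mu1, s1) + (1 - pi1) * dnorm(x, mu2, s2)))

# Dense matrix -> count_matrix with generated ids.
cm <- function(m, class = "ADT", prefix = "c") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("%s%04d", prefix, seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%03d", seq_len(ncol(m)))
  count_matrix(m, class)
}
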