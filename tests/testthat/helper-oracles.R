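# Independent oracles, kept deliberately separate from the package's code
# paths.

# G statistic computed from the 2 x L contingency-table formulation:
# E = row total * column total / grand total, G = 2 * sum O*log(O/E).
g_stat_oracle <- function(a, b) {
  O <- rbind(a, b)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

# Recursive enumeration of all compositions of n into k nonnegative parts,
# in a different order and by a different algorithm than the package's
# stars-and-bars encoding.
compositions_recursive <- function(n, k) {
  if (k == 1) return(matrix(n, nrow = 1))
  cols <- lapply(0:n, function(first) {
    rest <- compositions_recursive(n - first, k - 1)
    rbind(first, rest)
  })
  do.call(cbind, cols)
}

# Exact randomization-limit p-value via the recursive enumeration: an
# independent re-derivation of exact_pvalue().
exact_pvalue_oracle <- function(a, b) {
  active <- which(a + b > 0)
  n_a <- sum(a); n_b <- sum(b)
  p0 <- (a + b)[active] / (n_a + n_b)
  t_obs <- g_stat_oracle(a, b)
  Ca <- compositions_recursive(n_a, length(active))
  Cb <- compositions_recursive(n_b, length(active))
  p <- 0
  for (i in seq_len(ncol(Ca))) {
    for (j in seq_len(ncol(Cb))) {
      t_ij <- g_stat_oracle(Ca[, i], Cb[, j])
      if (t_ij >= t_obs - 1e-9) {
        p <- p + dmultinom(Ca[, i], prob = p0) * dmultinom(Cb[, j], prob = p0)
      }
    }
  }
  p
}

# Draw a random sparse two-group stage table (levels x 1 each) for
# property sweeps.
random_stage_pair <- function(max_total = 40) {
  probs <- as.numeric(rmultinom(1, 20, rep(1 / 8, 8))) + 0.5
  probs <- probs / sum(probs)
  n_a <- sample(1:max_total, 1)
  n_b <- sample(1:max_total, 1)
  list(a = as.numeric(rmultinom(1, n_a, probs)),
       b = as.numeric(rmultinom(1, n_b, probs)))
}

# Minimal valid per-root observation data.frame for IO tests.
make_root_df <- function(genotype, counts_list, pr_length = 5) {
  rows <- lapply(seq_along(counts_list), function(i) {
    cnt <- counts_list[[i]]
    df <- data.frame(root_id = sprintf("%s_r%d", genotype[i], i),
                     genotype = genotype[i], pr_length_cm = pr_length,
                     emerged_count = cnt[8], stringsAsFactors = FALSE)
    df[paste0("stage_", stage_levels())] <- as.list(cnt)
    df
  })
  do.call(rbind, rows)
}
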