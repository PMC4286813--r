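# Tolerance used when comparing simulated/enumerated statistics to the
# observed one: tables whose statistics are mathematically equal can differ
# in the last float bit, and "at least as extreme" must treat them as tied.
TIE_TOL <- 1e-9

#' Multinomial log-likelihood kernel
#'
#' `sum(counts * log(probs))` with the convention `0 * log(0) = 0`. The
#' multinomial coefficient is omitted: it depends only on the counts, so it
#' cancels in every likelihood ratio formed here.
#'
#' @param counts Stage-count vector (see [stage_counts()]) or any
#'   nonnegative integer vector.
#' @param probs Probability vector of the same length (nonnegative, sums
#'   to 1). A zero probability is only admissible where the count is zero.
#' @return The kernel log-likelihood (a real, `<= 0` scaled by counts).
#' @export
#' @examples
#' multinomial_loglik_kernel(c(1, 1, rep(0, 6)), c(0.5, 0.5, rep(0, 6)))  # log(0.25)
multinomial_loglik_kernel <- function(counts, probs) {
  if (length(counts) != length(probs)) {
    lrp_stop("counts and probs must have equal length", "lrp_validation_error")
  }
  check_probs(probs, k = length(probs))
  if (any(counts < 0)) lrp_stop("counts must be nonnegative", "lrp_validation_error")
  if (any(counts > 0 & probs == 0)) {
    lrp_stop("positive count at zero probability: observation impossible under these probabilities",
             "lrp_impossible_observation_error")
  }
  pos <- counts > 0
  sum(counts[pos] * log(probs[pos]))
}

#' Two-sample multinomial generalized likelihood-ratio statistic
#'
#' Compares two genotypes' stage-count vectors under the null hypothesis
#' that the stage frequencies are identical (pooled multinomial) against
#' the alternative that each group has its own frequencies. The statistic
#' is the deviance form
#' \deqn{T = 2\,[\ell_a(\hat p_a) + \ell_b(\hat p_b)
#'            - \ell_a(\hat p_0) - \ell_b(\hat p_0)]}
#' where \eqn{\hat p_a, \hat p_b} are the groups' own frequencies and
#' \eqn{\hat p_0} the pooled frequencies. This is algebraically the
#' two-sample G statistic \eqn{2 \sum O \ln(O/E)} on the 2-by-8 table.
#' Levels empty in both groups contribute 0 and are retained.
#'
#' @param a,b Stage-count vectors (each total >= 1); any equal-length
#'   nonnegative integer vectors are accepted.
#' @return A list: `statistic` (>= 0) and `pooled_freqs` (the null MLE).
#' @export
#' @examples
#' glr_statistic(c(10, rep(0, 7)), c(0, 10, rep(0, 6)))$statistic  # 40 * log(2)
glr_statistic <- function(a, b) {
  if (length(a) != length(b)) {
    lrp_stop("count vectors must have equal length", "lrp_validation_error")
  }
  if (any(a < 0) || any(b < 0)) lrp_stop("counts must be nonnegative", "lrp_validation_error")
  n_a <- sum(a); n_b <- sum(b)
  if (n_a < 1 || n_b < 1) {
    lrp_stop("each group needs at least one observed LRP", "lrp_insufficient_data_error")
  }
  p0 <- (a + b) / (n_a + n_b)
  stat <- 2 * (multinomial_loglik_kernel(a, a / n_a) +
               multinomial_loglik_kernel(b, b / n_b) -
               multinomial_loglik_kernel(a, p0) -
               multinomial_loglik_kernel(b, p0))
  list(statistic = max(stat, 0), pooled_freqs = p0)
}

# Strict lexicographic comparison of two numeric vectors.
vec_less <- function(x, y) {
  i <- which(x != y)
  length(i) > 0 && x[i[1]] < y[i[1]]
}

# Vectorized G statistic for replicate count matrices (levels x replicates).
# Same quantity as glr_statistic(), computed column-wise.
glr_statistic_matrix <- function(A, B) {
  n_a <- colSums(A); n_b <- colSums(B)
  P0 <- sweep(A + B, 2, n_a + n_b, "/")
  xlogx <- function(O, E) {
    out <- O * log(O / E)
    out[O == 0] <- 0
    out
  }
  stat <- 2 * (colSums(xlogx(A, sweep(P0, 2, n_a, "*"))) +
               colSums(xlogx(B, sweep(P0, 2, n_b, "*"))))
  pmax(stat, 0)
}

#' Randomization (parametric bootstrap) test for stage distributions
#'
#' The Monte Carlo test used when pooled stage counts are too sparse for a
#' chi-squared approximation. The observed G statistic (see
#' [glr_statistic()]) is compared against its distribution under the fitted
#' null: each of `B` replicates draws both groups afresh from a multinomial
#' with the pooled frequencies, at the groups' observed totals, and
#' recomputes the statistic. The p-value is the proportion of replicate
#' statistics at least as extreme as the observed one.
#'
#' The draws are made in a canonical internal ordering of groups and
#' levels, so the reported p-value is exactly invariant under relabelling
#' of stage levels and under swapping the two groups.
#'
#' Tie rules: `"geq"` (default) counts replicates with `T* >= T_obs`;
#' `"strict"` counts `T* > T_obs`; `"plus_one"` uses the add-one estimator
#' `(1 + #\{T* >= T_obs\}) / (B + 1)`, which can never return 0.
#'
#' @param a,b Stage-count vectors for the two genotypes.
#' @param B Number of randomization replicates (default 10000; minimum 100,
#'   with a warning below 1000).
#' @param seed Integer seed; identical seeds reproduce identical results.
#' @param tie_rule One of `"geq"`, `"strict"`, `"plus_one"`.
#' @return An object of class `"glrt_result"`: `statistic`, `p_value`, `B`,
#'   `null_statistics` (the B replicate statistics), `tie_rule`, `seed`,
#'   `n_a`, `n_b`, `pooled_freqs`.
#' @export
#' @examples
#' a <- c(12, 8, 5, 3, 1, 1, 0, 0)
#' b <- c(4, 5, 6, 5, 4, 3, 2, 1)
#' randomization_test(a, b, B = 1000, seed = 1)
randomization_test <- function(a, b, B = 10000, seed = 1,
                               tie_rule = c("geq", "strict", "plus_one")) {
  tie_rule <- match.arg(tie_rule)
  B <- as.integer(B)
  if (is.na(B) || B < 1) lrp_stop("B must be a positive integer", "lrp_domain_error")
  if (B < 100) lrp_stop("B below the enforced minimum of 100", "lrp_domain_error")
  if (B < 1000) warning("B < 1000: Monte Carlo error on the p-value may be substantial")
  obs <- glr_statistic(a, b)
  n_a <- sum(a); n_b <- sum(b)
  # Canonical internal ordering makes the Monte Carlo draws -- and hence the
  # p-value -- exactly invariant to relabelling the stage levels and to
  # swapping the two groups: the lexicographically larger group (by total,
  # then counts) is drawn first, and levels are sorted by decreasing pooled
  # count with per-group counts breaking ties (levels with fully identical
  # counts are exchangeable, so their order cannot matter).
  if (vec_less(c(n_a, a), c(n_b, b))) { tmp <- a; a <- b; b <- tmp }
  ord <- order(-(a + b), -a, -b)
  ac <- a[ord]; bc <- b[ord]
  p0c <- (ac + bc) / (n_a + n_b)
  set.seed(seed)
  A <- stats::rmultinom(B, sum(ac), p0c)
  Bm <- stats::rmultinom(B, sum(bc), p0c)
  null_stats <- glr_statistic_matrix(A, Bm)
  n_ge <- sum(null_stats >= obs$statistic - TIE_TOL)
  p <- switch(tie_rule,
    geq = n_ge / B,
    strict = sum(null_stats > obs$statistic + TIE_TOL) / B,
    plus_one = (1 + n_ge) / (B + 1)
  )
  structure(list(statistic = obs$statistic, p_value = p, B = B,
                 null_statistics = null_stats, tie_rule = tie_rule, seed = seed,
                 n_a = n_a, n_b = n_b, pooled_freqs = obs$pooled_freqs),
            class = "glrt_result")
}

#' @export
print.glrt_result <- function(x, ...) {
  cat("Two-sample multinomial GLRT with randomization null\n")
  cat(sprintf("  G statistic: %.4f   (n_a = %d, n_b = %d)\n", x$statistic, x$n_a, x$n_b))
  cat(sprintf("  p-value:     %.4g   (B = %d, tie rule: %s, seed = %d)\n",
              x$p_value, x$B, x$tie_rule, x$seed))
  invisible(x)
}

# Enumerate all compositions of n into k nonnegative parts, as a k x M
# matrix, via divider positions in the stars-and-bars encoding.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, nrow = 1))
  div <- utils::combn(n + k - 1, k - 1)
  bounds <- rbind(0L, div, n + k)
  diff(bounds) - 1L
}

#' Exact p-value by full enumeration of the null distribution
#'
#' Brute-force oracle for [randomization_test()]: enumerates every pair of
#' null tables (all compositions of `n_a` and of `n_b` over the levels with
#' nonzero pooled counts), sums the exact multinomial null probabilities of
#' pairs whose statistic is at least the observed one. This is the limit of
#' the randomization p-value (tie rule `"geq"`) as `B` grows. Feasible only
#' for small totals and few active levels.
#'
#' @param a,b Stage-count vectors.
#' @param max_states Refuse if the number of table pairs exceeds this
#'   (default 5e6).
#' @return The exact p-value.
#' @export
exact_pvalue <- function(a, b, max_states = 5e6) {
  obs <- glr_statistic(a, b)
  active <- which(a + b > 0)
  k <- length(active)
  n_a <- sum(a); n_b <- sum(b)
  m_a <- choose(n_a + k - 1, k - 1)
  m_b <- choose(n_b + k - 1, k - 1)
  if (m_a * m_b > max_states) {
    lrp_stop(sprintf("state space too large: %.0f x %.0f = %.3g pairs exceeds max_states = %g",
                     m_a, m_b, m_a * m_b, max_states),
             "lrp_state_space_error")
  }
  p0 <- obs$pooled_freqs[active]
  Ca <- compositions(n_a, k)
  Cb <- compositions(n_b, k)
  logp_comp <- function(C, n) {
    # log multinomial pmf for each composition column
    lgamma(n + 1) - colSums(lgamma(C + 1)) + colSums(C * ifelse(p0 > 0, log(p0), 0))
  }
  lpa <- logp_comp(Ca, n_a)
  lpb <- logp_comp(Cb, n_b)
  idx <- expand.grid(ia = seq_len(ncol(Ca)), ib = seq_len(ncol(Cb)))
  A <- Ca[, idx$ia, drop = FALSE]
  Bm <- Cb[, idx$ib, drop = FALSE]
  stats_all <- glr_statistic_matrix(A, Bm)
  probs <- exp(lpa[idx$ia] + lpb[idx$ib])
  sum(probs[stats_all >= obs$statistic - TIE_TOL])
}
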