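# Derive a per-replicate seed from a base seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483629)
}

#' Type-I error / power calibration of the randomization test
#'
#' Simulates repeated two-group staging datasets and measures how often
#' [randomization_test()] rejects at level `alpha`. Under `regime = "null"`
#' both groups are drawn from `null_probs` (so the rejection rate estimates
#' the type-I error); supplying `alt_probs` switches group b to the
#' alternative frequencies (so the rate estimates power).
#'
#' @param null_probs Stage probabilities for group a (and for group b when
#'   no alternative is given). Any length; typically 8 (the ontology).
#' @param n_a,n_b Group totals (pooled LRP counts) for each simulated
#'   dataset.
#' @param alt_probs Optional stage probabilities for group b (alternative
#'   regime).
#' @param reps Number of simulated datasets.
#' @param B Randomization replicates per dataset.
#' @param alpha Nominal test level.
#' @param seed Integer seed; dataset draws and every inner randomization
#'   test are deterministically derived from it.
#' @param tie_rule Passed to [randomization_test()].
#' @return An object of class `"calibration_report"`: `regime`,
#'   `nominal_alpha`, `rejection_rate`, `reps`, `binom_ci95` (exact
#'   Clopper--Pearson 95% interval), `p_values` (per-dataset).
#' @export
#' @examples
#' calibrate(rep(0.25, 4), n_a = 40, n_b = 40, reps = 50, B = 200, seed = 1)
calibrate <- function(null_probs, n_a, n_b, alt_probs = NULL,
                      reps = 500, B = 1000, alpha = 0.05, seed = 1,
                      tie_rule = "geq") {
  check_probs(null_probs, k = length(null_probs))
  if (!is.null(alt_probs)) {
    if (length(alt_probs) != length(null_probs)) {
      lrp_stop("alt_probs must match null_probs in length", "lrp_domain_error")
    }
    check_probs(alt_probs, k = length(alt_probs))
  }
  if (reps < 1) lrp_stop("reps must be >= 1", "lrp_domain_error")
  regime <- if (is.null(alt_probs)) "null" else "alternative"
  pb <- if (is.null(alt_probs)) null_probs else alt_probs
  set.seed(seed)
  As <- stats::rmultinom(reps, n_a, null_probs)
  Bs <- stats::rmultinom(reps, n_b, pb)
  pvals <- vapply(seq_len(reps), function(i) {
    suppressWarnings(
      randomization_test(As[, i], Bs[, i], B = B,
                         seed = derive_seed(seed, i), tie_rule = tie_rule)$p_value
    )
  }, numeric(1))
  n_rej <- sum(pvals <= alpha)
  ci <- stats::binom.test(n_rej, reps)$conf.int
  structure(list(regime = regime, nominal_alpha = alpha,
                 rejection_rate = n_rej / reps, reps = reps, B = B,
                 binom_ci95 = c(lo = ci[1], hi = ci[2]), p_values = pvals,
                 seed = seed),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration (%s regime): rejection rate %.3f at alpha = %.3g\n",
              x$regime, x$rejection_rate, x$nominal_alpha))
  cat(sprintf("  reps = %d, B = %d, 95%% CI [%.3f, %.3f]\n",
              x$reps, x$B, x$binom_ci95["lo"], x$binom_ci95["hi"]))
  invisible(x)
}
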