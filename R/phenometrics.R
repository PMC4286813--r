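#' Emerged lateral root density
#'
#' Emerged-LR density is defined per seedling as the number of visible
#' emerged lateral roots divided by the primary-root length in cm.
#'
#' @param emerged_count Nonnegative integer, emerged LRs on the seedling.
#' @param pr_length_cm Positive primary-root length (cm).
#' @return Density in LRs per cm.
#' @export
#' @examples
#' lr_density(10, 5.0)  # 2 LRs / cm
lr_density <- function(emerged_count, pr_length_cm) {
  if (any(is.na(pr_length_cm)) || any(pr_length_cm <= 0)) {
    lrp_stop("pr_length_cm must be positive", "lrp_domain_error")
  }
  if (any(is.na(emerged_count)) || any(emerged_count < 0)) {
    lrp_stop("emerged_count must be nonnegative", "lrp_domain_error")
  }
  emerged_count / pr_length_cm
}

#' Branching-zone lateral root density
#'
#' Density of emerged LRs per cm of the branching zone, the primary-root
#' segment spanning the most shootward to the most rootward emerged LR.
#' Requires at least two emerged LRs, since a single LR defines a zone of
#' zero extent.
#'
#' @param lr_positions_cm Positions of the emerged LRs along the PR (cm from
#'   the root--shoot junction); length must equal `emerged_count`.
#' @param emerged_count Number of emerged LRs (>= 2).
#' @return Density in LRs per cm of branching zone.
#' @export
#' @examples
#' branching_density(c(0.5, 1.5, 2.5, 3.5), 4)  # 4 LRs over a 3 cm zone
branching_density <- function(lr_positions_cm, emerged_count) {
  if (length(lr_positions_cm) != emerged_count) {
    lrp_stop("positions length must equal emerged_count", "lrp_validation_error")
  }
  if (emerged_count < 2) {
    lrp_stop("branching density is undefined for fewer than 2 emerged LRs (zero-extent zone)",
             "lrp_undefined_metric_error")
  }
  span <- max(lr_positions_cm) - min(lr_positions_cm)
  if (span <= 0) {
    lrp_stop("branching density is undefined: all LRs at one position (zero-extent zone)",
             "lrp_undefined_metric_error")
  }
  emerged_count / span
}

#' Standard error of a proportion
#'
#' `sqrt(p * (1 - p) / n)`, the binomial standard error used for
#' stage-distribution error bars.
#'
#' @param p Proportion in `[0, 1]`.
#' @param n Population size (positive integer).
#' @return Standard error (same length as `p`).
#' @export
#' @examples
#' proportion_se(0.5, 100)  # 0.05
proportion_se <- function(p, n) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    lrp_stop("p must lie in [0, 1]", "lrp_domain_error")
  }
  if (any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    lrp_stop("n must be a positive integer", "lrp_domain_error")
  }
  sqrt(p * (1 - p) / n)
}

#' Stage-distribution summary for one genotype
#'
#' Summarizes a genotype's LRP stage distribution either from the pooled
#' strain-level counts (`basis = "pooled_counts"`: proportions are pooled
#' counts over the pooled total, with binomial standard errors at the pooled
#' n) or as the mean of per-root proportion vectors
#' (`basis = "per_root_mean"`: each root contributes its own percentage
#' vector; the standard error is the between-root SEM). Proportions are on
#' `[0, 1]`; multiply by 100 for presentation.
#'
#' @param pooled One-genotype row of a [pool_by_genotype()] table (or the
#'   full table plus `genotype`).
#' @param basis `"pooled_counts"` or `"per_root_mean"`.
#' @param per_root Per-root observation table, required for
#'   `"per_root_mean"`; only rows of the target genotype are used, and every
#'   such root must have at least one scored LRP.
#' @param genotype Genotype label (needed when `pooled` has several rows).
#' @return A list of class `"stage_distribution"`: `genotype`, `basis`,
#'   `proportions` and `se_per_level` (named over [stage_levels()]), and `n`
#'   (pooled LRP count, or root count for the per-root basis).
#' @export
stage_distribution <- function(pooled, basis = c("pooled_counts", "per_root_mean"),
                               per_root = NULL, genotype = NULL) {
  basis <- match.arg(basis)
  if (is.null(genotype)) {
    if (nrow(pooled) != 1) {
      lrp_stop("supply `genotype` when the pooled table has several rows",
               "lrp_validation_error")
    }
    genotype <- pooled$genotype[1]
  }
  cnt <- genotype_counts(pooled, genotype)
  if (basis == "pooled_counts") {
    n <- sum(cnt)
    if (n == 0) {
      lrp_stop(sprintf("genotype '%s' has zero pooled LRPs: stage distribution is degenerate",
                       genotype),
               "lrp_degenerate_error")
    }
    p <- cnt / n
    se <- proportion_se(p, n)
  } else {
    if (is.null(per_root)) {
      lrp_stop("per_root observations are required for basis = 'per_root_mean'",
               "lrp_validation_error")
    }
    rows <- per_root[per_root$genotype == genotype, , drop = FALSE]
    if (nrow(rows) == 0) {
      lrp_stop(sprintf("no per-root observations for genotype '%s'", genotype),
               "lrp_validation_error")
    }
    mat <- as.matrix(rows[, stage_cols()])
    tot <- rowSums(mat)
    if (any(tot == 0)) {
      lrp_stop("per_root_mean basis requires every root to have >= 1 scored LRP",
               "lrp_degenerate_error")
    }
    props <- mat / tot
    p <- colMeans(props)
    n <- nrow(rows)
    se <- if (n > 1) apply(props, 2, stats::sd) / sqrt(n) else rep(NA_real_, n_stages())
  }
  names(p) <- names(se) <- stage_levels()
  structure(list(genotype = genotype, basis = basis, proportions = p,
                 se_per_level = se, n = n),
            class = "stage_distribution")
}

#' @export
print.stage_distribution <- function(x, ...) {
  cat(sprintf("Stage distribution for %s (basis: %s, n = %d)\n",
              x$genotype, x$basis, x$n))
  print(round(rbind(proportion = x$proportions, se = x$se_per_level), 4))
  invisible(x)
}

#' Compare mean LR densities between two genotypes
#'
#' Two-sample t-test of the null hypothesis that mean per-seedling LR
#' density does not differ between the groups. Welch's unequal-variance
#' test is the default; set `var_equal = TRUE` for the pooled-variance
#' Student variant.
#'
#' @param group_a,group_b Numeric vectors of per-root densities, each of
#'   length >= 2 and with nonzero combined variance.
#' @param var_equal Assume equal variances (default `FALSE`, Welch).
#' @return A list: `statistic` (t), `df`, `p_value` (two-sided).
#' @export
#' @examples
#' compare_densities(c(1.0, 1.1, 0.9, 1.0), c(2.0, 2.1, 1.9, 2.0))
compare_densities <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    lrp_stop("each group needs at least 2 density values", "lrp_insufficient_data_error")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    lrp_stop("both groups are constant: zero variance, t-test undefined",
             "lrp_degenerate_error")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
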