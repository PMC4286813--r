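---
title: "Stage-distribution statistics for lateral root phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-distribution statistics for lateral root phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpstage)
```

## The problem

Lateral root (LR) development in Arabidopsis proceeds through a stereotyped
series of primordium stages: pericycle founder cells divide to form a lateral
root primordium (LRP) that is scored morphologically into stages I–VII before
it emerges through the primary root (PR) surface. Mutants that accelerate or
delay this progression shift the *distribution* of LRP stages observed in a
population of seedlings, even when endpoint counts look similar. Two assay
designs produce such data:

* **whole-root surveys** — every LRP on a cleared root is staged, and emerged
  LRs are counted along with the PR length (giving densities in LRs cm⁻¹);
* **gravistimulation time courses** — rotating the plate 90° induces a single
  LRP per seedling at a bend, and the stage of that primordium is scored at
  fixed times (18 h and 42 h) after the stimulus.

Either way the data are sparse categorical counts over an eight-level
ontology (`I II III IV V VI VII E`, where `E` is the emerged class sometimes
written "VIII"). Pooled per-genotype counts are typically a few dozen to a few
hundred, spread over eight cells, so the usual chi-squared approximation for
comparing two genotypes is unreliable. This package implements the
alternative used for such tables: a multinomial generalized likelihood-ratio
(G) test whose null distribution is generated by parametric randomization,
plus the surrounding phenometrics and a stage-progression simulator that
makes the whole pipeline testable without laboratory data.

## The test

For genotypes $a$ and $b$ with pooled stage counts $O_{a k}, O_{b k}$ and
totals $n_a, n_b$, the null hypothesis is that both groups draw from one
multinomial with frequencies $p_k$; the alternative gives each group its own
frequencies. Maximizing the multinomial likelihoods gives the group
frequencies $\hat p_{g k} = O_{g k} / n_g$ under the alternative and the
pooled frequencies $\hat p_{0 k} = (O_{a k} + O_{b k}) / (n_a + n_b)$ under
the null, and the deviance-form statistic

$$T \;=\; 2 \sum_{g \in \{a,b\}} \sum_k O_{g k}
      \ln \frac{O_{g k}}{n_g \, \hat p_{0 k}},$$

the two-sample G statistic on the $2 \times 8$ table ($0 \ln 0 = 0$; levels
empty in both groups contribute nothing and are retained). Any strictly
monotone transform of the likelihood ratio yields the same randomization
p-value, because the identical statistic is applied to observed and simulated
data; the factor 2 is adopted so that the large-sample reference distribution
is $\chi^2_7$, which the test suite uses as a cross-check.

`randomization_test()` draws $B$ replicate datasets under the fitted null —
$a^* \sim \mathrm{Mult}(n_a, \hat p_0)$ and
$b^* \sim \mathrm{Mult}(n_b, \hat p_0)$, group sizes fixed, drawn
independently — recomputes $T^*$ for each, and reports
$p = \#\{T^* \ge T_{\mathrm{obs}}\} / B$. The default $B$ is 10 000;
$B < 100$ is refused and $B < 1000$ warns.

Design choices that were genuinely open:

* **Tie rule.** "At least as extreme" is implemented as $\ge$ by default,
  which is conservative when many replicates tie with the observed statistic
  (notably at $T_{\mathrm{obs}} = 0$, where $p = 1$). A strict-$>$ rule and
  the add-one estimator $(1 + \#\{T^* \ge T\})/(B + 1)$ (which can never
  return 0, and is exact-valid under continuity) are available via
  `tie_rule`.
* **Tie tolerance.** Replicate tables whose statistics are mathematically
  equal to $T_{\mathrm{obs}}$ can differ in the last float bit, so
  comparisons use $T^* \ge T_{\mathrm{obs}} - 10^{-9}$; the exact-enumeration
  oracle applies the same tolerance, so the two routes count ties
  identically.
* **Invariance by construction.** The Monte Carlo draws are made in a
  canonical internal ordering — levels sorted by decreasing pooled count
  with per-group counts breaking ties, and the lexicographically larger
  group drawn first — so the reported p-value is *exactly* unchanged by
  relabelling stages consistently in both groups or by swapping the groups,
  not merely unchanged in distribution.
* **Pooling before testing.** Counts are pooled across roots within a
  genotype before testing; per-root percentage vectors are descriptive
  summaries only. The test is pairwise (each genotype against a reference),
  with no correction across comparisons by default; a Bonferroni adjustment
  is a caller-side multiplication and deliberately not wired in.

`exact_pvalue()` is the brute-force oracle: it enumerates every pair of
compositions of $n_a$ and $n_b$ over the levels with nonzero pooled counts
and sums exact multinomial probabilities of outcomes at least as extreme.
The state space grows as
$\binom{n_a + k - 1}{k - 1}\binom{n_b + k - 1}{k - 1}$, so it is only usable
for small totals over few active levels — which is exactly its role: the
$B \to \infty$ limit against which the randomization route is verified, on
tables with totals at most 8 over at most 3 active levels.

`calibrate()` treats the whole procedure as the object under study: it
simulates many two-group datasets (both groups from the null frequencies, or
group b from alternative frequencies), runs the randomization test on each,
and reports the rejection rate at a nominal level with an exact
Clopper–Pearson 95% interval. The suite checks that the type-I error at
$\alpha = 0.05$ (uniform four-level null, $n = 40/40$, $B = 1000$, 500
datasets) is statistically compatible with 0.05, and that power rises with
the total-variation distance between null and alternative.

## Phenometrics

* `lr_density(count, length)` — emerged LRs per cm of PR, per seedling.
* `branching_density(positions, count)` — emerged LRs per cm of the
  branching zone, the PR segment from the most shootward to the most
  rootward emerged LR. The zone is defined by the LR positions themselves,
  so the metric requires at least two emerged LRs; fewer is an error, not a
  zero. This span definition follows the metric's standard usage and is
  recorded here as an assumption.
* `proportion_se(p, n)` — $\sqrt{p(1-p)/n}$, the error bar for a stage
  proportion.
* `stage_distribution()` — proportions per stage either from pooled counts
  (binomial SEs at the pooled total) or as the mean of per-root proportion
  vectors (between-root SEM). Proportions live on $[0,1]$ internally;
  multiply by 100 only for presentation.
* `compare_densities()` — the two-sample t-test on per-seedling densities.
  Welch's unequal-variance form is the default on robustness grounds; the
  pooled-variance Student form is `var_equal = TRUE`.

Zero-LRP roots are legal observations throughout: they contribute zero
counts to pooling and a zero density, and dropping them would bias density
comparisons.

## The synthetic-data generator

No accession numbers or per-seedling tables accompany the assays this
package targets, so the generator is first-class, tested code that stands in
for the measurements. Progression is modelled as a linear continuous-time
Markov chain over I → II → … → VII → E with exponential dwell times
(`stage_rates`, per hour; E absorbing). A genotype is one positive
multiplier scaling all seven rates — faster progression is a multiplier
above 1, slower below 1 — which matches the qualitative phenotype the assays
detect (an overall shift of the stage distribution) and keeps recovery
one-dimensional. An Erlang-type refinement (less dispersed dwell times) was
considered and left out: snapshot data at two observation times barely
constrain dwell-time shape, and the exponential chain is the simplest model
identifiable from these designs.

Defaults, chosen once as a realistic wild-type baseline:

| parameter | default | why |
|---|---|---|
| `stage_rates` | 0.14 h⁻¹ × 7 | median induced LRP near stage III at 18 h and near VI at 42 h, so the two scoring times straddle the ontology |
| `initiation_lag_h_mean` | 6 h | mean delay from gravistimulus to the first pericycle division; exponential, genotype-independent |
| `initiation_intensity` | 2 cm⁻¹ | whole-root LRP initiations per cm; with roughly half emerged this gives emerged densities near 1 LR cm⁻¹, the magnitude seen in wild-type seedlings |
| `pr_length_mean_cm`, `sd` | 5 ± 1 cm | 10-day-old vertically grown seedlings |
| `root_age_h` | 96 h | LRP ages are uniform on this window. Initiation begins ~3 d after germination, but the PR accelerates as it grows, so most primordia present at day 10 are only a few days old; a ~4-day uniform cohort reproduces the roughly half-emerged, half-staged composition of wild-type surveys. Using the full seedling age here would make ~80% of LRPs emerged and hollow out the staged classes |
| `observation_times_h` | 18, 42 | the induced-assay scoring times |
| `n_roots` | 30 | within the 20–60 seedlings-per-genotype range of such experiments |

`simulate_induced()` gives each seedling an exponential initiation lag and
one chain trajectory, recording the occupied stage (or `NONE` before
initiation) at each observation time; a seedling's stage is nondecreasing
across its own observation times and E is absorbing. `NONE` seedlings are
recorded but excluded from stage-distribution proportions — a convention
this package fixes explicitly, since assay reports typically leave it
implicit. `simulate_whole_root()` draws a truncated-normal PR length, a
Poisson number of LRPs (intensity × length), uniform LRP ages, and each
LRP's stage from its own chain at its own age (no lag: age is measured from
initiation); emerged LRs get uniform positions along the PR. The spanned
branching zone is therefore a byproduct of the positions, not a parameter.

What the generator does *not* emulate: spatial structure (acropetal ranking
of primordia, priming oscillations, left–right alternation), primordium
arrest, between-seedling rate heterogeneity, and measurement error in
staging. Passing tests therefore demonstrate that the statistical machinery
behaves correctly on data with the assays' *sampling structure* — sparse
multinomial snapshots of a monotone progression — not that the kinetic model
is a faithful account of root biology.

`recover_multiplier()` closes the loop: the stage occupied at a snapshot
time is a phase-type observation of the chain, so occupancy probabilities
are the first row of $e^{Qt}$ for the chain generator $Q$ (with a `NONE`
state prepended when the lag is positive; the lag rate is known and not
scaled by the multiplier, mirroring the simulator). The categorical
log-likelihood over all records is maximized over the multiplier by 1-D
golden-section search on the log scale over $[10^{-3}, 10^3]$
(`stats::optimize`, tolerance $10^{-7}$). Data saturated at a boundary —
every record `E`, or every record `NONE` — carry no rate information and are
flagged as non-identifiable rather than returning a boundary estimate.

## Randomness and reproducibility

Every stochastic entry point takes a single integer seed and makes all its
draws in a fixed vectorized order, so identical seeds give bit-identical
results. Replicate loops (`calibrate()`, the power checks) derive one seed
per replicate through an explicit integer recurrence kept below $2^{31}$,
making each replicate reproducible in isolation and the whole loop
independent of execution order.

## Problem sizes used by the checks

The shipped verification uses: 1000 random sparse tables for the
G-statistic oracle comparison (agreement to $10^{-10}$); 20 enumerable
tables (totals ≤ 8, ≤ 3 active levels) for randomization-vs-exact
convergence within four Monte Carlo standard errors at $B = 10^4$; 500
datasets at $B = 1000$ for type-I calibration; 2000 replicates at
$n = 500/500$ with all eight levels active for the $\chi^2_7$
Kolmogorov–Smirnov cross-check (distance < 0.03); 1000 seedlings per
genotype for multiplier recovery within ±10% at multipliers 1.0 and 1.5;
and 200 replicates of the full pipeline (30 roots per genotype,
$B = 2000$, $\alpha = 0.05$) for end-to-end power against a 1.5× mutant.
These sizes make each property decidable with comfortable statistical
margin while keeping the whole suite quick on a laptop.

## Known limitations

* The test compares two genotypes; multi-group comparisons are a sequence
  of pairwise tests against a reference, uncorrected by default.
* The exact oracle is combinatorial and refuses large state spaces by
  design (`max_states`).
* The recovery model assumes the baseline rates are known exactly; jointly
  estimating seven rates and a multiplier from two snapshot times is not
  identifiable and is deliberately out of scope.
* `branching_density` needs per-LR positions, which whole-root tables may
  lack; it returns an error, never a silent fallback to whole-root density.

## A worked example

```{r example}
sc <- progression_scenario(genotype_multipliers = c(Col0 = 1.0, mutant = 1.5),
                           n_roots = 30, seed = 42)
d <- simulate_dataset(sc)
pooled <- pool_by_genotype(d$roots)
res <- randomization_test(genotype_counts(pooled, "Col0"),
                          genotype_counts(pooled, "mutant"),
                          B = 10000, seed = 42)
res
dens <- with(d$roots, tapply(lr_density(emerged_count, pr_length_cm), genotype, mean))
round(dens, 3)
est <- recover_multiplier(d$induced[d$induced$genotype == "mutant", ],
                          sc$stage_rates, lag_mean = sc$initiation_lag_h_mean)
round(as.numeric(est), 3)
```
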