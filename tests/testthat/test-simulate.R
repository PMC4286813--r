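scenario_two <- function(mult = 1.5, n_roots = 30, seed = 1, ...) {
  progression_scenario(genotype_multipliers = c(wt = 1.0, mut = mult),
                       n_roots = n_roots, seed = seed, ...)
}

test_that("scenario construction validates its parameters", {
  expect_s3_class(scenario_two(), "progression_scenario")
  expect_error(progression_scenario(stage_rates = rep(0.1, 6)),
               class = "lrp_config_error")
  expect_error(progression_scenario(genotype_multipliers = c(1, 2)),
               class = "lrp_config_error")
  expect_error(progression_scenario(genotype_multipliers = c(wt = -1)),
               class = "lrp_config_error")
  expect_error(progression_scenario(observation_times_h = c(18, 0)),
               class = "lrp_config_error")
})

test_that("scenario YAML round-trips through read_scenario", {
  f <- withr::local_tempfile(fileext = ".yaml")
  sc <- scenario_two(n_roots = 12, seed = 9)
  yaml::write_yaml(list(stage_rates = sc$stage_rates,
                        genotype_multipliers = as.list(sc$genotype_multipliers),
                        n_roots = 12, seed = 9), f)
  back <- read_scenario(f)
  expect_equal(back$stage_rates, sc$stage_rates)
  expect_equal(back$genotype_multipliers, sc$genotype_multipliers)
  expect_equal(back$n_roots, 12L)
  yaml::write_yaml(list(bogus_field = 1), f)
  expect_error(read_scenario(f), class = "lrp_config_error")
  # the committed example fixture parses
  ex <- system.file("extdata", "scenario_example.yaml", package = "lrpstage")
  expect_s3_class(read_scenario(ex), "progression_scenario")
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- scenario_two(n_roots = 15, seed = 33)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$roots, d2$roots)
  expect_identical(d1$induced, d2$induced)
  d3 <- simulate_dataset(sc, seed = 34)
  expect_false(identical(d1$roots, d3$roots))
})

test_that("simulated records pass the data model's own validation", {
  d <- simulate_dataset(scenario_two(n_roots = 20, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_result_table(d$roots, f)
  expect_equal(nrow(read_root_table(f)), 40)
  write_result_table(d$induced, f)
  expect_equal(nrow(read_induced_table(f)), 80)
  # positions lie within each root
  ok <- mapply(function(p, len) length(p) == 0 || all(p >= 0 & p <= len),
               d$roots$lr_positions_cm, d$roots$pr_length_cm)
  expect_true(all(ok))
  expect_identical(d$roots$emerged_count, d$roots$stage_E)
})

test_that("induced assay: stage is monotone in time and limits are absorbing/frozen", {
  d <- simulate_induced(scenario_two(n_roots = 200, seed = 8))
  idx <- function(s) match(s, c("NONE", stage_levels())) - 1
  by_seedling <- split(d, d$seedling_id)
  for (s in by_seedling) {
    s <- s[order(s$observation_time_h), ]
    expect_true(all(diff(idx(s$stage)) >= 0))
  }

  fast <- progression_scenario(genotype_multipliers = c(g = 1e6),
                               initiation_lag_h_mean = 0, n_roots = 50, seed = 3)
  expect_true(all(simulate_induced(fast)$stage == "E"))

  frozen <- progression_scenario(genotype_multipliers = c(g = 1e-6),
                                 n_roots = 50, seed = 3)
  expect_true(all(simulate_induced(frozen)$stage %in% c("NONE", "I")))
})

test_that("faster genotypes are shifted toward later stages (stochastic dominance)", {
  sc <- scenario_two(mult = 1.5, n_roots = 2000, seed = 12)
  d <- simulate_induced(sc)
  d18 <- d[d$observation_time_h == 18 & d$stage != "NONE", ]
  idx <- match(d18$stage, stage_levels())
  expect_gt(mean(idx[d18$genotype == "mut"]), mean(idx[d18$genotype == "wt"]))
  # empirical CDF of the faster genotype lies below at every cut-point
  cdf_wt <- cumsum(tabulate(idx[d18$genotype == "wt"], 8)) /
    sum(d18$genotype == "wt")
  cdf_mut <- cumsum(tabulate(idx[d18$genotype == "mut"], 8)) /
    sum(d18$genotype == "mut")
  expect_true(all(cdf_mut[1:7] <= cdf_wt[1:7] + 0.02))
  # and the two distributions differ by the randomization test
  cnt <- function(g) tabulate(idx[d18$genotype == g], 8)
  p <- randomization_test(cnt("wt"), cnt("mut"), B = 2000, seed = 4)$p_value
  expect_lt(p, 0.01)
})

test_that("whole-root survey respects the Poisson initiation process", {
  empty <- progression_scenario(genotype_multipliers = c(g = 1),
                                initiation_intensity = 0, n_roots = 20, seed = 5)
  r0 <- simulate_whole_root(empty)
  expect_true(all(r0[paste0("stage_", stage_levels())] == 0))
  expect_true(all(lr_density(r0$emerged_count, r0$pr_length_cm) == 0))

  # doubling the intensity doubles the expected emerged count (3 MC SEs)
  sc1 <- progression_scenario(genotype_multipliers = c(g = 1),
                              initiation_intensity = 1, n_roots = 5000, seed = 6)
  sc2 <- progression_scenario(genotype_multipliers = c(g = 1),
                              initiation_intensity = 2, n_roots = 5000, seed = 7)
  e1 <- simulate_whole_root(sc1)$emerged_count
  e2 <- simulate_whole_root(sc2)$emerged_count
  se <- sqrt(var(e2) / length(e2) + 4 * var(e1) / length(e1))
  expect_lt(abs(mean(e2) - 2 * mean(e1)), 3 * se)
})

test_that("faster genotypes show higher density and late-shifted pooled stages", {
  d <- simulate_whole_root(scenario_two(mult = 1.5, n_roots = 400, seed = 19))
  dens <- lr_density(d$emerged_count, d$pr_length_cm)
  expect_gt(mean(dens[d$genotype == "mut"]), mean(dens[d$genotype == "wt"]))
  pooled <- pool_by_genotype(d)
  late <- function(g) {
    pr <- stage_distribution(pooled, genotype = g)$proportions
    sum(pr[late_stages()])
  }
  expect_gt(late("mut"), late("wt"))
})

test_that("multiplier recovery is consistent and flags saturation", {
  sc <- scenario_two(mult = 1.5, n_roots = 400, seed = 23)
  d <- simulate_induced(sc)
  for (g in c("wt", "mut")) {
    truth <- sc$genotype_multipliers[[g]]
    est <- recover_multiplier(d[d$genotype == g, ], sc$stage_rates,
                              lag_mean = sc$initiation_lag_h_mean)
    expect_gt(as.numeric(est), truth * 0.8)
    expect_lt(as.numeric(est), truth * 1.25)
  }
  allE <- data.frame(seedling_id = "s", genotype = "g",
                     observation_time_h = 18, stage = rep("E", 10))
  expect_error(recover_multiplier(allE, sc$stage_rates, lag_mean = 6),
               class = "lrp_nonidentifiable_error")
  allN <- transform(allE, stage = "NONE")
  expect_error(recover_multiplier(allN, sc$stage_rates, lag_mean = 6),
               class = "lrp_nonidentifiable_error")
  expect_error(recover_multiplier(allN[0, ], sc$stage_rates),
               class = "lrp_insufficient_data_error")
})
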