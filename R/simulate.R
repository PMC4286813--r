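#' Parameterization of the stage-progression simulator
#'
#' A scenario bundles everything needed to emulate the two seedling assay
#' designs: a whole-root staging/density survey, and a gravistimulation
#' time course in which a single LRP is induced per seedling and scored at
#' fixed times. Progression is a linear continuous-time Markov chain over
#' the stages I -> II -> ... -> VII -> E with exponential dwell times;
#' genotype differences are a single positive multiplier scaling all seven
#' stage exit rates (multiplier > 1 = faster progression, < 1 = slower).
#'
#' Defaults describe a wild-type-like baseline: dwell rate 0.14 per hour at
#' every stage and a 6 h mean initiation lag put the median induced LRP
#' near stage III at 18 h and near stage VI at 42 h, spanning the early and
#' late halves of the ontology at the two scoring times.
#'
#' @param stage_rates Seven positive per-hour exit rates (I->II ... VII->E).
#' @param genotype_multipliers Named positive numeric vector, one entry per
#'   genotype, scaling all `stage_rates`.
#' @param initiation_intensity Expected LRP initiations per cm of PR
#'   (whole-root survey).
#' @param pr_length_mean_cm,pr_length_sd_cm Primary-root length
#'   distribution (Normal truncated at 0).
#' @param initiation_lag_h_mean Mean of the exponential delay from
#'   gravistimulus to first pericycle division (induced assay); 0 means no
#'   lag. Genotype-independent.
#' @param observation_times_h Scoring times for the induced assay (hours).
#' @param n_roots Seedlings (or roots) per genotype.
#' @param root_age_h Age horizon of the whole-root survey: LRP ages are
#'   drawn uniformly on `[0, root_age_h]`. Default 96 h: although lateral
#'   root initiation begins about 3 d after germination, the primary root
#'   accelerates as it grows, so most primordia present in a 10-day-old
#'   seedling initiated within the last few days; a uniform age window of
#'   about four days approximates that cohort and yields roughly equal
#'   numbers of emerged and unemerged primordia, as seen in wild-type
#'   staging surveys.
#' @param seed Integer seed.
#' @return A list of class `"progression_scenario"`.
#' @export
#' @examples
#' sc <- progression_scenario(genotype_multipliers = c(Col0 = 1, mut = 1.5))
progression_scenario <- function(stage_rates = rep(0.14, 7),
                                 genotype_multipliers = c(Col0 = 1.0),
                                 initiation_intensity = 2.0,
                                 pr_length_mean_cm = 5.0,
                                 pr_length_sd_cm = 1.0,
                                 initiation_lag_h_mean = 6.0,
                                 observation_times_h = c(18, 42),
                                 n_roots = 30L,
                                 root_age_h = 96,
                                 seed = 1L) {
  if (length(stage_rates) != 7 || any(stage_rates <= 0)) {
    lrp_stop("stage_rates must be 7 positive per-hour rates", "lrp_config_error")
  }
  if (length(genotype_multipliers) == 0 || is.null(names(genotype_multipliers)) ||
      any(!nzchar(names(genotype_multipliers))) || any(genotype_multipliers <= 0)) {
    lrp_stop("genotype_multipliers must be a named vector of positive reals",
             "lrp_config_error")
  }
  if (initiation_intensity < 0) lrp_stop("initiation_intensity must be >= 0", "lrp_config_error")
  if (pr_length_mean_cm <= 0) lrp_stop("pr_length_mean_cm must be > 0", "lrp_config_error")
  if (initiation_lag_h_mean < 0) lrp_stop("initiation_lag_h_mean must be >= 0", "lrp_config_error")
  if (any(observation_times_h <= 0)) lrp_stop("observation times must be > 0", "lrp_config_error")
  if (n_roots < 1) lrp_stop("n_roots must be >= 1", "lrp_config_error")
  if (root_age_h <= 0) lrp_stop("root_age_h must be > 0", "lrp_config_error")
  structure(list(stage_rates = as.numeric(stage_rates),
                 genotype_multipliers = genotype_multipliers,
                 initiation_intensity = initiation_intensity,
                 pr_length_mean_cm = pr_length_mean_cm,
                 pr_length_sd_cm = pr_length_sd_cm,
                 initiation_lag_h_mean = initiation_lag_h_mean,
                 observation_times_h = as.numeric(observation_times_h),
                 n_roots = as.integer(n_roots),
                 root_age_h = root_age_h,
                 seed = as.integer(seed)),
            class = "progression_scenario")
}

#' Read a progression scenario from a YAML file
#'
#' The YAML keys mirror the arguments of [progression_scenario()];
#' `genotype_multipliers` is a mapping from genotype label to multiplier.
#' See `system.file("extdata", "scenario_example.yaml", package =
#' "lrpstage")` for a committed example.
#'
#' @param path Path to the YAML file.
#' @return A `"progression_scenario"`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) lrp_stop(sprintf("file not found: %s", path), "lrp_io_error")
  y <- yaml::read_yaml(path)
  if (!is.null(y$genotype_multipliers)) {
    y$genotype_multipliers <- unlist(y$genotype_multipliers)
  }
  known <- names(formals(progression_scenario))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    lrp_stop(sprintf("unknown scenario field(s): %s", paste(unknown, collapse = ", ")),
             "lrp_config_error")
  }
  do.call(progression_scenario, y)
}

# Cumulative stage-entry times for m LRPs: an m x 8 matrix whose column s is
# the time each LRP enters stage s (col 1 is 0 or the supplied lag; col 8 is
# entry into E). Dwell times are exponential at rates * mult.
stage_entry_times <- function(m, rates, mult, lag = rep(0, m)) {
  dwell <- matrix(stats::rexp(m * 7, rate = 1), nrow = m)
  dwell <- sweep(dwell, 2, rates * mult, "/")
  cbind(lag, lag + t(apply(dwell, 1, cumsum)))
}

# Stage index occupied at time t given entry-time rows: 0 = pre-initiation
# (NONE), 1..7 = stages I..VII, 8 = E (absorbing).
stage_at <- function(entry, t) {
  rowSums(entry <= t)
}

stage_label <- function(idx) {
  c("NONE", stage_levels())[idx + 1L]
}

#' Simulate the gravistimulation single-LRP induction assay
#'
#' Each seedling receives a gravistimulus at time 0; a single LRP initiates
#' after an exponential lag (mean `initiation_lag_h_mean`; immediately if
#' 0) and then progresses through stages I..VII to emergence (E, absorbing)
#' with exponential dwell times at `stage_rates * multiplier(genotype)`.
#' The stage occupied at each observation time is recorded; `NONE` marks a
#' seedling whose primordium had not initiated by that time.
#'
#' @param scenario A [progression_scenario()].
#' @param seed Optional seed overriding `scenario$seed`.
#' @return A `data.frame` of induced-LRP records: `seedling_id`,
#'   `genotype`, `observation_time_h`, `stage` — one row per seedling and
#'   observation time, matching the schema of [read_induced_table()].
#' @export
simulate_induced <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "progression_scenario"))
  set.seed(seed)
  genos <- names(scenario$genotype_multipliers)
  times <- sort(scenario$observation_times_h)
  out <- lapply(genos, function(g) {
    m <- scenario$n_roots
    mult <- scenario$genotype_multipliers[[g]]
    lag <- if (scenario$initiation_lag_h_mean > 0) {
      stats::rexp(m, rate = 1 / scenario$initiation_lag_h_mean)
    } else rep(0, m)
    entry <- stage_entry_times(m, scenario$stage_rates, mult, lag)
    do.call(rbind, lapply(times, function(t) {
      data.frame(seedling_id = sprintf("%s_s%03d", g, seq_len(m)),
                 genotype = g,
                 observation_time_h = t,
                 stage = stage_label(stage_at(entry, t)),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Simulate a whole-root LRP staging and density survey
#'
#' Emulates the static whole-root assay: per root, a primary-root length is
#' drawn (Normal truncated at 0), LRP initiations follow a Poisson process
#' along the root (`initiation_intensity` per cm), each LRP's age is
#' uniform on `[0, root_age_h]`, and its stage is the state of the
#' progression chain at that age (no initiation lag: age is measured from
#' initiation). Emerged LRs are the LRPs that reached E; their positions
#' are uniform along the PR.
#'
#' @inheritParams simulate_induced
#' @return A per-root observation `data.frame` with the schema of
#'   [read_root_table()] (including the `lr_positions_cm` list-column).
#' @export
simulate_whole_root <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "progression_scenario"))
  set.seed(seed)
  genos <- names(scenario$genotype_multipliers)
  sc_cols <- stage_cols()
  out <- lapply(genos, function(g) {
    mult <- scenario$genotype_multipliers[[g]]
    rows <- lapply(seq_len(scenario$n_roots), function(i) {
      len <- 0
      while (len <= 0) {
        len <- stats::rnorm(1, scenario$pr_length_mean_cm, scenario$pr_length_sd_cm)
      }
      n_lrp <- stats::rpois(1, scenario$initiation_intensity * len)
      counts <- integer(n_stages())
      pos <- numeric(0)
      if (n_lrp > 0) {
        ages <- stats::runif(n_lrp, 0, scenario$root_age_h)
        entry <- stage_entry_times(n_lrp, scenario$stage_rates, mult)
        idx <- rowSums(entry <= ages)  # stage index at each LRP's own age
        counts <- tabulate(idx, nbins = n_stages())
        n_e <- counts[n_stages()]
        if (n_e > 0) pos <- sort(stats::runif(n_e, 0, len))
      }
      df <- data.frame(root_id = sprintf("%s_r%03d", g, i), genotype = g,
                       pr_length_cm = len, emerged_count = counts[n_stages()],
                       stringsAsFactors = FALSE)
      df[sc_cols] <- as.list(counts)
      df$lr_positions_cm <- list(pos)
      df
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic dataset
#'
#' Runs both assay simulators under a single seed, so the whole pipeline
#' (ingestion, pooling, phenometrics, testing, recovery) can be exercised
#' end to end without external data.
#'
#' @inheritParams simulate_induced
#' @return A list of class `"simulated_dataset"`: `roots` (per-root
#'   observations), `induced` (induced-LRP records), `scenario`,
#'   `seed_used`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed) {
  roots <- simulate_whole_root(scenario, seed = seed)
  induced <- simulate_induced(scenario, seed = derive_seed(seed, 1L))
  structure(list(roots = roots, induced = induced, scenario = scenario,
                 seed_used = seed),
            class = "simulated_dataset")
}
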