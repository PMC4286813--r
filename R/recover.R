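# Generator matrix of the progression chain at a given multiplier, over the
# states (NONE,) I..VII, E. The NONE state is included only when the
# initiation lag is positive; its exit rate (1/lag_mean) is not scaled by
# the multiplier, matching the simulator.
progression_generator <- function(rates, mult, lag_mean = 0) {
  exit <- rates * mult
  if (lag_mean > 0) exit <- c(1 / lag_mean, exit)
  k <- length(exit) + 1          # + absorbing E
  Q <- matrix(0, k, k)
  for (s in seq_along(exit)) {
    Q[s, s] <- -exit[s]
    Q[s, s + 1] <- exit[s]
  }
  Q
}

# Occupancy probabilities over states at time t, starting in state 1.
occupancy_probs <- function(Q, t) {
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t, sparse = FALSE)))
  pmax(P[1, ], 0)
}

#' Recover a genotype's progression-rate multiplier from induced-assay data
#'
#' Maximum-likelihood estimation of the single multiplier scaling the
#' baseline stage dwell rates, from snapshot stage records of the
#' gravistimulation assay. The stage occupied at each observation time is a
#' phase-type snapshot of the linear progression chain; its occupancy
#' probabilities are computed by matrix exponential of the chain generator,
#' and the multiplier is found by 1-D numerical optimization of the
#' categorical log-likelihood over all records.
#'
#' @param induced Induced-LRP records (schema of [read_induced_table()]);
#'   typically one genotype's rows.
#' @param stage_rates The seven known baseline dwell rates (per hour).
#' @param lag_mean Known mean initiation lag (hours); 0 for none. Must
#'   match the process that produced the records — the lag rate is treated
#'   as known and is not scaled by the multiplier.
#' @param interval Search interval for the multiplier (default
#'   `c(1e-3, 1e3)`; optimization is on the log scale).
#' @return The multiplier MLE (a single positive number), with the
#'   maximized log-likelihood as attribute `"logLik"`.
#' @export
recover_multiplier <- function(induced, stage_rates, lag_mean = 0,
                               interval = c(1e-3, 1e3)) {
  if (length(stage_rates) != 7 || any(stage_rates <= 0)) {
    lrp_stop("stage_rates must be 7 positive rates", "lrp_config_error")
  }
  if (nrow(induced) == 0) lrp_stop("no records supplied", "lrp_insufficient_data_error")
  states <- if (lag_mean > 0) c("NONE", stage_levels()) else stage_levels()
  if (any(!(induced$stage %in% c(states, "NONE")))) {
    lrp_stop("records contain stage labels outside the ontology", "lrp_validation_error")
  }
  if (lag_mean == 0 && any(induced$stage == "NONE")) {
    lrp_stop("NONE records are impossible with lag_mean = 0", "lrp_validation_error")
  }
  if (all(induced$stage == "E") || all(induced$stage == "NONE")) {
    lrp_stop(paste("non-identifiable: every record is saturated at the same boundary",
                   "state, so the likelihood has no interior maximum"),
             "lrp_nonidentifiable_error")
  }
  tab <- table(time = induced$observation_time_h,
               stage = factor(induced$stage, levels = states))
  times <- as.numeric(rownames(tab))
  negll <- function(logm) {
    m <- exp(logm)
    Q1 <- progression_generator(stage_rates, m, lag_mean)
    ll <- 0
    for (j in seq_along(times)) {
      p <- occupancy_probs(Q1, times[j])
      cnt <- as.numeric(tab[j, ])
      if (any(cnt > 0 & p <= 0)) return(1e12)
      pos <- cnt > 0
      ll <- ll + sum(cnt[pos] * log(p[pos]))
    }
    -ll
  }
  opt <- stats::optimize(negll, interval = log(interval), tol = 1e-7)
  structure(exp(opt$minimum), logLik = -opt$objective)
}
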