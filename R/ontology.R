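#' The lateral root primordium stage ontology
#'
#' Lateral root primordia (LRPs) in Arabidopsis are scored into seven
#' morphological stages (I--VII, from the first anticlinal pericycle
#' divisions to the dome about to break through the epidermis), followed by
#' emergence. The emerged class, sometimes written "VIII", is labelled `"E"`
#' here. The ontology is fixed: every stage-count vector in this package has
#' exactly these eight ordered levels.
#'
#' @return Character vector of the eight ordered stage labels:
#'   `"I" "II" "III" "IV" "V" "VI" "VII" "E"`.
#' @seealso [early_stages()], [late_stages()], [stage_counts()]
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() {
  c("I", "II", "III", "IV", "V", "VI", "VII", "E")
}

#' @rdname stage_levels
#' @details `early_stages()` returns the early group (stages I--IV);
#'   `late_stages()` returns the late group (stage VII plus emerged), the
#'   two groupings used when summarizing shifts in developmental timing.
#' @export
early_stages <- function() c("I", "II", "III", "IV")

#' @rdname stage_levels
#' @export
late_stages <- function() c("VII", "E")

#' Number of stage levels in the ontology
#' @keywords internal
#' @noRd
n_stages <- function() 8L

# classed conditions -------------------------------------------------------

lrp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lrpstage_error")))
}

#' Construct a validated stage-count vector
#'
#' A stage-count vector holds the number of LRPs observed at each of the
#' eight ontology levels (see [stage_levels()]). Counts must be nonnegative
#' integers; the vector may be all zero (a root with no primordia is a legal
#' observation).
#'
#' @param counts Numeric vector of length 8, nonnegative integers. May be
#'   named; if named, names must be exactly the ontology levels (any order;
#'   reordered to canonical order). Unnamed vectors are taken to be in
#'   canonical order.
#' @return Named integer vector of length 8 in canonical stage order.
#' @export
#' @examples
#' stage_counts(c(2, 1, 0, 0, 0, 0, 1, 3))
stage_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) != n_stages()) {
    lrp_stop(sprintf("stage counts must be a numeric vector of length %d (one per ontology level)",
                     n_stages()),
             "lrp_validation_error")
  }
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), stage_levels())) {
      bad <- setdiff(names(counts), stage_levels())
      lrp_stop(sprintf("unknown stage label(s): %s (ontology is %s)",
                       paste(bad, collapse = ", "),
                       paste(stage_levels(), collapse = ", ")),
               "lrp_validation_error")
    }
    counts <- counts[stage_levels()]
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    lrp_stop("stage counts must be nonnegative integers", "lrp_validation_error")
  }
  counts <- as.integer(round(counts))
  names(counts) <- stage_levels()
  counts
}

#' Validate a probability vector over the stage ontology
#' @keywords internal
#' @noRd
check_probs <- function(probs, k = n_stages()) {
  if (!is.numeric(probs) || length(probs) != k || anyNA(probs) ||
      any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    lrp_stop(sprintf("probabilities must be %d nonnegative reals summing to 1", k),
             "lrp_domain_error")
  }
  invisible(probs)
}
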