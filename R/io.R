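stage_cols <- function() paste0("stage_", stage_levels())

root_table_cols <- function() {
  c("root_id", "genotype", "pr_length_cm", "emerged_count", stage_cols())
}

#' Read a per-root observation table
#'
#' Reads a tidy CSV of per-seedling root phenotypes: one row per root, with
#' the primary-root (PR) length, the emerged lateral root count, and the
#' number of LRPs scored at each developmental stage. Expected columns:
#' `root_id, genotype, pr_length_cm, emerged_count, stage_I ... stage_VII,
#' stage_E`, optionally followed by `lr_positions_cm` (semicolon-joined
#' positions of emerged LRs in cm from the root--shoot junction).
#'
#' Every row is validated: stage counts must be nonnegative integers,
#' `pr_length_cm` must be positive, `emerged_count` must equal `stage_E`,
#' and any LR positions must lie within `[0, pr_length_cm]`. Validation
#' failures report the offending data row number.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with one row per root: the schema columns above,
#'   plus `lr_positions_cm` as a list-column of numeric vectors (`NULL`
#'   where absent).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(root_id = "r1", genotype = "Col0", pr_length_cm = 5,
#'                      emerged_count = 2, stage_I = 1, stage_II = 0,
#'                      stage_III = 0, stage_IV = 0, stage_V = 0,
#'                      stage_VI = 0, stage_VII = 0, stage_E = 2),
#'           f, row.names = FALSE)
#' read_root_table(f)
read_root_table <- function(path) {
  if (!file.exists(path)) lrp_stop(sprintf("file not found: %s", path), "lrp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(root_table_cols(), names(df))
  if (length(missing) > 0) {
    lrp_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
             "lrp_schema_error")
  }
  extra <- setdiff(names(df), c(root_table_cols(), "lr_positions_cm"))
  stagey <- grep("^stage_", extra, value = TRUE)
  if (length(stagey) > 0) {
    lrp_stop(sprintf("stage column(s) outside the ontology: %s",
                     paste(stagey, collapse = ", ")),
             "lrp_schema_error")
  }
  has_pos <- "lr_positions_cm" %in% names(df)
  if (nrow(df) == 0) {
    df$lr_positions_cm <- list()
    return(df[, c(root_table_cols(), "lr_positions_cm")])
  }
  pos <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row_counts <- suppressWarnings(as.numeric(df[i, stage_cols()]))
    ok <- tryCatch({
      stage_counts(row_counts)
      TRUE
    }, lrpstage_error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      lrp_stop(sprintf("row %d: %s", i, ok), "lrp_validation_error")
    }
    if (is.na(df$pr_length_cm[i]) || df$pr_length_cm[i] <= 0) {
      lrp_stop(sprintf("row %d: pr_length_cm must be positive", i), "lrp_validation_error")
    }
    if (is.na(df$emerged_count[i]) || df$emerged_count[i] != df$stage_E[i]) {
      lrp_stop(sprintf("row %d: emerged_count (%s) must equal stage_E (%s)",
                       i, df$emerged_count[i], df$stage_E[i]),
               "lrp_validation_error")
    }
    if (has_pos && !is.na(df$lr_positions_cm[i]) && nzchar(df$lr_positions_cm[i])) {
      p <- as.numeric(strsplit(as.character(df$lr_positions_cm[i]), ";", fixed = TRUE)[[1]])
      if (anyNA(p) || any(p < 0) || any(p > df$pr_length_cm[i])) {
        lrp_stop(sprintf("row %d: LR positions must lie in [0, pr_length_cm]", i),
                 "lrp_validation_error")
      }
      pos[[i]] <- p
    }
  }
  for (col in c(stage_cols(), "emerged_count")) df[[col]] <- as.integer(df[[col]])
  df$lr_positions_cm <- pos
  df[, c(root_table_cols(), "lr_positions_cm")]
}

#' Read an induced-LRP record table
#'
#' Reads the gravistimulation assay table: one row per seedling and
#' observation time, recording the stage of the single induced LRP (or
#' `NONE` if no primordium had initiated by that time). Expected columns:
#' `seedling_id, genotype, observation_time_h, stage`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with the four schema columns; `stage` is a
#'   character vector over `stage_levels()` plus `"NONE"`.
#' @export
read_induced_table <- function(path) {
  if (!file.exists(path)) lrp_stop(sprintf("file not found: %s", path), "lrp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("seedling_id", "genotype", "observation_time_h", "stage")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    lrp_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
             "lrp_schema_error")
  }
  bad <- which(!(df$stage %in% c(stage_levels(), "NONE")))
  if (length(bad) > 0) {
    lrp_stop(sprintf("row %d: stage '%s' is not an ontology level or NONE",
                     bad[1], df$stage[bad[1]]),
             "lrp_validation_error")
  }
  bad_t <- which(is.na(df$observation_time_h) | df$observation_time_h <= 0)
  if (length(bad_t) > 0) {
    lrp_stop(sprintf("row %d: observation_time_h must be positive", bad_t[1]),
             "lrp_validation_error")
  }
  df[, req]
}

#' Pool per-root stage counts by genotype
#'
#' Sums the per-root stage-count vectors within each genotype, producing the
#' strain-level count tables that enter the two-sample stage-distribution
#' test. Roots with zero LRPs contribute zero counts but still count towards
#' `n_roots`.
#'
#' @param obs A per-root observation `data.frame` as returned by
#'   [read_root_table()] or [simulate_whole_root()].
#' @return A `data.frame` with one row per genotype: `genotype`, `n_roots`,
#'   and the eight `stage_*` columns of element-wise count sums.
#' @export
pool_by_genotype <- function(obs) {
  if (!is.data.frame(obs) || nrow(obs) == 0) {
    lrp_stop("need a nonempty per-root observation table", "lrp_validation_error")
  }
  sc <- stage_cols()
  split_idx <- split(seq_len(nrow(obs)), obs$genotype)
  out <- lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    sums <- vapply(sc, function(cl) sum(obs[[cl]][idx]), numeric(1))
    cbind(data.frame(genotype = g, n_roots = length(idx), stringsAsFactors = FALSE),
          as.data.frame(as.list(as.integer(sums)), col.names = sc))
  })
  do.call(rbind, out)
}

#' Extract one genotype's pooled stage-count vector
#'
#' @param pooled A pooled table from [pool_by_genotype()].
#' @param genotype Genotype label to extract.
#' @return Named integer stage-count vector (see [stage_counts()]).
#' @export
genotype_counts <- function(pooled, genotype) {
  i <- which(pooled$genotype == genotype)
  if (length(i) != 1) {
    lrp_stop(sprintf("genotype '%s' not found in pooled table", genotype),
             "lrp_validation_error")
  }
  cnt <- unlist(pooled[i, stage_cols()])
  names(cnt) <- stage_levels()
  stage_counts(cnt)
}

#' Write a result table to CSV
#'
#' Writes any tabular result with a deterministic column order and fixed
#' printed precision for floating-point columns, so written files
#' round-trip through `read.csv` and diff cleanly across runs.
#'
#' @param results A `data.frame`. List-columns (e.g. `lr_positions_cm`) are
#'   serialized as semicolon-joined values.
#' @param path Output path.
#' @param digits Number of significant digits for numeric (non-integer)
#'   columns (default 10).
#' @return Invisibly, the path written.
#' @export
write_result_table <- function(results, path, digits = 10) {
  if (!is.data.frame(results)) {
    lrp_stop("results must be a data.frame", "lrp_validation_error")
  }
  out <- results
  for (cl in names(out)) {
    if (is.list(out[[cl]])) {
      out[[cl]] <- vapply(out[[cl]], function(x) {
        if (is.null(x) || length(x) == 0) "" else paste(format(x, digits = digits, trim = TRUE), collapse = ";")
      }, character(1))
    } else if (is.double(out[[cl]])) {
      out[[cl]] <- vapply(out[[cl]], function(v) format(v, digits = digits, trim = TRUE),
                          character(1))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) conditionMessage(e), warning = function(w) conditionMessage(w))
  if (!isTRUE(ok)) lrp_stop(sprintf("cannot write '%s': %s", path, ok), "lrp_io_error")
  invisible(path)
}
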