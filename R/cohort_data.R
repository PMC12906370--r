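#' Merge per-cohort visit tables into one harmonization dataset
#'
#' Concatenates the per-cohort tables into a single [visit_table()] over the
#' shared catalog. Participant identifiers are prefixed with their cohort id
#' (`"<cohort>:<participant>"`) so they remain unique after pooling, and each
#' row keeps its dataset-of-origin identifier in `cohort_id`. Tests that a
#' cohort does not administer stay entirely missing in that cohort's rows
#' (structural missingness), which the result is verified against.
#'
#' @param cohort_tables List of [visit_table()] objects sharing one catalog,
#'   with pairwise-disjoint `cohort_id` values.
#' @param validate Verify the merged table's invariants, including
#'   structural missingness (default `TRUE`).
#' @return A merged [visit_table()].
#' @export
build_merged_table <- function(cohort_tables, validate = TRUE) {
  stopifnot(is.list(cohort_tables), length(cohort_tables) >= 1)
  for (tb in cohort_tables) stopifnot(inherits(tb, "visit_table"))
  cat0 <- vt_catalog(cohort_tables[[1]])
  for (tb in cohort_tables[-1]) {
    if (!identical(as.data.frame(vt_catalog(tb)), as.data.frame(cat0))) {
      stop("catalog mismatch: all cohort tables must share one catalog")
    }
  }
  cohort_sets <- lapply(cohort_tables, function(tb) unique(tb$data$cohort_id))
  all_cohorts <- unlist(cohort_sets)
  if (anyDuplicated(all_cohorts)) {
    stop("cohort_ids must be disjoint across input tables")
  }
  pieces <- lapply(cohort_tables, function(tb) {
    d <- tb$data
    d$participant_id <- paste(d$cohort_id, d$participant_id, sep = ":")
    d
  })
  all_cols <- unique(unlist(lapply(pieces, names)))
  pieces <- lapply(pieces, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
    d[, all_cols]
  })
  merged <- do.call(rbind, pieces)
  rownames(merged) <- NULL
  key <- paste(merged$participant_id, merged$visit_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, visit_index) pairs after merging")
  }
  visit_table(merged, cat0, validate = validate, check_structural = validate)
}

#' Assign clinical-pathological group labels
#'
#' Classifies participants into amyloid-by-CDR strata using the Centiloid
#' amyloid-PET value and the CDR global score. Amyloid positivity is a strict
#' `centiloid > 25` (a value of exactly 25 is negative). Amyloid-negative
#' participants with cognitive symptoms (CDR > 0), and anyone without a
#' Centiloid value, are excluded from group analyses.
#'
#' @param centiloid Numeric vector of Centiloid values (may contain `NA`).
#' @param cdr Numeric vector of CDR global scores in {0, 0.5, 1}.
#' @param threshold Centiloid positivity threshold (default 25).
#' @return Factor with levels `ABNEG_CDR0`, `ABPOS_CDR0`, `ABPOS_CDR05`,
#'   `ABPOS_CDR1`, `EXCLUDED`.
#' @examples
#' assign_group_label(c(26, 25, 10, NA), c(0, 0, 0.5, 0))
#' @export
assign_group_label <- function(centiloid, cdr, threshold = 25) {
  stopifnot(length(centiloid) == length(cdr))
  if (!all(cdr %in% c(0, 0.5, 1))) stop("cdr values must be 0, 0.5 or 1")
  pos <- !is.na(centiloid) & centiloid > threshold
  neg <- !is.na(centiloid) & centiloid <= threshold
  lab <- rep("EXCLUDED", length(centiloid))
  lab[pos & cdr == 0]   <- "ABPOS_CDR0"
  lab[pos & cdr == 0.5] <- "ABPOS_CDR05"
  lab[pos & cdr == 1]   <- "ABPOS_CDR1"
  lab[neg & cdr == 0]   <- "ABNEG_CDR0"
  factor(lab, levels = group_levels())
}

#' Group-label levels, reference group first
#' @return Character vector of the five labels.
#' @export
group_levels <- function() {
  c("ABNEG_CDR0", "ABPOS_CDR0", "ABPOS_CDR05", "ABPOS_CDR1", "EXCLUDED")
}

#' Per-participant group membership from baseline measures
#'
#' Group membership is time-invariant: the Centiloid value and CDR score at
#' each participant's first (baseline) visit determine the label for all of
#' that participant's visits.
#'
#' @param table A [visit_table()].
#' @param threshold Centiloid positivity threshold.
#' @return Data frame with `participant_id`, `cohort_id`, `group`.
#' @export
participant_groups <- function(table, threshold = 25) {
  d <- visits(table)
  base <- d[d$visit_index == 0, c("participant_id", "cohort_id", "centiloid", "cdr")]
  base$group <- assign_group_label(base$centiloid, base$cdr, threshold = threshold)
  base[, c("participant_id", "cohort_id", "group")]
}

#' Apply longitudinal inclusion criteria
#'
#' Drops (1) visits carrying no neuropsychological test score at all (rows
#' with demographics and CDR only), (2) participants whose `diagnosis` label
#' is outside `eligible_diagnoses` or missing (when a `diagnosis` column is
#' present), and (3) participants left with fewer than `min_assessments`
#' visits. `visit_index` and `time_years` are recomputed on the retained
#' visits so that each participant's first retained visit is visit 0 at time
#' 0.
#'
#' @param table A [visit_table()].
#' @param min_assessments Minimum number of retained visits per participant
#'   (default 3).
#' @param eligible_diagnoses Diagnosis labels compatible with the AD spectrum
#'   (used only when the table has a `diagnosis` column).
#' @return List with elements `table` (filtered [visit_table()]) and `log`
#'   (data frame of visits/participants removed per rule). Emits a warning,
#'   not an error, if nothing survives.
#' @export
apply_inclusion_criteria <- function(table, min_assessments = 3,
                                     eligible_diagnoses = c("CU", "MCI", "AD")) {
  d <- visits(table)
  sc <- score_columns(table)
  log_rows <- list()
  n_part <- function(x) length(unique(x$participant_id))

  # rule 1: visits with zero test scores
  has_score <- rowSums(!is.na(d[, sc, drop = FALSE])) > 0
  log_rows[["no_test_scores"]] <-
    data.frame(rule = "no_test_scores",
               visits_removed = sum(!has_score),
               participants_removed = 0L)
  d <- d[has_score, , drop = FALSE]

  # rule 2: diagnosis flag (per participant)
  if ("diagnosis" %in% names(d)) {
    diag <- tapply(as.character(d$diagnosis), d$participant_id,
                   function(z) z[!is.na(z)][1])
    drop_ids <- names(diag)[is.na(diag) | !(diag %in% eligible_diagnoses)]
    keep <- !(d$participant_id %in% drop_ids)
    log_rows[["diagnosis"]] <-
      data.frame(rule = "diagnosis",
                 visits_removed = sum(!keep),
                 participants_removed = length(drop_ids))
    d <- d[keep, , drop = FALSE]
  }

  # rule 3: minimum number of assessments
  n_visits <- table(d$participant_id)
  drop_ids <- names(n_visits)[n_visits < min_assessments]
  keep <- !(d$participant_id %in% drop_ids)
  log_rows[["min_assessments"]] <-
    data.frame(rule = "min_assessments",
               visits_removed = sum(!keep),
               participants_removed = length(drop_ids))
  d <- d[keep, , drop = FALSE]

  if (nrow(d) == 0) {
    warning("no visits remain after applying inclusion criteria")
  } else {
    # recompute visit_index and time_years from the retained visits
    ord <- order(d$participant_id, d$visit_index)
    d <- d[ord, , drop = FALSE]
    new_index <- stats::ave(seq_len(nrow(d)), d$participant_id,
                            FUN = seq_along) - 1L
    d$visit_index <- as.integer(new_index)
    t0 <- stats::ave(d$time_years, d$participant_id, FUN = min)
    d$time_years <- d$time_years - t0
    rownames(d) <- NULL
  }

  list(table = visit_table(d, vt_catalog(table), validate = nrow(d) > 0),
       log = do.call(rbind, c(log_rows, list(make.row.names = FALSE))))
}

#' Missing-data summary per test and CDR stratum
#'
#' For each test, the number of visits with an available score (`n`) and the
#' missing-data rate `100 * (N - n) / N`, where `N` is the number of visits
#' in scope; reported for all visits together and within each CDR stratum,
#' with an `(average)` row per stratum averaging the per-test rates.
#'
#' @param table A [visit_table()].
#' @param by_cohort Also stratify by cohort (columns appear per cohort in
#'   long format).
#' @return Data frame with columns `stratum`, `cohort_id`, `test_id`,
#'   `n_visits`, `n_available`, `pct_missing`.
#' @export
missingness_summary <- function(table, by_cohort = TRUE) {
  d <- visits(table)
  sc <- score_columns(table)
  strata <- list(all = rep(TRUE, nrow(d)),
                 cdr_0 = d$cdr == 0,
                 cdr_0.5 = d$cdr == 0.5,
                 cdr_1 = d$cdr == 1)
  cohorts <- if (by_cohort) c("(merged)", sort(unique(d$cohort_id)))
             else "(merged)"
  out <- list()
  for (s in names(strata)) {
    for (co in cohorts) {
      in_scope <- strata[[s]] & (co == "(merged)" | d$cohort_id == co)
      N <- sum(in_scope)
      if (N == 0) next
      n_avail <- vapply(sc, function(t) sum(!is.na(d[[t]][in_scope])), 0L)
      pct <- 100 * (N - n_avail) / N
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, cohort_id = co,
        test_id = c(sc, "(average)"),
        n_visits = N,
        n_available = c(n_avail, round(mean(n_avail))),
        pct_missing = c(pct, mean(pct)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
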