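#' Longitudinal participant-visit table over a test catalog
#'
#' A `visit_table` holds one row per participant-visit with identifiers,
#' demographics, clinical status, amyloid burden, and one numeric column per
#' catalogued test. Missing scores are `NA`. The merged multi-cohort dataset
#' is itself a `visit_table` whose `cohort_id` column records the dataset of
#' origin.
#'
#' Required columns of `data`: `participant_id`, `cohort_id`, `visit_index`
#' (0-based, ordered by time within participant), `time_years` (years since
#' the participant's first included visit), `age_years`, `sex`
#' (`"female"`/`"male"`), `education_years`, `apoe4`
#' (`"carrier"`/`"non-carrier"`), `cdr` (0, 0.5 or 1, where 1 encodes CDR >=
#' 1), `centiloid` (numeric, may be `NA`), plus one column per catalog test.
#' An optional `diagnosis` column carries a per-participant diagnosis label
#' used by [apply_inclusion_criteria()].
#'
#' @param data Data frame of visits as described above.
#' @param catalog A [test_catalog()].
#' @param validate Check the table invariants (uniqueness of
#'   `(participant_id, visit_index)`, a single cohort per participant,
#'   `time_years` anchored at 0 for visit 0, scores within catalog ranges,
#'   valid `cdr` values). Disable only for tables that legitimately break a
#'   constraint, e.g. an imputed table whose unclipped predictions may sit
#'   slightly outside a catalog range.
#' @param check_structural Additionally require that every test is entirely
#'   missing in cohorts that do not administer it. Off by default because a
#'   harmonized (imputed) table intentionally violates it.
#'
#' @return An object of class `visit_table`: a list with elements `data`
#'   (data frame) and `catalog`.
#' @export
visit_table <- function(data, catalog, validate = TRUE, check_structural = FALSE) {
  stopifnot(inherits(catalog, "test_catalog"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("participant_id", "cohort_id", "visit_index", "time_years",
                "age_years", "sex", "education_years", "apoe4", "cdr",
                "centiloid")
  missing_cols <- setdiff(c(required, catalog_tests(catalog)), names(data))
  if (length(missing_cols) > 0) {
    stop("visit table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data$participant_id <- as.character(data$participant_id)
  data$cohort_id <- as.character(data$cohort_id)
  data$visit_index <- as.integer(data$visit_index)
  for (col in c("time_years", "age_years", "education_years", "cdr",
                "centiloid", catalog_tests(catalog))) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data$sex <- as.character(data$sex)
  data$apoe4 <- as.character(data$apoe4)

  x <- structure(list(data = data, catalog = catalog), class = "visit_table")
  if (validate) validate_visit_table(x, check_structural = check_structural)
  x
}

#' Validate visit-table invariants
#'
#' @param x A [visit_table()].
#' @inheritParams visit_table
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_visit_table <- function(x, check_structural = FALSE) {
  stopifnot(inherits(x, "visit_table"))
  d <- x$data
  key <- paste(d$participant_id, d$visit_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, visit_index) pairs in visit table")
  }
  n_cohorts <- tapply(d$cohort_id, d$participant_id,
                      function(z) length(unique(z)))
  if (any(n_cohorts > 1)) {
    stop("participant(s) appear in more than one cohort: ",
         paste(utils::head(names(n_cohorts)[n_cohorts > 1], 3), collapse = ", "))
  }
  if (any(d$time_years < 0, na.rm = TRUE)) stop("time_years must be >= 0")
  t0 <- d$time_years[d$visit_index == 0]
  if (any(abs(t0) > 1e-8, na.rm = TRUE)) {
    stop("time_years must be 0 at visit_index 0")
  }
  if (!all(d$cdr %in% c(0, 0.5, 1) | is.na(d$cdr))) {
    stop("cdr values must be 0, 0.5 or 1")
  }
  cat <- x$catalog
  for (i in seq_len(nrow(cat))) {
    v <- d[[cat$test_id[i]]]
    obs <- v[!is.na(v)]
    if (length(obs) > 0 &&
        (min(obs) < cat$score_min[i] - 1e-8 ||
         max(obs) > cat$score_max[i] + 1e-8)) {
      stop("scores outside catalog range for test: ", cat$test_id[i])
    }
    if (check_structural) {
      adm <- administered_in(cat, cat$test_id[i])
      off_panel <- !(d$cohort_id %in% adm)
      if (any(!is.na(v[off_panel]))) {
        stop("structural-missingness violation: observed ", cat$test_id[i],
             " scores in a cohort that does not administer it")
      }
    }
  }
  invisible(x)
}

#' Visit rows of a table
#' @param x A [visit_table()].
#' @return The underlying data frame.
#' @export
visits <- function(x) {
  stopifnot(inherits(x, "visit_table"))
  x$data
}

#' Catalog of a visit table
#' @param x A [visit_table()].
#' @return The [test_catalog()].
#' @export
vt_catalog <- function(x) {
  stopifnot(inherits(x, "visit_table"))
  x$catalog
}

#' Score columns of a visit table
#' @param x A [visit_table()].
#' @return Character vector of test-score column names.
#' @export
score_columns <- function(x) catalog_tests(vt_catalog(x))

#' @export
print.visit_table <- function(x, ...) {
  d <- x$data
  cat("Visit table:", nrow(d), "visits,",
      length(unique(d$participant_id)), "participants,",
      length(unique(d$cohort_id)), "cohort(s),",
      nrow(x$catalog), "tests\n")
  sc <- as.matrix(d[, score_columns(x), drop = FALSE])
  cat(sprintf("Missing scores: %.1f%%\n", 100 * mean(is.na(sc))))
  invisible(x)
}

#' Read / write a visit table as delimited text
#'
#' Plain CSV with a header row; missing values are written as empty fields
#' and both empty fields and the literal string `"NA"` are read back as
#' missing.
#'
#' @param path File path of the visits CSV.
#' @param catalog A [test_catalog()] describing the score columns.
#' @param ... Passed to [visit_table()] (e.g. `validate`).
#' @return `read_visits()` returns a [visit_table()]; `write_visits()`
#'   returns `path` invisibly.
#' @export
read_visits <- function(path, catalog, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  visit_table(df, catalog, ...)
}

#' @rdname read_visits
#' @param x A [visit_table()].
#' @export
write_visits <- function(x, path) {
  stopifnot(inherits(x, "visit_table"))
  utils::write.csv(x$data, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}
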