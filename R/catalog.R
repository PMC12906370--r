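#' Construct a test catalog
#'
#' A test catalog declares, for every neuropsychological test that can appear
#' in a visit table, its score range, scoring direction, cognitive domain,
#' discreteness, and the set of cohorts that administer it. Tests absent from
#' a cohort's panel are structurally missing (100% missing by design) in that
#' cohort and become imputation targets during harmonization.
#'
#' @param specs A data frame with one row per test and columns `test_id`,
#'   `domain` (one of `"episodic_memory"`, `"executive_function"`,
#'   `"language"`, `"global"`), `direction` (+1 if higher scores mean better
#'   performance, -1 for time- or error-scored tests), `score_min`,
#'   `score_max`, `discrete` (logical; integer-valued score), and `cohorts`
#'   (semicolon-separated cohort identifiers administering the test).
#'
#' @return An object of class `test_catalog` (a validated data frame).
#' @seealso [default_catalog()], [read_catalog()], [write_catalog()]
#' @export
test_catalog <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  required <- c("test_id", "domain", "direction", "score_min", "score_max",
                "discrete", "cohorts")
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols) > 0) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  specs <- specs[, required]
  specs$test_id <- as.character(specs$test_id)
  specs$domain <- as.character(specs$domain)
  specs$direction <- as.integer(specs$direction)
  specs$score_min <- as.numeric(specs$score_min)
  specs$score_max <- as.numeric(specs$score_max)
  specs$discrete <- as.logical(specs$discrete)
  specs$cohorts <- as.character(specs$cohorts)

  if (anyDuplicated(specs$test_id)) {
    stop("duplicate test_id in catalog: ",
         paste(unique(specs$test_id[duplicated(specs$test_id)]), collapse = ", "))
  }
  valid_domains <- c("episodic_memory", "executive_function", "language", "global")
  bad <- setdiff(unique(specs$domain), valid_domains)
  if (length(bad) > 0) stop("unknown domain(s): ", paste(bad, collapse = ", "))
  if (!all(specs$direction %in% c(-1L, 1L))) {
    stop("direction must be +1 or -1")
  }
  if (any(!(specs$score_min < specs$score_max))) {
    stop("score_min must be strictly less than score_max for every test")
  }
  if (any(!nzchar(specs$cohorts) | is.na(specs$cohorts))) {
    stop("every test must be administered in at least one cohort")
  }
  rownames(specs) <- NULL
  class(specs) <- c("test_catalog", "data.frame")
  specs
}

#' Default 16-test catalog for a three-cohort harmonization
#'
#' Encodes the test battery of a three-cohort merged design (cohort
#' identifiers `"aibl"`, `"adni"`, `"oasis"`): published raw-score ranges,
#' scoring direction (TMT-B is time-scored, so higher is worse), a single
#' cognitive domain per test, and the per-cohort administration pattern that
#' produces structural missingness when the cohorts are merged. MMSE is
#' treated as a global screening measure so it can enter the PACC composite.
#'
#' @return A [test_catalog()] with 16 tests.
#' @export
default_catalog <- function() {
  specs <- data.frame(
    test_id = c("mmse", "lmii",
                "ravlt_total", "ravlt_delayed", "ravlt_recognition",
                "cvlt_total", "cvlt_delayed", "cvlt_recognition",
                "srt_free", "tmt_b", "digit_symbol",
                "digit_span_f", "digit_span_b",
                "bnt", "category_fluency", "fluency_switching"),
    domain = c("global", "episodic_memory",
               "episodic_memory", "episodic_memory", "episodic_memory",
               "episodic_memory", "episodic_memory", "episodic_memory",
               "episodic_memory", "executive_function", "executive_function",
               "executive_function", "executive_function",
               "language", "language", "executive_function"),
    direction = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L, 1L, 1L, 1L, 1L, 1L, 1L),
    score_min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0, 0),
    score_max = c(30, 25, 75, 15, 15, 80, 16, 16, 48, 300, 127, 16, 14, 30, 60, 24),
    discrete = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    cohorts = c("aibl;adni;oasis",      # mmse
                "aibl;adni;oasis",      # lmii
                "adni",                 # ravlt_total
                "adni",                 # ravlt_delayed
                "adni",                 # ravlt_recognition
                "aibl",                 # cvlt_total
                "aibl",                 # cvlt_delayed
                "aibl",                 # cvlt_recognition
                "oasis",                # srt_free
                "adni;oasis",           # tmt_b
                "aibl",                 # digit_symbol
                "aibl;adni;oasis",      # digit_span_f
                "aibl;adni;oasis",      # digit_span_b
                "aibl;adni;oasis",      # bnt
                "aibl;adni;oasis",      # category_fluency
                "aibl"),                # fluency_switching
    stringsAsFactors = FALSE
  )
  test_catalog(specs)
}

#' Cohorts administering a test
#'
#' @param catalog A [test_catalog()].
#' @param test_id Test identifier.
#' @return Character vector of cohort identifiers.
#' @export
administered_in <- function(catalog, test_id) {
  stopifnot(inherits(catalog, "test_catalog"))
  i <- match(test_id, catalog$test_id)
  if (is.na(i)) stop("unknown test_id: ", test_id)
  strsplit(catalog$cohorts[i], ";", fixed = TRUE)[[1]]
}

#' Test identifiers in a catalog
#' @param catalog A [test_catalog()].
#' @return Character vector of test ids, in catalog order.
#' @export
catalog_tests <- function(catalog) {
  stopifnot(inherits(catalog, "test_catalog"))
  catalog$test_id
}

#' All cohort identifiers referenced by a catalog
#' @param catalog A [test_catalog()].
#' @return Character vector of cohort ids.
#' @export
catalog_cohorts <- function(catalog) {
  stopifnot(inherits(catalog, "test_catalog"))
  sort(unique(unlist(strsplit(catalog$cohorts, ";", fixed = TRUE))))
}

#' Read / write a test catalog as delimited text
#'
#' The on-disk format is a plain CSV with a header row and columns `test_id`,
#' `domain`, `direction`, `score_min`, `score_max`, `discrete`, `cohorts`
#' (semicolon-separated).
#'
#' @param path File path.
#' @return `read_catalog()` returns a [test_catalog()]; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  test_catalog(df)
}

#' @rdname read_catalog
#' @param catalog A [test_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "test_catalog"))
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.test_catalog <- function(x, ...) {
  cat("Test catalog:", nrow(x), "tests across",
      length(catalog_cohorts(x)), "cohorts\n")
  print.data.frame(x, ...)
  invisible(x)
}
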