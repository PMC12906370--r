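#' Composite-score definitions
#'
#' A composite is the unweighted mean of standardized member-test scores.
#' The defaults follow the common clinical-trial and domain constructions:
#' PACC (MMSE, Logical Memory II, list-learning delayed recall, digit symbol
#' coding), episodic memory (LMII, CVLT-II delayed recall), executive
#' function (TMT-B, digit symbol coding), and language (Boston Naming Test,
#' category fluency). Apart from the PACC, no test belongs to more than one
#' domain composite.
#'
#' @param name Composite name.
#' @param members Character vector of member test ids.
#' @return A list of class `composite_spec`.
#' @export
composite_spec <- function(name, members) {
  stopifnot(nzchar(name), length(members) >= 1)
  structure(list(name = name, members = as.character(members)),
            class = "composite_spec")
}

#' @rdname composite_spec
#' @param catalog A [test_catalog()]; membership is checked against it.
#' @return `default_composites()`: named list of four `composite_spec`s.
#' @export
default_composites <- function(catalog = default_catalog()) {
  specs <- list(
    pacc = composite_spec("pacc",
                          c("mmse", "lmii", "cvlt_delayed", "digit_symbol")),
    episodic_memory = composite_spec("episodic_memory",
                                     c("lmii", "cvlt_delayed")),
    executive_function = composite_spec("executive_function",
                                        c("tmt_b", "digit_symbol")),
    language = composite_spec("language", c("bnt", "category_fluency"))
  )
  validate_composites(specs, catalog)
  specs
}

validate_composites <- function(specs, catalog) {
  members <- lapply(specs, `[[`, "members")
  unknown <- setdiff(unlist(members), catalog_tests(catalog))
  if (length(unknown) > 0) {
    stop("composite member(s) not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  domain_members <- unlist(members[names(specs) != "pacc"])
  if (anyDuplicated(domain_members)) {
    stop("a test may not belong to more than one domain composite: ",
         paste(unique(domain_members[duplicated(domain_members)]),
               collapse = ", "))
  }
  invisible(specs)
}

#' Baseline norms from the cognitively unimpaired reference group
#'
#' Computes, for each test, the mean and sample SD (n - 1 denominator) of
#' baseline (visit 0) scores in the cognitively unimpaired reference group.
#' By default the reference is everyone with CDR 0 at baseline, irrespective
#' of amyloid status; `reference = "cu_abneg"` restricts to amyloid-negative
#' CU participants. Norms are intended to be fit on the harmonized
#' (post-imputation) table so that structurally imputed tests have defined
#' norms in every cohort.
#'
#' @param table A complete (harmonized) [visit_table()].
#' @param reference `"cu"` (CDR 0 at baseline) or `"cu_abneg"` (additionally
#'   Centiloid <= 25).
#' @param tests Tests to norm (default: all catalog tests).
#' @return Data frame of class `baseline_norms`: `test_id`, `mean`, `sd`,
#'   `n`. Errors if a test has a zero or undefined SD in the reference.
#' @export
fit_baseline_norms <- function(table, reference = c("cu", "cu_abneg"),
                               tests = NULL) {
  reference <- match.arg(reference)
  d <- visits(table)
  if (is.null(tests)) tests <- score_columns(table)
  base <- d[d$visit_index == 0 & d$cdr == 0, , drop = FALSE]
  if (reference == "cu_abneg") {
    base <- base[!is.na(base$centiloid) & base$centiloid <= 25, , drop = FALSE]
  }
  if (nrow(base) == 0) stop("empty reference group for baseline norms")
  rows <- lapply(tests, function(t) {
    v <- base[[t]][!is.na(base[[t]])]
    if (length(v) < 2) {
      stop("degenerate norm for test ", t, ": fewer than 2 reference values")
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate norm for test ", t, ": zero reference SD")
    }
    data.frame(test_id = t, mean = mean(v), sd = s, n = length(v),
               stringsAsFactors = FALSE)
  })
  norms <- do.call(rbind, rows)
  rownames(norms) <- NULL
  class(norms) <- c("baseline_norms", "data.frame")
  norms
}

#' Standardize raw scores against baseline norms
#'
#' `z = direction * (score - mean) / sd`, so that higher standardized scores
#' always mean better performance: the sign is reversed for time- or
#' error-scored tests (direction -1, e.g. TMT-B).
#'
#' @param score Numeric vector of raw scores.
#' @param test_id Test identifier (scalar).
#' @param norms A [fit_baseline_norms()] result.
#' @param catalog A [test_catalog()] supplying the direction.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(score, test_id, norms, catalog) {
  i <- match(test_id, norms$test_id)
  if (is.na(i)) stop("no norms for test ", test_id)
  j <- match(test_id, catalog$test_id)
  if (is.na(j)) stop("test not in catalog: ", test_id)
  catalog$direction[j] * (score - norms$mean[i]) / norms$sd[i]
}

#' Compute per-visit composite scores from a harmonized table
#'
#' Standardizes each member test against the baseline norms and averages the
#' member z-scores (unweighted) per visit. Requires complete member scores,
#' i.e. a post-imputation table. The result carries the participant's
#' clinical-pathological group label and the covariates needed for
#' trajectory modelling, including baseline age.
#'
#' @param table A complete [visit_table()].
#' @param specs List of [composite_spec()]s (default [default_composites()]).
#' @param norms A [fit_baseline_norms()] result covering all member tests.
#' @return Data frame keyed by `(participant_id, visit_index)` with
#'   `time_years`, `cohort_id`, `group`, `age_baseline`, `sex`,
#'   `education_years`, `apoe4`, `cdr`, and one column per composite.
#' @export
composite_scores <- function(table, specs = NULL, norms) {
  d <- visits(table)
  cat <- vt_catalog(table)
  if (is.null(specs)) specs <- default_composites(cat)
  validate_composites(specs, cat)
  members <- unique(unlist(lapply(specs, `[[`, "members")))
  for (t in members) {
    if (anyNA(d[[t]])) {
      stop("missing ", t, " scores: composites are defined on harmonized ",
           "(complete) data only")
    }
  }
  grp <- participant_groups(table)
  out <- d[, c("participant_id", "cohort_id", "visit_index", "time_years",
               "age_years", "sex", "education_years", "apoe4", "cdr")]
  out$group <- grp$group[match(out$participant_id, grp$participant_id)]
  age0 <- d$age_years[d$visit_index == 0]
  names(age0) <- d$participant_id[d$visit_index == 0]
  out$age_baseline <- as.numeric(age0[out$participant_id])
  z <- sapply(members, function(t) standardize(d[[t]], t, norms, cat))
  for (s in specs) {
    out[[s$name]] <- rowMeans(z[, s$members, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Read / write baseline norms as delimited text
#' @param path File path.
#' @return `read_norms()` returns a `baseline_norms` data frame.
#' @export
read_norms <- function(path) {
  norms <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("test_id", "mean", "sd", "n") %in% names(norms)))
  class(norms) <- c("baseline_norms", "data.frame")
  norms
}

#' @rdname read_norms
#' @param norms A `baseline_norms` data frame.
#' @export
write_norms <- function(norms, path) {
  utils::write.csv(as.data.frame(norms), path, row.names = FALSE)
  invisible(path)
}
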