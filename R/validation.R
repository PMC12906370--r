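#' Plan for the mask-and-reimpute precision protocol
#'
#' @param tests Test ids to evaluate.
#' @param mask_fraction Proportion of observed values to withhold per test
#'   (default 0.30).
#' @param n_repeats Number of independent masking repeats per test
#'   (default 50).
#' @param master_seed Master seed; per-test, per-repeat seeds are derived
#'   deterministically from it.
#' @return A list of class `holdout_plan`.
#' @export
holdout_plan <- function(tests, mask_fraction = 0.30, n_repeats = 50,
                         master_seed = 1) {
  stopifnot(length(tests) >= 1, mask_fraction > 0, mask_fraction < 1,
            n_repeats >= 1)
  structure(list(tests = as.character(tests),
                 mask_fraction = mask_fraction,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "holdout_plan")
}

# run expr with a private RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

validation_seed <- function(master_seed, test_id, repeat_index) {
  h <- sum(utf8ToInt(test_id) * seq_along(utf8ToInt(test_id)))
  as.integer((as.numeric(master_seed) + 211 * h + repeat_index) %% 2147483647)
}

#' Withhold a random subset of one test's observed scores
#'
#' Masks exactly `round(fraction * n_observed)` (round half up, so "at least
#' 30%" never drops below the floor) observed entries of `test_id`, chosen
#' uniformly without replacement. All other columns are untouched, and the
#' withheld values are returned with their row positions so they can be
#' compared against re-imputed values.
#'
#' @param table A [visit_table()].
#' @param test_id Test to mask.
#' @param fraction Proportion of observed values to withhold.
#' @param seed Seed for the mask draw.
#' @return List with `masked` (the [visit_table()] with values withheld) and
#'   `truth` (data frame `row`, `value` of the withheld entries).
#' @export
simulate_missing <- function(table, test_id, fraction = 0.30, seed = 1) {
  d <- visits(table)
  if (!test_id %in% score_columns(table)) stop("unknown test_id: ", test_id)
  obs_rows <- which(!is.na(d[[test_id]]))
  m <- floor(fraction * length(obs_rows) + 0.5)
  if (m < 1 || m > length(obs_rows)) {
    stop("infeasible mask fraction for test ", test_id, ": ",
         length(obs_rows), " observed values, ", m, " requested")
  }
  masked_rows <- with_seed(seed, sort(sample(obs_rows, m)))
  truth <- data.frame(row = masked_rows, value = d[[test_id]][masked_rows])
  d[[test_id]][masked_rows] <- NA_real_
  list(masked = visit_table(d, vt_catalog(table), validate = FALSE),
       truth = truth)
}

#' Mean absolute error between withheld and imputed values
#'
#' @param truth,imputed Numeric vectors of equal positive length.
#' @return Mean of `abs(imputed - truth)`.
#' @export
mae <- function(truth, imputed) {
  if (length(truth) != length(imputed)) stop("length mismatch")
  if (length(truth) == 0) stop("empty input")
  mean(abs(imputed - truth))
}

#' Percentage of imputed values beyond 2.5 SD of their true values
#'
#' An imputed score counts as an outlier when it lies more than `2.5 *
#' sd_actual` from the withheld true value, with `sd_actual` the SD of the
#' test's observed values in the full (unmasked) table.
#'
#' @param truth,imputed Numeric vectors of equal length.
#' @param sd_actual SD of the test's observed score distribution (> 0).
#' @return Percentage in \[0, 100\].
#' @export
outlier_rate <- function(truth, imputed, sd_actual) {
  if (length(truth) != length(imputed)) stop("length mismatch")
  stopifnot(sd_actual > 0)
  100 * mean(abs(imputed - truth) > 2.5 * sd_actual)
}

#' Test-retest maximum discrepancy in stable participants
#'
#' For each cognitively unimpaired amyloid-negative participant (group
#' `ABNEG_CDR0` with CDR 0 at every visit) with at least two observed scores
#' on a test, the difference between their highest and lowest observed
#' scores. Because these participants are expected to be cognitively stable,
#' the mean of this statistic estimates natural test-retest variability and
#' serves as the benchmark against which imputation MAE is judged.
#'
#' @param table A [visit_table()] (pre-imputation: observed scores only).
#' @param test_id Test to summarize.
#' @return List with `per_participant` (data frame `participant_id`,
#'   `discrepancy`), `mean`, `sd`, `min`, `max`, `n`. Warns (with `NA`
#'   summaries) when no participant qualifies.
#' @export
max_discrepancy <- function(table, test_id) {
  d <- visits(table)
  if (!test_id %in% score_columns(table)) stop("unknown test_id: ", test_id)
  grp <- participant_groups(table)
  cu <- grp$participant_id[grp$group == "ABNEG_CDR0"]
  always_cdr0 <- tapply(d$cdr, d$participant_id, function(z) all(z == 0))
  cu <- cu[cu %in% names(always_cdr0)[always_cdr0]]
  sub <- d[d$participant_id %in% cu & !is.na(d[[test_id]]),
           c("participant_id", test_id)]
  counts <- table(sub$participant_id)
  keep <- names(counts)[counts >= 2]
  sub <- sub[sub$participant_id %in% keep, ]
  if (nrow(sub) == 0) {
    warning("no qualifying CU amyloid-negative participants for test ", test_id)
    return(list(per_participant = data.frame(participant_id = character(),
                                             discrepancy = numeric()),
                mean = NA_real_, sd = NA_real_, min = NA_real_,
                max = NA_real_, n = 0L))
  }
  disc <- tapply(sub[[test_id]], sub$participant_id,
                 function(z) max(z) - min(z))
  per <- data.frame(participant_id = names(disc),
                    discrepancy = as.numeric(disc),
                    stringsAsFactors = FALSE)
  list(per_participant = per,
       mean = mean(per$discrepancy),
       sd = stats::sd(per$discrepancy),
       min = min(per$discrepancy),
       max = max(per$discrepancy),
       n = nrow(per))
}

#' Run the mask-and-reimpute precision protocol
#'
#' For each test in the plan, and independently for each repeat: a random 30%
#' (by default) of the test's observed values are withheld, the entire table
#' is re-imputed (all missing scores, not just the masked column), and the
#' imputed values at the withheld positions are scored with [mae()] and
#' [outlier_rate()]. Repeats are aggregated as mean +/- SD. Each test's
#' report also carries the catalog range, the observed-score mean/SD, and the
#' [max_discrepancy()] benchmark over stable amyloid-negative participants.
#' Tests are masked one at a time; the other tests keep their original
#' observed values.
#'
#' @param table The merged (pre-imputation) [visit_table()].
#' @param plan A [holdout_plan()].
#' @param config An [imputation_config()] for the default imputer.
#' @param imputer Optional function `(masked_table, seed) -> completed
#'   visit_table` replacing the default [impute()] call; used to calibrate
#'   the harness with oracle imputers.
#' @return A data frame of class `validation_report`, one row per test, with
#'   columns `test_id`, `range_min`, `range_max`, `actual_mean`, `actual_sd`,
#'   `maxdisc_mean`, `maxdisc_sd`, `maxdisc_min`, `maxdisc_max`, `n_masked`,
#'   `n_failed`, `mae_mean`, `mae_sd`, `outlier_pct_mean`, `outlier_pct_sd`,
#'   `mae_le_maxdisc`, `outlier_lt_5pct`. Per-repeat values are attached as
#'   attribute `"repeats"`. Failed repeats are recorded, not fatal.
#' @export
run_validation <- function(table, plan, config = imputation_config(),
                           imputer = NULL) {
  stopifnot(inherits(table, "visit_table"), inherits(plan, "holdout_plan"))
  validate_visit_table(table)
  if (is.null(imputer)) {
    imputer <- function(masked_table, seed) {
      cfg <- config
      cfg$seed <- seed
      impute(masked_table, config = cfg)$completed
    }
  }
  d <- visits(table)
  rows <- list()
  repeat_rows <- list()
  for (test_id in plan$tests) {
    obs <- d[[test_id]][!is.na(d[[test_id]])]
    sd_actual <- stats::sd(obs)
    md <- max_discrepancy(table, test_id)
    maes <- rep(NA_real_, plan$n_repeats)
    outs <- rep(NA_real_, plan$n_repeats)
    n_masked <- NA_integer_
    for (r in seq_len(plan$n_repeats)) {
      seed_r <- validation_seed(plan$master_seed, test_id, r)
      res <- tryCatch({
        sim <- simulate_missing(table, test_id, plan$mask_fraction,
                                seed = seed_r)
        completed <- imputer(sim$masked, seed_r + 10000L)
        imp <- visits(completed)[[test_id]][sim$truth$row]
        if (anyNA(imp)) stop("imputer left masked values missing")
        list(mae = mae(sim$truth$value, imp),
             out = outlier_rate(sim$truth$value, imp, sd_actual),
             n = nrow(sim$truth))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("repeat ", r, " failed for test ", test_id, ": ",
                conditionMessage(res))
      } else {
        maes[r] <- res$mae
        outs[r] <- res$out
        n_masked <- res$n
      }
      repeat_rows[[length(repeat_rows) + 1L]] <-
        data.frame(test_id = test_id, repeat_index = r,
                   mae = maes[r], outlier_pct = outs[r],
                   failed = inherits(res, "error"))
    }
    ok <- !is.na(maes)
    i <- match(test_id, vt_catalog(table)$test_id)
    rows[[test_id]] <- data.frame(
      test_id = test_id,
      range_min = vt_catalog(table)$score_min[i],
      range_max = vt_catalog(table)$score_max[i],
      actual_mean = mean(obs), actual_sd = sd_actual,
      maxdisc_mean = md$mean, maxdisc_sd = md$sd,
      maxdisc_min = md$min, maxdisc_max = md$max,
      n_masked = n_masked, n_failed = sum(!ok),
      mae_mean = mean(maes[ok]), mae_sd = stats::sd(maes[ok]),
      outlier_pct_mean = mean(outs[ok]), outlier_pct_sd = stats::sd(outs[ok]),
      stringsAsFactors = FALSE)
    rows[[test_id]]$mae_le_maxdisc <-
      !is.na(md$mean) && rows[[test_id]]$mae_mean <= md$mean
    rows[[test_id]]$outlier_lt_5pct <- rows[[test_id]]$outlier_pct_mean < 5
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "repeats") <- do.call(rbind, repeat_rows)
  attr(report, "plan") <- plan
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Hold-out validation report (", nrow(x), " tests, ",
      attr(x, "plan")$n_repeats, " repeats, mask fraction ",
      attr(x, "plan")$mask_fraction, ")\n", sep = "")
  cols <- c("test_id", "actual_mean", "actual_sd", "maxdisc_mean",
            "mae_mean", "mae_sd", "outlier_pct_mean")
  print.data.frame(format(as.data.frame(x)[, cols], digits = 3), ...)
  invisible(x)
}
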