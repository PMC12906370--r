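#' Configuration for the iterative random-forest imputer
#'
#' @param max_iterations Maximum number of full sweeps over the target
#'   columns (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param min_leaf Minimum terminal-node size (default 5).
#' @param stop_rule `"first_increase"` stops the first time the convergence
#'   statistic rises between successive sweeps and returns the previous
#'   sweep's values (the classic MissForest rule); `"threshold"` stops once
#'   every applicable statistic falls below `threshold`.
#' @param threshold Relative-change tolerance for the `"threshold"` rule.
#' @param seed Master seed; per-column, per-sweep substreams are derived from
#'   it with [impute_seed()], so results are reproducible regardless of
#'   execution order.
#' @param clip_to_range Clamp imputed scores into their catalog
#'   `[score_min, score_max]` (default `TRUE`).
#' @param round_discrete Round imputed values of discrete tests to integers
#'   after convergence (default `FALSE`; validation statistics are computed
#'   on unrounded imputations).
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(max_iterations = 10, n_trees = 100, min_leaf = 5,
                              stop_rule = c("first_increase", "threshold"),
                              threshold = 1e-4, seed = 1,
                              clip_to_range = TRUE, round_discrete = FALSE) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(max_iterations >= 1, n_trees >= 1, min_leaf >= 1, threshold > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf),
                 stop_rule = stop_rule,
                 threshold = threshold,
                 seed = as.integer(seed),
                 clip_to_range = isTRUE(clip_to_range),
                 round_discrete = isTRUE(round_discrete)),
            class = "imputation_config")
}

#' Derive the forest seed for one target column in one sweep
#'
#' A deterministic substream of the master seed, keyed by sweep number and
#' target column name, so that every forest fit is reproducible independently
#' of the order in which columns are visited.
#'
#' @param seed Master seed (integer).
#' @param iteration Sweep number (1-based).
#' @param target Target column name.
#' @return An integer seed below 2^31.
#' @export
impute_seed <- function(seed, iteration, target) {
  h <- sum(utf8ToInt(target) * seq_along(utf8ToInt(target)))
  as.integer((as.numeric(seed) + 98807 * iteration + 131 * h) %% 2147483647)
}

#' Fill missing values with column means/medians
#'
#' The starting point of the iterative imputer: missing entries of continuous
#' tests are replaced by the column mean over observed values, and missing
#' entries of discrete tests by the column median; observed entries are left
#' untouched.
#'
#' @param table A [visit_table()].
#' @param targets Score columns to initialize (default: all with at least one
#'   missing value).
#' @return A [visit_table()] with the targets filled.
#' @export
initialize_missing <- function(table, targets = NULL) {
  d <- visits(table)
  cat <- vt_catalog(table)
  sc <- score_columns(table)
  if (is.null(targets)) {
    targets <- sc[vapply(sc, function(t) anyNA(d[[t]]), TRUE)]
  }
  for (t in targets) {
    v <- d[[t]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0) {
      stop("cannot initialize column with no observed values: ", t)
    }
    discrete <- cat$discrete[match(t, cat$test_id)]
    fill <- if (isTRUE(discrete)) stats::median(obs) else mean(obs)
    v[is.na(v)] <- fill
    d[[t]] <- v
  }
  visit_table(d, cat, validate = FALSE)
}

#' Convergence statistic between successive imputation sweeps
#'
#' For continuous variables, the normalized squared change over imputed
#' positions, `sum((current - previous)^2) / sum(current^2)` (0 when both
#' sums are 0, `Inf` when only the denominator is 0). For categorical
#' variables, the proportion of imputed positions whose category changed.
#'
#' @param previous,current Vectors of values at the imputed positions only.
#' @param scope `"continuous"` or `"categorical"`.
#' @return A nonnegative number.
#' @export
convergence_delta <- function(previous, current,
                              scope = c("continuous", "categorical")) {
  scope <- match.arg(scope)
  if (length(previous) != length(current)) {
    stop("previous and current must have equal length")
  }
  if (length(previous) == 0) return(0)
  if (scope == "continuous") {
    num <- sum((as.numeric(current) - as.numeric(previous))^2)
    den <- sum(as.numeric(current)^2)
    if (den == 0) {
      if (num == 0) 0 else Inf
    } else {
      num / den
    }
  } else {
    mean(as.character(previous) != as.character(current))
  }
}

demographic_predictors <- function() {
  c("age_years", "sex", "education_years", "apoe4", "cdr", "cohort_id")
}

# Build the mixed-type working frame used by the forests: demographic
# predictors (categoricals as factors) followed by score columns, in a fixed
# canonical order.
build_working_frame <- function(d, sc) {
  W <- d[, c(demographic_predictors(), sc), drop = FALSE]
  W$sex <- factor(W$sex)
  W$apoe4 <- factor(W$apoe4)
  W$cdr <- factor(W$cdr, levels = c(0, 0.5, 1))
  W$cohort_id <- factor(W$cohort_id)
  W
}

#' Iterative random-forest imputation of a merged visit table
#'
#' Implements MissForest-style chained random-forest imputation. After a
#' mean/median initialization, target columns are visited in ascending order
#' of missingness; for each target, a random forest is trained on the rows
#' where the target was originally observed, using demographics (age, sex,
#' education), clinical status (CDR), APOE epsilon-4 carriage, the dataset of
#' origin, and all other score columns as predictors, and the originally
#' missing rows are re-predicted. Each row is treated as an independent
#' observation; visit timing is not modelled directly, with age and CDR at
#' each visit acting as proxies for disease stage. Sweeps repeat until the
#' configured stopping rule fires or `max_iterations` is reached. Sporadic
#' and structural missingness are treated identically, so tests never
#' administered in a cohort are filled from the cohorts that do administer
#' them.
#'
#' Forests are fit with \pkg{ranger} (single-threaded, seeded per column and
#' sweep via [impute_seed()]); regression forests use `mtry = floor(p/3)` and
#' classification forests `mtry = floor(sqrt(p))`. Predictor columns are
#' passed in the table's canonical order (demographics first, then scores),
#' which matters for exact reproducibility.
#'
#' @param table A [visit_table()] (typically the merged multi-cohort table).
#' @param config An [imputation_config()].
#' @param targets Columns to impute. Default: every score column with at
#'   least one missing value, plus any of `sex`, `apoe4`, `education_years`,
#'   `age_years` that contain missing values (imputed with
#'   classification/regression forests in the same loop).
#' @param predictors Predictor columns. Default: the demographic set plus all
#'   score columns; the current target is always excluded from its own
#'   predictors.
#' @return A list of class `imputation_result`: `completed` (a
#'   [visit_table()] with no missing entries among the targets),
#'   `iterations_run`, `delta_trace` (data frame with one row per sweep:
#'   `iteration`, `delta_continuous`, `delta_categorical`), `imputed_mask`
#'   (logical matrix, rows x targets), and `config`.
#' @export
impute <- function(table, config = imputation_config(),
                   targets = NULL, predictors = NULL) {
  stopifnot(inherits(table, "visit_table"),
            inherits(config, "imputation_config"))
  d <- visits(table)
  cat <- vt_catalog(table)
  sc <- score_columns(table)

  demo_imputable <- c("age_years", "sex", "education_years", "apoe4")
  if (is.null(targets)) {
    targets <- c(sc[vapply(sc, function(t) anyNA(d[[t]]), TRUE)],
                 demo_imputable[vapply(demo_imputable,
                                       function(t) anyNA(d[[t]]), TRUE)])
  }
  bad <- setdiff(targets, c(sc, demo_imputable))
  if (length(bad) > 0) {
    stop("targets must be score columns or imputable demographics; offending: ",
         paste(bad, collapse = ", "))
  }

  W <- build_working_frame(d, sc)
  if (is.null(predictors)) {
    predictors <- colnames(W)
  }

  miss <- vapply(targets, function(t) is.na(W[[t]]), logical(nrow(W)))
  if (!is.matrix(miss)) miss <- matrix(miss, nrow = nrow(W),
                                       dimnames = list(NULL, targets))

  n_missing <- colSums(miss)
  if (all(n_missing == 0)) {
    return(structure(list(completed = table, iterations_run = 0L,
                          delta_trace = data.frame(iteration = integer(),
                                                   delta_continuous = numeric(),
                                                   delta_categorical = numeric()),
                          imputed_mask = miss, config = config),
                     class = "imputation_result"))
  }
  unobservable <- targets[n_missing == nrow(W)]
  if (length(unobservable) > 0) {
    stop("target column(s) observed in zero rows: ",
         paste(unobservable, collapse = ", "))
  }
  targets <- targets[n_missing > 0]
  miss <- miss[, targets, drop = FALSE]

  # initialization: mean (continuous) / median (discrete) / mode (categorical)
  for (t in targets) {
    v <- W[[t]]
    obs <- v[!is.na(v)]
    if (is.factor(v)) {
      fill <- names(sort(table(obs), decreasing = TRUE))[1]
      v[is.na(v)] <- fill
    } else {
      discrete <- t %in% cat$test_id && cat$discrete[match(t, cat$test_id)]
      v[is.na(v)] <- if (discrete) stats::median(obs) else mean(obs)
    }
    W[[t]] <- v
  }

  # visit order: ascending fraction of missing values
  ord <- targets[order(colMeans(miss), match(targets, colnames(W)))]
  continuous_targets <- ord[!vapply(ord, function(t) is.factor(W[[t]]), TRUE)]
  categorical_targets <- setdiff(ord, continuous_targets)

  trace <- data.frame(iteration = integer(), delta_continuous = numeric(),
                      delta_categorical = numeric())
  prev_deltas <- NULL
  W_prev <- NULL
  iterations_run <- 0L
  stopped_early <- FALSE

  for (it in seq_len(config$max_iterations)) {
    W_prev <- W
    for (t in ord) {
      preds <- setdiff(predictors, t)
      obs_rows <- !miss[, t]
      y <- W[[t]][obs_rows]
      x_train <- W[obs_rows, preds, drop = FALSE]
      p <- length(preds)
      classification <- is.factor(y)
      mtry <- if (classification) max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
      rf <- ranger::ranger(x = x_train, y = y,
                           num.trees = config$n_trees,
                           mtry = mtry,
                           min.node.size = config$min_leaf,
                           seed = impute_seed(config$seed, it, t),
                           num.threads = 1,
                           respect.unordered.factors = "ignore")
      pred <- stats::predict(rf, W[miss[, t], preds, drop = FALSE],
                             num.threads = 1)$predictions
      W[[t]][miss[, t]] <- pred
    }
    d_cont <- {
      prevs <- unlist(lapply(continuous_targets,
                             function(t) W_prev[[t]][miss[, t]]))
      curs <- unlist(lapply(continuous_targets,
                            function(t) W[[t]][miss[, t]]))
      convergence_delta(prevs, curs, "continuous")
    }
    d_cat <- if (length(categorical_targets) == 0) NA_real_ else {
      prevs <- unlist(lapply(categorical_targets,
                             function(t) as.character(W_prev[[t]][miss[, t]])))
      curs <- unlist(lapply(categorical_targets,
                            function(t) as.character(W[[t]][miss[, t]])))
      convergence_delta(prevs, curs, "categorical")
    }
    trace <- rbind(trace, data.frame(iteration = it, delta_continuous = d_cont,
                                     delta_categorical = d_cat))
    iterations_run <- it

    if (config$stop_rule == "first_increase") {
      if (!is.null(prev_deltas)) {
        increased <- c(length(continuous_targets) > 0 &&
                         d_cont > prev_deltas[1],
                       length(categorical_targets) > 0 &&
                         d_cat > prev_deltas[2])
        applicable <- c(length(continuous_targets) > 0,
                        length(categorical_targets) > 0)
        if (all(increased[applicable])) {
          W <- W_prev  # return the previous sweep's values
          stopped_early <- TRUE
          break
        }
      }
      prev_deltas <- c(d_cont, d_cat)
    } else {
      deltas <- c(if (length(continuous_targets) > 0) d_cont,
                  if (length(categorical_targets) > 0) d_cat)
      if (all(deltas < config$threshold)) break
    }
  }

  # post-processing on imputed cells only
  for (t in intersect(ord, sc)) {
    i <- match(t, cat$test_id)
    v <- W[[t]]
    cells <- miss[, t]
    if (config$round_discrete && cat$discrete[i]) {
      v[cells] <- round(v[cells])
    }
    if (config$clip_to_range) {
      v[cells] <- pmin(pmax(v[cells], cat$score_min[i]), cat$score_max[i])
    }
    W[[t]] <- v
  }

  out <- d
  for (t in ord) {
    v <- W[[t]]
    if (is.factor(v)) v <- as.character(v)
    out[[t]] <- v
  }
  completed <- visit_table(out, cat, validate = FALSE)
  structure(list(completed = completed, iterations_run = iterations_run,
                 delta_trace = trace, imputed_mask = miss, config = config),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Imputation result:", sum(x$imputed_mask), "cells imputed across",
      ncol(x$imputed_mask), "columns in", x$iterations_run, "sweep(s)\n")
  if (nrow(x$delta_trace) > 0) {
    cat("Final delta (continuous):",
        format(utils::tail(x$delta_trace$delta_continuous, 1), digits = 4), "\n")
  }
  invisible(x)
}

#' Before/after distribution comparison for a harmonized table
#'
#' For each test and cohort, compares the mean and SD of observed values in
#' the pre-imputation table with the mean and SD of all (observed + imputed)
#' values in the completed table. Columns that are 100% structurally missing
#' in a cohort report only the harmonized statistics.
#'
#' @param before The pre-imputation [visit_table()].
#' @param after The completed [visit_table()] from [impute()].
#' @return Data frame with one row per test per cohort: `n_observed`,
#'   `before_mean`, `before_sd`, `after_mean`, `after_sd`, `abs_diff_mean`,
#'   `rel_diff_mean` (absolute difference over the observed SD), and a
#'   `structural` flag.
#' @export
distribution_shift_report <- function(before, after) {
  db <- visits(before)
  da <- visits(after)
  stopifnot(nrow(db) == nrow(da))
  sc <- score_columns(before)
  out <- list()
  for (co in sort(unique(db$cohort_id))) {
    rows <- db$cohort_id == co
    for (t in sc) {
      vb <- db[[t]][rows]
      va <- da[[t]][rows]
      obs <- vb[!is.na(vb)]
      n_obs <- length(obs)
      bm <- if (n_obs > 0) mean(obs) else NA_real_
      bs <- if (n_obs > 1) stats::sd(obs) else NA_real_
      am <- mean(va, na.rm = TRUE)
      as_ <- stats::sd(va, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        cohort_id = co, test_id = t, n_observed = n_obs,
        before_mean = bm, before_sd = bs,
        after_mean = am, after_sd = as_,
        abs_diff_mean = abs(am - bm),
        rel_diff_mean = abs(am - bm) / bs,
        structural = n_obs == 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
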