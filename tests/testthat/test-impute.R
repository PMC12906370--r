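test_that("initialization fills means for continuous and medians for discrete", {
  d <- visits(tiny_table(n = 1, visits = 3))
  d$alpha <- c(1, NA, 3)        # continuous -> mean 2
  d$beta <- c(4, NA, 10)        # discrete -> median of {4, 10} = 7
  tb <- visit_table(d, tiny_catalog())
  out <- visits(initialize_missing(tb))
  expect_equal(out$alpha, c(1, 2, 3))
  expect_equal(out$beta[2], 7)
  expect_equal(out$gamma, d$gamma)  # untouched, no missing values

  d2 <- visits(tiny_table(n = 1, visits = 4))
  d2$beta <- c(4, 4, NA, 10)    # median of {4, 4, 10} = 4
  out2 <- visits(initialize_missing(visit_table(d2, tiny_catalog())))
  expect_equal(out2$beta[3], 4)

  d3 <- d; d3$alpha <- NA_real_
  expect_error(initialize_missing(visit_table(d3, tiny_catalog())), "alpha")
})

test_that("convergence delta follows the normalized-change definition", {
  expect_equal(convergence_delta(c(1, 2), c(1, 2)), 0)
  expect_equal(convergence_delta(c(0, 0), c(1, 1)), 1.0)
  expect_equal(convergence_delta(c(5, 5, 5), c(0, 0, 0)), Inf)
  expect_equal(convergence_delta(numeric(0), numeric(0)), 0)
  expect_equal(convergence_delta(c("a", "a", "b", "b"), c("a", "a", "b", "a"),
                                 scope = "categorical"), 0.25)
  expect_error(convergence_delta(1:3, 1:2), "equal length")
})

test_that("a table with nothing missing is returned unchanged", {
  tb <- tiny_table(n = 5)
  res <- impute(tb, imputation_config(n_trees = 10, seed = 1))
  expect_equal(res$iterations_run, 0)
  expect_identical(visits(res$completed), visits(tb))
  expect_equal(nrow(res$delta_trace), 0)
})

test_that("observed values are preserved and imputations bounded on fuzzed tables", {
  cfg_gen <- generator_config(n_participants = c(aibl = 25, adni = 25, oasis = 25),
                              mar_rates = c(aibl = 0.15, adni = 0.25, oasis = 0.10))
  for (s in c(11, 12)) {
    sim <- generate_cohorts(cfg_gen, seed = s)
    merged <- build_merged_table(sim$tables)
    before <- visits(merged)
    res <- impute(merged, imputation_config(n_trees = 15, max_iterations = 2,
                                            seed = s, clip_to_range = TRUE))
    after <- visits(res$completed)
    cat <- vt_catalog(merged)
    for (t in score_columns(merged)) {
      obs <- !is.na(before[[t]])
      expect_identical(after[[t]][obs], before[[t]][obs])
      expect_false(anyNA(after[[t]]))
      i <- match(t, cat$test_id)
      expect_true(all(after[[t]] >= cat$score_min[i] - 1e-9))
      expect_true(all(after[[t]] <= cat$score_max[i] + 1e-9))
    }
    expect_equal(nrow(res$delta_trace), res$iterations_run)
  }
})

test_that("imputation is deterministic under a fixed seed", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  cfg <- imputation_config(n_trees = 10, max_iterations = 2, seed = 77)
  r1 <- impute(merged, cfg)
  r2 <- impute(merged, cfg)
  expect_identical(visits(r1$completed), visits(r2$completed))
  expect_identical(r1$delta_trace, r2$delta_trace)
  r3 <- impute(merged, imputation_config(n_trees = 10, max_iterations = 2,
                                         seed = 78))
  expect_false(identical(visits(r1$completed), visits(r3$completed)))
})

test_that("a single missing cell reproduces a directly-fit forest oracle", {
  # independently coded one-shot oracle: per sweep, fit one regression forest
  # on the complete rows with the same derived seed and hyperparameters, and
  # replay the first-increase stopping rule on the published delta formula
  tb <- tiny_table(n = 20, visits = 3)
  d <- visits(tb)
  hole <- 17
  truth <- d$alpha[hole]
  d$alpha[hole] <- NA
  tb <- visit_table(d, tiny_catalog())
  cfg <- imputation_config(n_trees = 30, max_iterations = 6, seed = 99,
                           clip_to_range = FALSE)
  res <- impute(tb, cfg)

  W <- d[, c("age_years", "sex", "education_years", "apoe4", "cdr",
             "cohort_id", "alpha", "beta", "gamma")]
  W$sex <- factor(W$sex); W$apoe4 <- factor(W$apoe4)
  W$cdr <- factor(W$cdr, levels = c(0, 0.5, 1))
  W$cohort_id <- factor(W$cohort_id)
  preds <- setdiff(names(W), "alpha")
  x_train <- W[-hole, preds]; y <- W$alpha[-hole]
  x_miss <- W[hole, preds, drop = FALSE]
  vals <- mean(y)  # mean initialization of the single continuous cell
  deltas <- numeric(0)
  expected <- NA_real_
  for (it in 1:6) {
    rf <- ranger::ranger(x = x_train, y = y, num.trees = 30,
                         mtry = max(1L, floor(length(preds) / 3)),
                         min.node.size = 5,
                         seed = impute_seed(99, it, "alpha"),
                         num.threads = 1,
                         respect.unordered.factors = "ignore")
    p_it <- predict(rf, x_miss, num.threads = 1)$predictions
    deltas <- c(deltas, (p_it - vals[length(vals)])^2 / p_it^2)
    vals <- c(vals, p_it)
    if (it >= 2 && deltas[it] > deltas[it - 1]) {
      expected <- vals[it]  # previous sweep's value
      break
    }
  }
  if (is.na(expected)) expected <- vals[length(vals)]

  expect_identical(visits(res$completed)$alpha[hole], as.numeric(expected))
  expect_equal(res$delta_trace$delta_continuous, deltas)
  # forest predictions average observed targets, so stay within their range
  expect_gte(visits(res$completed)$alpha[hole], min(y))
  expect_lte(visits(res$completed)$alpha[hole], max(y))
  expect_true(all(res$imputed_mask[hole, "alpha"]))
})

test_that("columns are visited in ascending missingness order via derived seeds", {
  # the derived substream depends only on (seed, sweep, column), so the same
  # column imputed alone or together with others gets the same forest seed
  expect_identical(impute_seed(5, 1, "alpha"), impute_seed(5, 1, "alpha"))
  expect_false(impute_seed(5, 1, "alpha") == impute_seed(5, 2, "alpha"))
  expect_false(impute_seed(5, 1, "alpha") == impute_seed(5, 1, "beta"))
  expect_true(impute_seed(2^30, 9, "fluency_switching") < 2^31)
})

test_that("categorical demographics are imputable in the same loop", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  d <- visits(merged)
  drop <- withr::with_seed(3, sample(nrow(d), 25))
  d$apoe4[drop] <- NA
  merged <- visit_table(d, vt_catalog(merged))
  res <- impute(merged, imputation_config(n_trees = 10, max_iterations = 2,
                                          seed = 5))
  after <- visits(res$completed)
  expect_false(anyNA(after$apoe4))
  expect_true(all(after$apoe4 %in% c("carrier", "non-carrier")))
  expect_identical(after$apoe4[-drop], d$apoe4[-drop])
  expect_true(any(!is.na(res$delta_trace$delta_categorical)))
})

test_that("distribution shift report separates observed and harmonized moments", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  # make one administered column fully observed so a no-missing case exists
  d0 <- visits(merged)
  truth <- sim$truth$scores
  sub <- truth[truth$test_id == "mmse" & truth$cohort_id == "oasis", ]
  idx <- match(paste(paste(sub$cohort_id, sub$participant_id, sep = ":"),
                     sub$visit_index),
               paste(d0$participant_id, d0$visit_index))
  d0$mmse[idx] <- sub$true_score
  merged <- visit_table(d0, vt_catalog(merged))
  res <- impute(merged, imputation_config(n_trees = 15, max_iterations = 2,
                                          seed = 9))
  rep <- distribution_shift_report(merged, res$completed)

  # no-missing columns: before and after identical
  d <- visits(merged)
  complete_cases <- rep[!rep$structural & rep$n_observed > 0, ]
  full <- complete_cases[vapply(seq_len(nrow(complete_cases)), function(i) {
    rows <- d$cohort_id == complete_cases$cohort_id[i]
    !anyNA(d[[complete_cases$test_id[i]]][rows])
  }, TRUE), ]
  expect_gt(nrow(full), 0)
  expect_equal(full$before_mean, full$after_mean)
  expect_equal(full$before_sd, full$after_sd)

  # structurally missing columns report only harmonized statistics
  struct <- rep[rep$structural, ]
  expect_gt(nrow(struct), 0)
  expect_true(all(is.na(struct$before_mean)))
  expect_true(all(is.finite(struct$after_mean)))

  # a perfect imputation leaves the mean unchanged by construction
  oracle_rep <- distribution_shift_report(merged, merged)
  sporadic <- oracle_rep[!oracle_rep$structural, ]
  expect_true(all(abs(sporadic$abs_diff_mean) < 1e-12 |
                    is.na(sporadic$abs_diff_mean)))
})
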