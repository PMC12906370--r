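test_that("masking withholds the requested share of observed values", {
  sim <- small_sim()$sim
  tb <- sim$tables$aibl
  d <- visits(tb)
  n_obs <- sum(!is.na(d$mmse))
  out <- simulate_missing(tb, "mmse", fraction = 0.30, seed = 4)
  expect_equal(nrow(out$truth), floor(0.30 * n_obs + 0.5))
  masked_d <- visits(out$masked)
  expect_equal(sum(!is.na(masked_d$mmse)), n_obs - nrow(out$truth))
  # only originally observed entries are masked, and truth records them
  expect_true(all(!is.na(d$mmse[out$truth$row])))
  expect_identical(out$truth$value, d$mmse[out$truth$row])
  # other columns untouched
  expect_identical(masked_d$lmii, d$lmii)
  # different seeds give different masks
  out2 <- simulate_missing(tb, "mmse", fraction = 0.30, seed = 5)
  expect_false(identical(out$truth$row, out2$truth$row))
  expect_error(simulate_missing(tb, "mmse", fraction = 1e-6), "infeasible")
})

test_that("error metrics follow their printed definitions", {
  expect_equal(mae(c(10, 20), c(12, 16)), 3.0)
  expect_equal(mae(c(5, 5), c(5, 5)), 0)
  expect_error(mae(1:3, 1:2), "length mismatch")

  expect_equal(outlier_rate(c(1, 2, 3), c(1, 2, 3), 1), 0)
  # |21 - 10| = 11 > 2.5 * 4 = 10 -> outlier
  expect_equal(outlier_rate(10, 21, 4), 100)
  expect_equal(outlier_rate(c(0, 0, 0, 0), c(11, 1, 1, 1), 4), 25)
})

test_that("mae of a constant-mean imputer matches the closed form", {
  # for N(mu, s) noise, E|X - mu| = s * sqrt(2 / pi)
  s <- 3
  x <- withr::with_seed(42, rnorm(2e5, 10, s))
  expect_equal(mae(x, rep(10, length(x))), s * sqrt(2 / pi), tolerance = 0.01)
})

test_that("max discrepancy summarizes stable amyloid-negative participants", {
  d <- visits(tiny_table(n = 3, visits = 3, centiloid = c(5, 10, 80)))
  d$alpha[d$participant_id == "x01"] <- c(27, 27, 27)
  d$alpha[d$participant_id == "x02"] <- c(28, 30, 29)
  d$alpha[d$participant_id == "x03"] <- c(10, 50, 90)  # amyloid-positive
  tb <- visit_table(d, tiny_catalog())
  md <- max_discrepancy(tb, "alpha")
  expect_equal(md$n, 2)  # x03 is not in the CU amyloid-negative group
  expect_equal(sort(md$per_participant$discrepancy), c(0, 2))
  expect_equal(md$mean, 1)
  # shuffling visit order does not change the statistic
  d_shuffled <- d[withr::with_seed(1, sample(nrow(d))), ]
  md2 <- max_discrepancy(visit_table(d_shuffled, tiny_catalog()), "alpha")
  expect_equal(md2$mean, md$mean)
  expect_true(all(md$per_participant$discrepancy >= 0))

  # mean/SD of {0, 2, 4}
  d$alpha[d$participant_id == "x02"] <- c(28, 30, 28)
  d$alpha[d$participant_id == "x03"] <- c(10, 14, 12)
  d$centiloid[d$participant_id == "x03"] <- 5
  md3 <- max_discrepancy(visit_table(d, tiny_catalog()), "alpha")
  expect_equal(md3$mean, 2)
  expect_equal(md3$sd, 2)
  expect_equal(c(md3$min, md3$max), c(0, 4))

  # participants whose CDR leaves 0 at any visit are not a stable benchmark
  d$cdr <- ifelse(d$participant_id == "x01" & d$visit_index == 2, 0.5, 0)
  md4 <- max_discrepancy(visit_table(d, tiny_catalog()), "alpha")
  expect_equal(md4$n, 2)
})

test_that("an identity oracle scores zero error and the report is deterministic", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  plan <- holdout_plan(c("mmse", "lmii", "category_fluency"),
                       mask_fraction = 0.3, n_repeats = 2, master_seed = 31)
  identity_imputer <- function(masked_table, seed) merged
  rep1 <- run_validation(merged, plan, imputer = identity_imputer)
  expect_equal(rep1$mae_mean, rep(0, 3))
  expect_equal(rep1$mae_sd, rep(0, 3))
  expect_equal(rep1$outlier_pct_mean, rep(0, 3))
  expect_true(all(rep1$mae_le_maxdisc))
  rep2 <- run_validation(merged, plan, imputer = identity_imputer)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("report aggregation matches recomputation from per-repeat values", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  noisy <- function(masked_table, seed) {
    d <- visits(merged)
    withr::with_seed(seed, {
      for (t in score_columns(merged)) d[[t]] <- d[[t]] + rnorm(nrow(d), 0, 1)
    })
    visit_table(d, vt_catalog(merged), validate = FALSE)
  }
  plan <- holdout_plan(c("mmse", "bnt"), n_repeats = 4, master_seed = 7)
  rep <- run_validation(merged, plan, imputer = noisy)
  per <- attr(rep, "repeats")
  for (t in plan$tests) {
    sub <- per[per$test_id == t & !per$failed, ]
    expect_equal(rep$mae_mean[rep$test_id == t], mean(sub$mae))
    expect_equal(rep$mae_sd[rep$test_id == t], sd(sub$mae))
    expect_equal(rep$outlier_pct_mean[rep$test_id == t], mean(sub$outlier_pct))
  }
})

test_that("hold-out MAE grows monotonically with oracle noise", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  plan <- holdout_plan("mmse", n_repeats = 3, master_seed = 11)
  mae_at <- vapply(c(0.25, 1, 4), function(s) {
    imp <- function(masked_table, seed) {
      d <- visits(merged)
      withr::with_seed(seed, d$mmse <- d$mmse + rnorm(nrow(d), 0, s))
      visit_table(d, vt_catalog(merged), validate = FALSE)
    }
    run_validation(merged, plan, imputer = imp)$mae_mean
  }, 0)
  expect_true(all(diff(mae_at) > 0))
})

test_that("failed repeats are recorded without aborting the report", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  flaky <- local({
    calls <- 0
    function(masked_table, seed) {
      calls <<- calls + 1
      if (calls == 1) stop("transient failure")
      merged
    }
  })
  plan <- holdout_plan("mmse", n_repeats = 3, master_seed = 13)
  expect_warning(rep <- run_validation(merged, plan, imputer = flaky),
                 "transient failure")
  expect_equal(rep$n_failed, 1)
  expect_equal(rep$mae_mean, 0)
})
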