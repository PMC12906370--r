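test_that("the generator echoes its configuration", {
  fx <- small_sim()
  sim <- fx$sim
  expect_setequal(names(sim$tables), c("aibl", "adni", "oasis"))
  for (co in names(sim$tables)) {
    d <- visits(sim$tables[[co]])
    expect_equal(length(unique(d$participant_id)), 60)
    n_visits <- table(d$participant_id)
    expect_true(all(n_visits >= 3 & n_visits <= 5))
    expect_true(all(d$time_years[d$visit_index == 0] == 0))
  }
  # cohort-specific visit cadence
  adni <- visits(sim$tables$adni)
  expect_equal(sort(unique(adni$time_years)), (0:4) * 0.5)
})

test_that("cohort panels produce the structural-missingness pattern", {
  sim <- small_sim()$sim
  expect_true(all(is.na(visits(sim$tables$adni)$cvlt_delayed)))
  expect_true(all(is.na(visits(sim$tables$oasis)$cvlt_delayed)))
  expect_gt(sum(!is.na(visits(sim$tables$aibl)$cvlt_delayed)), 0)
  expect_true(all(is.na(visits(sim$tables$aibl)$tmt_b)))
  # ground truth covers the structurally absent cells
  truth <- sim$truth$scores
  absent <- truth[!truth$administered, ]
  expect_gt(nrow(absent), 0)
  expect_false(anyNA(absent$true_score))
})

test_that("observed scores equal their ground-truth values", {
  sim <- small_sim()$sim
  truth <- sim$truth$scores
  for (co in names(sim$tables)) {
    d <- visits(sim$tables[[co]])
    tr <- truth[truth$cohort_id == co, ]
    key_d <- paste(d$participant_id, d$visit_index)
    for (t in c("mmse", "lmii")) {
      sub <- tr[tr$test_id == t, ]
      v <- d[[t]][match(paste(sub$participant_id, sub$visit_index), key_d)]
      obs <- !is.na(v)
      expect_identical(v[obs], sub$true_score[obs])
      # missing observed cells are exactly the MAR-masked ones
      expect_identical(!obs, sub$mar_masked)
    }
  }
})

test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- generator_config(n_participants = c(aibl = 20, adni = 20, oasis = 20))
  a <- generate_cohorts(cfg, seed = 9)
  b <- generate_cohorts(cfg, seed = 9)
  c <- generate_cohorts(cfg, seed = 10)
  expect_identical(lapply(a$tables, visits), lapply(b$tables, visits))
  expect_identical(a$truth$scores, b$truth$scores)
  expect_false(identical(visits(a$tables$aibl), visits(c$tables$aibl)))
})

test_that("amyloid values respect the group definition", {
  sim <- small_sim()$sim
  p <- sim$truth$participants
  expect_true(all(p$centiloid[p$group %in% c("ABNEG_CDR0")] <= 25))
  expect_true(all(p$centiloid[grepl("^ABPOS", p$group)] > 25))
  # the assigned labels round-trip through the labelling rule
  expect_identical(as.character(assign_group_label(p$centiloid, p$cdr)),
                   p$group)
})

test_that("simulated test-retest discrepancy tracks the calibration targets", {
  cfg <- generator_config(n_participants = c(aibl = 250, adni = 250,
                                             oasis = 250))
  sim <- generate_cohorts(cfg, seed = 77)
  merged <- build_merged_table(sim$tables)
  params <- cfg$test_params
  for (t in c("mmse", "lmii", "cvlt_delayed", "tmt_b", "category_fluency",
              "digit_symbol")) {
    md <- max_discrepancy(merged, t)
    target <- params$retest_disc[params$test_id == t]
    expect_gt(md$mean, 0.5 * target)
    expect_lt(md$mean, 1.5 * target)
  }
})

test_that("generated composites order the clinical-pathological groups", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  res <- impute(merged, imputation_config(n_trees = 15, max_iterations = 2,
                                          seed = 5))
  norms <- fit_baseline_norms(res$completed)
  comp <- composite_scores(res$completed, norms = norms)
  base <- comp[comp$visit_index == 0, ]
  m <- tapply(base$pacc, as.character(base$group), mean)
  expect_gt(m["ABNEG_CDR0"], m["ABPOS_CDR05"])
  expect_gt(m["ABPOS_CDR0"], m["ABPOS_CDR05"])
  expect_gt(m["ABPOS_CDR05"], m["ABPOS_CDR1"])
})

test_that("truth-based MAE flags empty scopes and scores the oracle at zero", {
  sim <- small_sim()$sim
  merged <- build_merged_table(sim$tables)
  # oracle imputation: copy the ground truth into every missing cell
  d <- visits(merged)
  truth <- sim$truth$scores
  key_d <- paste(d$participant_id, d$visit_index)
  for (t in score_columns(merged)) {
    sub <- truth[truth$test_id == t, ]
    idx <- match(key_d, paste(paste(sub$cohort_id, sub$participant_id,
                                    sep = ":"), sub$visit_index))
    hole <- is.na(d[[t]])
    d[[t]][hole] <- sub$true_score[idx][hole]
  }
  oracle <- structure(list(completed = visit_table(d, vt_catalog(merged),
                                                   validate = FALSE),
                           iterations_run = 0L, delta_trace = NULL,
                           imputed_mask = NULL,
                           config = imputation_config()),
                      class = "imputation_result")
  for (scope in c("structural", "sporadic")) {
    tm <- truth_mae(oracle, sim$truth, scope)
    scored <- tm[tm$n_cells > 0, ]
    expect_gt(nrow(scored), 0)
    expect_true(all(scored$mae == 0))
    # tests with no cells in scope are flagged, not invented
    expect_true(all(is.na(tm$mae[tm$n_cells == 0])))
  }
  # mmse is administered everywhere: no structural cells
  tm <- truth_mae(oracle, sim$truth, "structural")
  expect_equal(tm$n_cells[tm$test_id == "mmse"], 0)
})
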