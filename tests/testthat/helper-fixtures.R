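# Small in-code fixtures shared across test files.

# A three-test catalog over two cohorts: one shared continuous test, one
# shared discrete test, and one test administered only in cohort "x".
tiny_catalog <- function() {
  test_catalog(data.frame(
    test_id = c("alpha", "beta", "gamma"),
    domain = c("episodic_memory", "executive_function", "language"),
    direction = c(1, -1, 1),
    score_min = c(0, 0, 0),
    score_max = c(100, 100, 100),
    discrete = c(FALSE, TRUE, FALSE),
    cohorts = c("x;y", "x;y", "x")
  ))
}

# Hand-built two-cohort table over tiny_catalog(); n participants per cohort,
# `visits` visits each, complete for the administered tests.
tiny_table <- function(n = 4, visits = 3, cohort = "x", seed = 1,
                       centiloid = NULL, cdr = 0) {
  cat <- tiny_catalog()
  withr::with_seed(seed, {
    pid <- sprintf("%s%02d", cohort, seq_len(n))
    rows <- rep(seq_len(n), each = visits)
    vindex <- rep(0:(visits - 1), n)
    if (is.null(centiloid)) centiloid <- runif(n, 0, 20)
    d <- data.frame(
      participant_id = pid[rows], cohort_id = cohort, visit_index = vindex,
      time_years = vindex * 1.0,
      age_years = 70 + rows + vindex,
      sex = rep(c("female", "male"), length.out = n)[rows],
      education_years = 12 + (rows %% 5),
      apoe4 = rep(c("carrier", "non-carrier"), length.out = n)[rows],
      cdr = if (length(cdr) == 1) cdr else cdr[rows],
      centiloid = centiloid[rows],
      stringsAsFactors = FALSE)
    d$alpha <- round(runif(nrow(d), 20, 80), 2)
    d$beta <- round(runif(nrow(d), 10, 90))
    d$gamma <- if (cohort == "x") round(runif(nrow(d), 30, 70), 2) else NA_real_
    visit_table(d, cat)
  })
}

# Cached small synthetic dataset (generation is cheap but repeated in many
# tests); invalidated per R session.
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    cfg <- generator_config(
      n_participants = c(aibl = 60, adni = 60, oasis = 60))
    .fixture_env$small_sim <- list(cfg = cfg,
                                   sim = generate_cohorts(cfg, seed = 2024))
  }
  .fixture_env$small_sim
}

# Complete-panel continuous-score dataset for model-recovery tests.
complete_panel_config <- function(n = 200, ...) {
  cat <- default_catalog()
  cat$cohorts <- "aibl;adni;oasis"
  cat <- test_catalog(as.data.frame(cat))
  generator_config(catalog = cat,
                   n_participants = c(aibl = n, adni = n, oasis = n),
                   mar_rates = c(aibl = 0, adni = 0, oasis = 0),
                   discretize = FALSE, ...)
}
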