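#' Default per-test calibration for the synthetic generator
#'
#' For each catalogued test: the population mean and SD of raw scores
#' (`mu`, `sd`) and the target mean test-retest maximum-discrepancy in
#' cognitively stable participants (`retest_disc`), all in raw score units.
#' The values are the package's calibration for magnitudes typical of these
#' instruments in aging cohorts. The generator derives each test's
#' measurement-noise SD as `retest_disc / 2` (the expected range of 3-5
#' independent Gaussian draws is roughly twice their SD) and its latent
#' loading so that the total baseline SD in stable participants equals `sd`.
#'
#' @return Data frame `test_id`, `mu`, `sd`, `retest_disc`, `noise_sd`.
#' @export
default_test_params <- function() {
  p <- data.frame(
    test_id = c("mmse", "lmii",
                "ravlt_total", "ravlt_delayed", "ravlt_recognition",
                "cvlt_total", "cvlt_delayed", "cvlt_recognition",
                "srt_free", "tmt_b", "digit_symbol",
                "digit_span_f", "digit_span_b",
                "bnt", "category_fluency", "fluency_switching"),
    mu = c(26.93, 9.52, 35.67, 4.62, 10.66, 46.33, 9.78, 14.42,
           28.46, 113.89, 56.89, 8.86, 6.05, 26.39, 17.71, 10.83),
    sd = c(4.25, 5.9, 13.83, 4.58, 4.06, 15.9, 4.87, 2.24,
           8.51, 72.82, 17.0, 2.54, 2.22, 4.57, 6.05, 3.94),
    retest_disc = c(1.65, 3.61, 9.83, 3.78, 2.34, 9.28, 2.68, 1.33,
                    5.0, 30.81, 9.36, 1.84, 1.97, 1.44, 5.33, 4.03),
    stringsAsFactors = FALSE
  )
  p$noise_sd <- p$retest_disc / 2
  p
}

#' Configuration of the synthetic multi-cohort generator
#'
#' Defines three synthetic cohorts with cohort-specific test panels
#' (structural missingness), demographic profiles, visit cadences, and
#' missing-at-random masking, over a latent-trajectory model of cognitive
#' decline: each participant carries one latent ability per cognitive domain
#' (episodic memory, executive function, language; the global latent is
#' their average) that declines linearly by clinical-pathological group,
#' with per-participant random intercepts and slopes. Raw test scores load
#' on their domain latent with additive Gaussian measurement noise, and are
#' optionally rounded and clamped to their catalog range.
#'
#' @param catalog A [test_catalog()] (default [default_catalog()]); its
#'   per-cohort administration pattern defines the structural missingness.
#' @param n_participants Named integer vector, participants per cohort.
#' @param visit_spacing Named numeric vector, years between visits per
#'   cohort (defaults echo 18-month, 6-month and annual cadences).
#' @param visits_min,visits_max Visits per participant (uniform draw).
#' @param group_probs Probabilities of the four clinical-pathological groups
#'   (defaults proportional to 1198/524/995/433).
#' @param deficits,slopes Baseline latent deficits (reference-SD units) and
#'   latent slopes (per year) per group, in the order `ABNEG_CDR0`,
#'   `ABPOS_CDR0`, `ABPOS_CDR05`, `ABPOS_CDR1`; defaults 0/-0.2/-1.5/-2.8
#'   and 0/-0.05/-0.25/-0.45.
#' @param subject_intercept_sd,subject_slope_sd SDs of the per-participant
#'   random intercept (the reference SD, default 1) and random slope per
#'   domain.
#' @param latent_cor Shared-variance fraction across domain latents within a
#'   participant (positive-manifold correlation, default 0.6).
#' @param test_params Per-test calibration, see [default_test_params()].
#' @param mar_rates Named per-cohort probabilities of sporadic
#'   missing-at-random masking of administered scores (defaults 5% / 19% /
#'   2%).
#' @param mar_cdr_inflation Multiplier on `mar_rates` per CDR stratum
#'   (names `"0"`, `"0.5"`, `"1"`); default no inflation. Missingness
#'   depends only on observed CDR, never on the score itself.
#' @param demographics Per-cohort data frame of `age_mean`, `age_sd`,
#'   `edu_mean`, `edu_sd`, `p_female`, `p_apoe4`.
#' @param discretize Round discrete tests and clamp all scores into catalog
#'   ranges (default `TRUE`); disable for analytically exact latent-recovery
#'   studies.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(catalog = default_catalog(),
                             n_participants = c(aibl = 500, adni = 500,
                                                oasis = 500),
                             visit_spacing = c(aibl = 1.5, adni = 0.5,
                                               oasis = 1.0),
                             visits_min = 3, visits_max = 5,
                             group_probs = c(ABNEG_CDR0 = 1198, ABPOS_CDR0 = 524,
                                             ABPOS_CDR05 = 995, ABPOS_CDR1 = 433) / 3150,
                             deficits = c(0, -0.2, -1.5, -2.8),
                             slopes = c(0, -0.05, -0.25, -0.45),
                             subject_intercept_sd = 1,
                             subject_slope_sd = 0.04,
                             latent_cor = 0.6,
                             test_params = default_test_params(),
                             mar_rates = c(aibl = 0.05, adni = 0.19,
                                           oasis = 0.02),
                             mar_cdr_inflation = c("0" = 1, "0.5" = 1, "1" = 1),
                             demographics = NULL,
                             discretize = TRUE) {
  cohorts <- names(n_participants)
  stopifnot(!is.null(cohorts), all(cohorts %in% catalog_cohorts(catalog)) ||
              all(catalog_cohorts(catalog) %in% cohorts))
  stopifnot(abs(sum(group_probs) - 1) < 1e-8,
            length(deficits) == 4, length(slopes) == 4,
            visits_min >= 3, visits_max >= visits_min,
            all(test_params$noise_sd > 0),
            all(test_params$noise_sd < test_params$sd),
            latent_cor >= 0, latent_cor < 1)
  missing_params <- setdiff(catalog_tests(catalog), test_params$test_id)
  if (length(missing_params) > 0) {
    stop("no test_params for catalogued test(s): ",
         paste(missing_params, collapse = ", "))
  }
  if (is.null(demographics)) {
    demographics <- data.frame(
      cohort_id = c("aibl", "adni", "oasis"),
      age_mean = c(72.3, 74.0, 73.5), age_sd = c(7.0, 7.3, 6.7),
      edu_mean = c(12.9, 16.2, 15.7), edu_sd = c(3.1, 2.6, 2.6),
      p_female = c(0.53, 0.47, 0.52), p_apoe4 = c(0.40, 0.43, 0.39),
      stringsAsFactors = FALSE)
    demographics <- demographics[demographics$cohort_id %in% cohorts, ]
    if (nrow(demographics) < length(cohorts)) {
      extra <- setdiff(cohorts, demographics$cohort_id)
      demographics <- rbind(demographics, data.frame(
        cohort_id = extra, age_mean = 73, age_sd = 7, edu_mean = 14,
        edu_sd = 3, p_female = 0.5, p_apoe4 = 0.4))
    }
  }
  structure(list(catalog = catalog, n_participants = n_participants,
                 visit_spacing = visit_spacing, visits_min = visits_min,
                 visits_max = visits_max, group_probs = group_probs,
                 deficits = deficits, slopes = slopes,
                 subject_intercept_sd = subject_intercept_sd,
                 subject_slope_sd = subject_slope_sd,
                 latent_cor = latent_cor, test_params = test_params,
                 mar_rates = mar_rates,
                 mar_cdr_inflation = mar_cdr_inflation,
                 demographics = demographics, discretize = discretize),
            class = "generator_config")
}

latent_domains <- function() c("episodic_memory", "executive_function", "language")

# variance of a domain latent's subject part; the global latent averages the
# three domains, which shrinks its variance by the positive-manifold factor
latent_variance <- function(config, domain) {
  f <- config$latent_cor
  v <- config$subject_intercept_sd^2
  if (domain == "global") v * (f + (1 - f) / 3) else v
}

# loading of a test on its domain latent, chosen so that the total baseline
# SD in stable reference participants equals the calibrated sd
test_loading <- function(config, test_id) {
  cat <- config$catalog
  p <- config$test_params
  i <- match(test_id, p$test_id)
  dom <- cat$domain[match(test_id, cat$test_id)]
  sqrt((p$sd[i]^2 - p$noise_sd[i]^2) / latent_variance(config, dom))
}

#' Generate synthetic cohorts with known ground truth
#'
#' Draws participants, groups, demographics, amyloid values, latent
#' trajectories and raw test scores per [generator_config()]; returns one
#' [visit_table()] per cohort (with structural missingness from the catalog
#' panels and sporadic missing-at-random masking) together with the complete
#' ground truth, including true scores for tests the cohort never
#' administers. Every visit keeps at least one observed administered score,
#' so generated tables already satisfy the longitudinal inclusion criteria.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `tables` (named list of [visit_table()]s), `truth`
#'   (list of data frames `participants`, `visits`, `scores`), and `config`.
#' @export
generate_cohorts <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  cat <- config$catalog
  tests <- catalog_tests(cat)
  glabels <- group_levels()[1:4]
  f <- config$latent_cor

  with_seed(seed, {
    parts <- list(); visits_out <- list(); scores_out <- list()
    tables <- list()
    for (co in names(config$n_participants)) {
      n <- config$n_participants[[co]]
      demo <- config$demographics[config$demographics$cohort_id == co, ]
      panel <- tests[vapply(tests, function(t) co %in% administered_in(cat, t),
                            TRUE)]
      pid <- sprintf("%s_%04d", co, seq_len(n))
      grp <- sample(glabels, n, replace = TRUE, prob = config$group_probs)
      gidx <- match(grp, glabels)
      cdr <- c(0, 0, 0.5, 1)[gidx]
      centiloid <- ifelse(gidx <= 1,
                          pmin(stats::rnorm(n, 5, 10), 24.5),
                          26 + abs(stats::rnorm(n, 30, 35)))
      age0 <- pmin(pmax(stats::rnorm(n, demo$age_mean, demo$age_sd), 45), 95)
      edu <- round(pmin(pmax(stats::rnorm(n, demo$edu_mean, demo$edu_sd), 5), 22))
      sex <- ifelse(stats::runif(n) < demo$p_female, "female", "male")
      apoe4 <- ifelse(stats::runif(n) < demo$p_apoe4, "carrier", "non-carrier")
      n_visits <- sample(config$visits_min:config$visits_max, n, replace = TRUE)

      # correlated per-domain random intercepts and slopes (positive manifold)
      g0 <- stats::rnorm(n); h0 <- stats::rnorm(n)
      b0 <- sapply(latent_domains(), function(d) {
        config$subject_intercept_sd *
          (sqrt(f) * g0 + sqrt(1 - f) * stats::rnorm(n))
      })
      b1 <- sapply(latent_domains(), function(d) {
        config$subject_slope_sd *
          (sqrt(f) * h0 + sqrt(1 - f) * stats::rnorm(n))
      })
      colnames(b0) <- colnames(b1) <- latent_domains()

      re <- cbind(b0, b1)
      colnames(re) <- c(paste0("b0_", latent_domains()),
                        paste0("b1_", latent_domains()))
      parts[[co]] <- data.frame(
        participant_id = pid, cohort_id = co, group = grp,
        centiloid = centiloid, cdr = cdr,
        re, stringsAsFactors = FALSE)

      rows <- rep(seq_len(n), n_visits)
      vindex <- unlist(lapply(n_visits, function(k) 0:(k - 1)))
      tim <- vindex * config$visit_spacing[[co]]
      nv <- length(rows)

      # latent values per visit
      L <- sapply(latent_domains(), function(d) {
        config$deficits[gidx[rows]] + config$slopes[gidx[rows]] * tim +
          b0[rows, d] + b1[rows, d] * tim
      })
      L <- cbind(L, global = rowMeans(L))

      Lnamed <- L
      colnames(Lnamed) <- paste0("L_", colnames(L))
      visits_out[[co]] <- data.frame(
        participant_id = pid[rows], cohort_id = co, visit_index = vindex,
        time_years = tim, Lnamed, stringsAsFactors = FALSE)

      d <- data.frame(
        participant_id = pid[rows], cohort_id = co, visit_index = vindex,
        time_years = tim, age_years = age0[rows] + tim, sex = sex[rows],
        education_years = edu[rows], apoe4 = apoe4[rows], cdr = cdr[rows],
        centiloid = centiloid[rows],
        diagnosis = c("CU", "MCI", "AD")[match(cdr[rows], c(0, 0.5, 1))],
        stringsAsFactors = FALSE)

      mar_p <- config$mar_rates[[co]] *
        config$mar_cdr_inflation[as.character(cdr[rows])]
      mar_p <- pmin(mar_p, 0.95)

      truth_sc <- matrix(NA_real_, nrow = nv, ncol = length(tests),
                         dimnames = list(NULL, tests))
      mar_mask <- matrix(FALSE, nrow = nv, ncol = length(tests),
                         dimnames = list(NULL, tests))
      for (t in tests) {
        i <- match(t, cat$test_id)
        p <- config$test_params[match(t, config$test_params$test_id), ]
        beta <- test_loading(config, t)
        raw <- p$mu + cat$direction[i] * beta * L[, cat$domain[i]] +
          stats::rnorm(nv, 0, p$noise_sd)
        if (config$discretize) {
          if (cat$discrete[i]) raw <- round(raw)
          raw <- pmin(pmax(raw, cat$score_min[i]), cat$score_max[i])
        }
        truth_sc[, t] <- raw
        if (t %in% panel) {
          mar_mask[, t] <- stats::runif(nv) < mar_p
          obs <- raw
          obs[mar_mask[, t]] <- NA_real_
          d[[t]] <- obs
        } else {
          d[[t]] <- NA_real_
        }
      }
      # guarantee at least one observed administered score per visit
      obs_count <- rowSums(!is.na(as.matrix(d[, panel, drop = FALSE])))
      for (r in which(obs_count == 0)) {
        unmask <- sample(panel, 1)
        d[[unmask]][r] <- truth_sc[r, unmask]
        mar_mask[r, unmask] <- FALSE
      }

      adm <- matrix(rep(tests %in% panel, each = nv), nrow = nv,
                    dimnames = list(NULL, tests))
      scores_out[[co]] <- data.frame(
        participant_id = rep(pid[rows], length(tests)),
        cohort_id = co,
        visit_index = rep(vindex, length(tests)),
        test_id = rep(tests, each = nv),
        true_score = as.vector(truth_sc),
        administered = as.vector(adm),
        mar_masked = as.vector(mar_mask),
        stringsAsFactors = FALSE)

      # unclamped continuous scores can sit outside the catalog range, so the
      # range check only applies when discretizing
      tables[[co]] <- visit_table(d, cat, validate = config$discretize,
                                  check_structural = config$discretize)
    }
    list(tables = tables,
         truth = list(participants = do.call(rbind, parts),
                      visits = do.call(rbind, visits_out),
                      scores = do.call(rbind, scores_out)),
         config = config)
  })
}

#' Population baseline norms implied by a generator configuration
#'
#' The analytic mean and SD of each test's baseline distribution in stable
#' reference participants (exact when `discretize = FALSE`); usable in place
#' of sample norms from [fit_baseline_norms()] for latent-recovery studies.
#'
#' @param config A [generator_config()].
#' @return A `baseline_norms` data frame.
#' @export
population_norms <- function(config) {
  p <- config$test_params
  norms <- data.frame(test_id = p$test_id, mean = p$mu, sd = p$sd,
                      n = NA_integer_, stringsAsFactors = FALSE)
  class(norms) <- c("baseline_norms", "data.frame")
  norms
}

#' Ground-truth composite trajectories implied by a generator configuration
#'
#' Under the generator's latent model, the expected standardized score of
#' test j in group g at time t is `(beta_j / sd_j) * (deficit_g + slope_g *
#' t)`, so each composite's group trajectory is linear with intercept and
#' slope scaled by the mean loading-to-SD ratio of its members. Exact when
#' `discretize = FALSE` and composites are standardized with
#' [population_norms()].
#'
#' @param config A [generator_config()].
#' @param specs Composite specs (default [default_composites()] on the
#'   config's catalog).
#' @return Data frame `composite`, `group`, `intercept`, `slope`.
#' @export
composite_truth <- function(config, specs = NULL) {
  if (is.null(specs)) specs <- default_composites(config$catalog)
  p <- config$test_params
  rows <- list()
  for (s in specs) {
    k <- mean(vapply(s$members, function(t) {
      test_loading(config, t) / p$sd[match(t, p$test_id)]
    }, 0))
    rows[[s$name]] <- data.frame(
      composite = s$name, group = group_levels()[1:4],
      intercept = k * config$deficits, slope = k * config$slopes,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score an imputation against synthetic ground truth
#'
#' Computes, per test, the mean absolute error of imputed values against the
#' generator's true scores, separately for structurally missing cells (test
#' never administered in the cohort) and sporadically masked cells
#' (missing-at-random). Only synthetic data can score structural cells,
#' which is the point of the generator.
#'
#' @param result An [impute()] result computed on the merged table built
#'   from generated cohorts (participant ids carry the `"cohort:"` prefix
#'   added by [build_merged_table()]).
#' @param truth The `truth` element of [generate_cohorts()].
#' @param scope `"structural"` or `"sporadic"`.
#' @return Data frame `test_id`, `n_cells`, `mae`; `mae` is `NA` (flagged by
#'   `n_cells = 0`) for tests with no cells in the requested scope.
#' @export
truth_mae <- function(result, truth, scope = c("structural", "sporadic")) {
  scope <- match.arg(scope)
  stopifnot(inherits(result, "imputation_result"))
  d <- visits(result$completed)
  sc <- truth$scores
  cells <- if (scope == "structural") !sc$administered else sc$mar_masked
  sc <- sc[cells, , drop = FALSE]
  key_table <- paste(d$participant_id, d$visit_index, sep = "\r")
  key_truth <- paste(paste(sc$cohort_id, sc$participant_id, sep = ":"),
                     sc$visit_index, sep = "\r")
  row_idx <- match(key_truth, key_table)
  ok <- !is.na(row_idx)
  sc <- sc[ok, , drop = FALSE]
  row_idx <- row_idx[ok]
  out <- lapply(unique(truth$scores$test_id), function(t) {
    sel <- sc$test_id == t
    if (!any(sel)) {
      return(data.frame(test_id = t, n_cells = 0L, mae = NA_real_))
    }
    imp <- d[[t]][row_idx[sel]]
    data.frame(test_id = t, n_cells = sum(sel),
               mae = mean(abs(imp - sc$true_score[sel])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
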