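#' Default pipeline configuration
#'
#' Stage-by-stage configuration for [run_pipeline()], expressed as a plain
#' list so it can be round-tripped through YAML. Only a subset of fields
#' needs to be given; anything absent falls back to these defaults.
#'
#' @return Nested list with elements `generator`, `inclusion`, `impute`,
#'   `validation`, `composites`, `model`.
#' @export
default_pipeline_config <- function() {
  list(
    generator = list(n_per_cohort = 500, visits_min = 3, visits_max = 5),
    inclusion = list(min_assessments = 3, centiloid_threshold = 25),
    impute = list(max_iterations = 10, n_trees = 100, min_leaf = 5,
                  stop_rule = "first_increase", clip_to_range = TRUE,
                  round_discrete = FALSE),
    validation = list(tests = NULL, mask_fraction = 0.30, n_repeats = 5),
    composites = list(reference = "cu"),
    model = list(window = 5, reference = "ABNEG_CDR0")
  )
}

merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      user[[k]] <- merge_config(user[[k]], defaults[[k]])
    }
  }
  user
}

pipeline_stages <- function() {
  c("simulate", "merge", "impute", "validate", "composites", "groupmodel")
}

#' Run the harmonization pipeline end to end
#'
#' Chains the stages `simulate` (synthetic cohorts + catalog), `merge`
#' (pooled table after inclusion criteria), `impute` (harmonized table +
#' convergence trace), `validate` (mask-and-reimpute precision report),
#' `composites` (baseline norms + composite scores) and `groupmodel`
#' (trajectory models), reading each stage's inputs from the previous
#' stage's files in `outdir`, and writes a run manifest with the config
#' snapshot, seeds and an MD5 digest of every output file. All stage
#' outputs are plain CSV; a rerun with the same seed reproduces identical
#' digests for every deterministic stage.
#'
#' @param config A nested list (see [default_pipeline_config()]) or the path
#'   of a YAML file holding one.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed routed to every source of randomness.
#' @param stages Subset of stages to run, in pipeline order; each stage
#'   requires its upstream files to exist, and the error message names the
#'   stage to run first.
#' @return The manifest (list), invisibly written to `manifest.yaml`.
#' @export
run_pipeline <- function(config = list(), outdir, seed = 1,
                         stages = pipeline_stages()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(config, default_pipeline_config())
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  need <- function(f, producer) {
    if (!file.exists(pth(f))) {
      stop("missing input '", f, "': run stage '", producer, "' first")
    }
    pth(f)
  }
  status <- list()
  outputs <- character()
  t_all <- Sys.time()

  for (stage in pipeline_stages()[pipeline_stages() %in% stages]) {
    t0 <- Sys.time()
    produced <- switch(stage,
      simulate = {
        g <- config$generator
        n <- g$n_per_cohort
        gc <- generator_config(
          n_participants = c(aibl = n, adni = n, oasis = n),
          visits_min = g$visits_min, visits_max = g$visits_max)
        sim <- generate_cohorts(gc, seed = seed)
        write_catalog(gc$catalog, pth("catalog.csv"))
        for (co in names(sim$tables)) {
          write_visits(sim$tables[[co]], pth(paste0("cohort_", co, ".csv")))
        }
        utils::write.csv(sim$truth$scores, pth("truth_scores.csv"),
                         row.names = FALSE, na = "")
        utils::write.csv(sim$truth$participants, pth("truth_participants.csv"),
                         row.names = FALSE, na = "")
        c("catalog.csv", paste0("cohort_", names(sim$tables), ".csv"),
          "truth_scores.csv", "truth_participants.csv")
      },
      merge = {
        cat <- read_catalog(need("catalog.csv", "simulate"))
        files <- list.files(outdir, pattern = "^cohort_.*\\.csv$")
        if (length(files) == 0) {
          stop("missing input 'cohort_*.csv': run stage 'simulate' first")
        }
        tables <- lapply(file.path(outdir, sort(files)), read_visits,
                         catalog = cat)
        merged <- build_merged_table(tables)
        inc <- apply_inclusion_criteria(
          merged, min_assessments = config$inclusion$min_assessments)
        write_visits(inc$table, pth("merged.csv"))
        utils::write.csv(inc$log, pth("exclusions.csv"), row.names = FALSE)
        utils::write.csv(missingness_summary(inc$table),
                         pth("missingness.csv"), row.names = FALSE)
        c("merged.csv", "exclusions.csv", "missingness.csv")
      },
      impute = {
        cat <- read_catalog(need("catalog.csv", "simulate"))
        merged <- read_visits(need("merged.csv", "merge"), cat)
        ic <- config$impute
        cfg <- imputation_config(max_iterations = ic$max_iterations,
                                 n_trees = ic$n_trees, min_leaf = ic$min_leaf,
                                 stop_rule = ic$stop_rule, seed = seed,
                                 clip_to_range = ic$clip_to_range,
                                 round_discrete = ic$round_discrete)
        res <- impute(merged, config = cfg)
        write_visits(res$completed, pth("harmonized.csv"))
        utils::write.csv(res$delta_trace, pth("trace.csv"), row.names = FALSE)
        utils::write.csv(distribution_shift_report(merged, res$completed),
                         pth("distribution_shift.csv"), row.names = FALSE, na = "")
        c("harmonized.csv", "trace.csv", "distribution_shift.csv")
      },
      validate = {
        cat <- read_catalog(need("catalog.csv", "simulate"))
        merged <- read_visits(need("merged.csv", "merge"), cat)
        vc <- config$validation
        tests <- vc$tests
        if (is.null(tests)) tests <- catalog_tests(cat)
        plan <- holdout_plan(tests, mask_fraction = vc$mask_fraction,
                             n_repeats = vc$n_repeats, master_seed = seed)
        ic <- config$impute
        cfg <- imputation_config(max_iterations = ic$max_iterations,
                                 n_trees = ic$n_trees, min_leaf = ic$min_leaf,
                                 stop_rule = ic$stop_rule, seed = seed,
                                 clip_to_range = ic$clip_to_range,
                                 round_discrete = ic$round_discrete)
        rep <- run_validation(merged, plan, cfg)
        utils::write.csv(as.data.frame(rep), pth("validation_report.csv"),
                         row.names = FALSE, na = "")
        "validation_report.csv"
      },
      composites = {
        cat <- read_catalog(need("catalog.csv", "simulate"))
        harmonized <- read_visits(need("harmonized.csv", "impute"), cat)
        norms <- fit_baseline_norms(harmonized,
                                    reference = config$composites$reference)
        comp <- composite_scores(harmonized, norms = norms)
        write_norms(norms, pth("norms.csv"))
        utils::write.csv(comp, pth("composites.csv"), row.names = FALSE, na = "")
        c("norms.csv", "composites.csv")
      },
      groupmodel = {
        comp <- utils::read.csv(need("composites.csv", "composites"),
                                stringsAsFactors = FALSE)
        res <- group_model_results(comp, window = config$model$window,
                                   reference = config$model$reference,
                                   keep_fits = FALSE)
        utils::write.csv(res$means, pth("model_means.csv"), row.names = FALSE)
        utils::write.csv(res$slopes, pth("model_slopes.csv"), row.names = FALSE)
        utils::write.csv(res$contrasts, pth("model_contrasts.csv"),
                         row.names = FALSE)
        utils::write.csv(res$varcomp, pth("model_varcomp.csv"),
                         row.names = FALSE)
        c("model_means.csv", "model_slopes.csv", "model_contrasts.csv",
          "model_varcomp.csv")
      })
    outputs <- c(outputs, produced)
    status[[stage]] <- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  }

  digests <- as.list(tools::md5sum(file.path(outdir, unique(outputs))))
  names(digests) <- unique(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cogharmon")),
    seed = seed,
    config = config,
    stages = status,
    outputs = digests,
    started = format(t_all, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
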