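#' Configure an end-to-end synthetic-cohort analysis run
#'
#' Bundles the stage specifications and seeds for [run_pipeline()]. Every
#' stochastic stage draws its own seed deterministically from the master
#' seed, so stages are decoupled: changing the bootstrap count does not
#' perturb the simulated cohort.
#'
#' @param design A [design_spec()].
#' @param cohort A [cohort_spec()].
#' @param mediation A [mediation_cohort_spec()].
#' @param grid_step RL grid resolution.
#' @param n_boot Bootstrap resamples for group stats and mediation.
#' @param seed Master integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = design_spec(),
                       cohort = cohort_spec(),
                       mediation = mediation_cohort_spec(),
                       grid_step = 1e-4,
                       n_boot = 5000,
                       seed = 1L) {
  stopifnot(inherits(design, "design_spec"),
            inherits(cohort, "cohort_spec"),
            inherits(mediation, "mediation_cohort_spec"))
  structure(
    list(design = design, cohort = cohort, mediation = mediation,
         grid_step = grid_step, n_boot = n_boot, seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_seeds <- function(master_seed) {
  old <- globalenv()$.Random.seed
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  stats::setNames(s, c("design", "cohort", "mediation", "group", "boot"))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes design generation, cohort simulation, predictor construction,
#' per-participant influence-model and RL fits, group statistics, and
#' bootstrap mediation, writing every intermediate table as CSV plus JSON
#' reports and a manifest (seeds, row counts, file hashes) to `out_dir`.
#' Re-running with the same config reproduces byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seeds <- stage_seeds(config$seed)
  stage <- "design"
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   started = format(Sys.time(), tz = "UTC"), stages = list())
  paths <- list()
  tryCatch({
    say("stage: design")
    dspec <- config$design
    dspec$seed <- seeds[["design"]]
    t0 <- Sys.time()
    design <- generate_design(dspec)
    violations <- validate_design(design, dspec)
    if (length(violations) > 0) {
      stop("generated design failed validation: ",
           paste(violations, collapse = "; "))
    }
    paths$design <- file.path(out_dir, "design.csv")
    write_design(design, paths$design)
    manifest$stages$design <- list(
      n_trials = nrow(design),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "cohort"
    say("stage: cohort simulation")
    t0 <- Sys.time()
    cspec <- config$cohort
    cspec$seed <- seeds[["cohort"]]
    cohort <- simulate_cohort(cspec, design)
    paths$participants <- file.path(out_dir, "participants.csv")
    paths$trials <- file.path(out_dir, "trials.csv")
    utils::write.csv(as.data.frame(cohort$participants),
                     paths$participants, row.names = FALSE)
    utils::write.csv(as.data.frame(cohort$trials), paths$trials,
                     row.names = FALSE)
    manifest$stages$cohort <- list(
      n_agents = nrow(cohort$participants),
      n_trial_rows = nrow(cohort$trials),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "predictors"
    say("stage: predictors")
    t0 <- Sys.time()
    analysis_ready <- add_predictors(cohort$trials,
                                     accfb_bound = config$design$accfb_bound)
    paths$analysis_ready <- file.path(out_dir, "analysis_ready.csv")
    utils::write.csv(as.data.frame(analysis_ready), paths$analysis_ready,
                     row.names = FALSE)
    manifest$stages$predictors <- list(
      n_rows = nrow(analysis_ready),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "influence_glm"
    say("stage: influence model fits")
    t0 <- Sys.time()
    glm_fits <- fit_influence_cohort(analysis_ready)
    paths$glm_fits <- file.path(out_dir, "glm_fits.csv")
    utils::write.csv(as.data.frame(glm_fits), paths$glm_fits,
                     row.names = FALSE)
    manifest$stages$influence_glm <- list(
      n_fit = sum(!glm_fits$excluded), n_excluded = sum(glm_fits$excluded),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "rl_fit"
    say("stage: RL grid fits")
    t0 <- Sys.time()
    rl_fits <- fit_rl_cohort(cohort$trials, grid_step = config$grid_step)
    paths$rl_fits <- file.path(out_dir, "rl_fits.csv")
    utils::write.csv(as.data.frame(rl_fits), paths$rl_fits,
                     row.names = FALSE)
    manifest$stages$rl_fit <- list(
      n_fit = sum(!rl_fits$excluded),
      n_violators = sum(rl_fits$violator, na.rm = TRUE),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "group_stats"
    say("stage: group statistics")
    t0 <- Sys.time()
    group <- group_analysis(glm_fits, rl_fits, cohort$participants,
                            n_boot = config$n_boot, seed = seeds[["group"]])
    bias <- vsp_bias_analysis(rl_fits, cohort$trials)
    paths$group_report <- file.path(out_dir, "group_report.json")
    jsonlite::write_json(
      list(group = group, vsp_bias = bias$tests,
           vsp_bias_per_participant = bias$per_participant),
      paths$group_report, digits = NA, na = "null"
    )
    manifest$stages$group_stats <- list(
      n_analyses = nrow(group),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )

    stage <- "mediation"
    say("stage: mediation")
    t0 <- Sys.time()
    mspec <- config$mediation
    mspec$seed <- seeds[["mediation"]]
    triad <- simulate_mediation_cohort(mspec)
    paths$mediation_cohort <- file.path(out_dir, "mediation_cohort.csv")
    utils::write.csv(as.data.frame(triad), paths$mediation_cohort,
                     row.names = FALSE)
    med <- run_mediation_suite(triad, mediators = "mediator",
                               outcome = "outcome",
                               n_boot = config$n_boot,
                               seed = seeds[["boot"]])
    paths$mediation_report <- file.path(out_dir, "mediation.json")
    jsonlite::write_json(med, paths$mediation_report, digits = NA,
                         na = "null")
    manifest$stages$mediation <- list(
      indirect = med$indirect, significant = med$significant,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)), marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$files <- lapply(paths, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
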