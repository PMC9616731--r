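# End-to-end orchestration over synthetic inputs: simulate -> score ->
# validate -> trips -> analyze, with a JSON manifest recording seeds,
# config hash, row counts and warnings. Single-process; structured data go
# to files, progress to messages.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @param design maze design for the cohort stage.
#' @param n_bees cohort size.
#' @param replicates simulant replicates for the validation stage.
#' @param statistic validation statistic (see [dataset_statistic()]).
#' @param nectar_max_pollen,min_duration,debounce_s,match_tol_s trip-stage
#'   thresholds (mg, min, s, s).
#' @param season a [season_params()] object for the field stage.
#' @param stages character vector of stages to run, in order.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("foragecog_run_"), seed = 1L,
                       design = "validation", n_bees = 20L,
                       replicates = 200L, statistic = "mean_errors",
                       nectar_max_pollen = 3, min_duration = 7,
                       debounce_s = 5, match_tol_s = 120,
                       season = season_params(),
                       stages = c("simulate", "score", "validate", "trips",
                                  "analyze")) {
  stopifnot(nectar_max_pollen > 0, min_duration > 0, debounce_s > 0,
            match_tol_s > 0)
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order on synthetic inputs and writes
#' every intermediate artifact plus a `manifest.json` under
#' `config$out_dir`. A stage failure aborts the run but still writes the
#' manifest with the completed stages marked.
#'
#' @param config a [run_config()] object.
#' @return the manifest, invisibly (list with per-stage metadata).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("foragecog")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = list())
  p <- function(...) file.path(config$out_dir, ...)
  state <- new.env()
  warnings_log <- character()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
  }

  on.exit({
    manifest$warnings <- warnings_log
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
  })

  run_stage("simulate", function() {
    set.seed(config$seed)
    coh <- simulate_cohort(n_bees = config$n_bees, design = config$design)
    state$cohort <- coh
    write_visits_csv(coh$visits, p("visits.csv"))
    bees <- simulate_bee_table(config$season)
    state$field_bees <- bees
    season <- simulate_season(bees, config$season)
    state$season <- season
    logs <- simulate_rfid_scale_logs(season$trips, duplicate_reads = TRUE)
    state$logs <- logs
    write_rfid_csv(logs$rfid, p("rfid.csv"))
    write_weighs_csv(logs$weighs, p("weights.csv"))
    write_weather_csv(season$weather, p("weather.csv"))
    write_bees_csv(bees, p("bees.csv"))
    list(n_visits = nrow(coh$visits), n_field_bees = nrow(bees),
         n_trips_true = nrow(season$trips))
  })

  run_stage("score", function() {
    scores <- ram_scores(state$cohort$visits, design = config$design)
    state$scores <- scores
    write_scores_csv(scores, p("scores.csv"))
    list(n_bees = nrow(scores), mean_ram_score = mean(scores$ram_score))
  })

  run_stage("validate", function() {
    val <- ram_validation(state$cohort$visits,
                          covariates = state$cohort$bees,
                          design = config$design,
                          n_replicates = config$replicates,
                          statistic = config$statistic,
                          seed = config$seed + 1L)
    jsonlite::write_json(
      list(observed = val$observed, p_value = val$p_value,
           N = val$n_replicates, tail = val$tail,
           statistic_name = val$statistic, seed = val$seed),
      p("null_summary.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(data.frame(replicate_id = seq_along(val$null_values),
                                statistic = val$statistic,
                                value = val$null_values),
                     p("null_distribution.csv"), progress = FALSE)
    list(N = val$n_replicates, p_value = val$p_value,
         observed = val$observed)
  })

  run_stage("trips", function() {
    trips <- pair_events_to_trips(state$logs$rfid, state$logs$weighs,
                                  debounce_s = config$debounce_s,
                                  match_tol_s = config$match_tol_s)
    trips <- derive_loads(trips)
    trips <- classify_and_filter(trips,
                                 nectar_max_pollen = config$nectar_max_pollen,
                                 min_duration = config$min_duration)
    state$trips <- trips
    write_trips_csv(trips, p("trips.csv"))
    list(n_trips = nrow(trips),
         n_nectar = sum(trips$trip_type == "nectar"),
         n_pollen = sum(trips$trip_type == "pollen"),
         n_excluded = sum(trips$trip_type == "excluded"))
  })

  run_stage("analyze", function() {
    eff <- efficiency_table(state$trips, bees = state$field_bees,
                            weather_scores = state$season$weather_scores)
    dat <- build_analysis_data(eff)
    dat <- dat[dat$trip_type == "nectar", , drop = FALSE]
    sel <- fit_and_select(candidate_set("nectar"), dat)
    writeLines(sel$trace, p("selection.txt"))
    fits_json <- lapply(sel$fits, function(f) {
      if (!isTRUE(f$converged)) return(list(name = f$name, converged = FALSE))
      list(name = f$name, logLik = f$logLik, k = f$k, n = f$n,
           AIC = f$AIC, AICc = f$AICc, converged = TRUE,
           coefficients = f$coefficients)
    })
    jsonlite::write_json(fits_json, p("fits.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
    prof <- tryCatch({
      fit_int <- sel$fits$covariates_ram_week
      pr <- interaction_profile(fit_int, weeks = sort(unique(dat$week)))
      readr::write_csv(pr$profile, p("profile.csv"), progress = FALSE)
      pr$reversal_week
    }, error = function(e) NA_real_)
    list(n_analysis_trips = nrow(dat), selected = sel$selected,
         criterion = sel$criterion_used, reversal_week = prof)
  })

  invisible(manifest)
}
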