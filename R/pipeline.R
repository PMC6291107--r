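## End-to-end orchestration: config -> report bundle.

#' Assemble a pipeline run configuration
#'
#' Exactly one of `log`/`roster` paths or a `simulate` block must be
#' given.  All stage randomness derives from the single `seed` via fixed
#' per-stage offsets, so adding a stage never perturbs earlier stages.
#'
#' @param log,roster input CSV paths (with `dialect`), or `NULL`.
#' @param simulate a [colony_config()] to generate inputs instead.
#' @param dialect detection-log dialect for file input.
#' @param gap_max_s visit segmentation gap rule.
#' @param long_overlap_s,transient_gap_s interaction thresholds.
#' @param survival_start `"YYYY-MM"` of CJS occasion 1, or `NULL` to skip
#'   the survival stage.
#' @param survival_occasions number of monthly occasions.
#' @param survival_cohort optional roster predicate for the CJS cohort.
#' @param n_perm permutation count for the network regressions.
#' @param seed master seed.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(log = NULL, roster = NULL, simulate = NULL,
                       dialect = detection_dialect(), gap_max_s = 11,
                       long_overlap_s = 11, transient_gap_s = 11,
                       survival_start = NULL, survival_occasions = 13,
                       survival_cohort = NULL, n_perm = 10000, seed = 1) {
  if (is.null(simulate) == (is.null(log) || is.null(roster)))
    stop("give either log+roster paths or a simulate block, not both",
         call. = FALSE)
  stopifnot(gap_max_s > 0, long_overlap_s > 0, transient_gap_s > 0)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, render = 211L, network = 307L,
            survival = 401L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Stages, in order: validate -> visits -> diel -> interactions/network ->
#' survival.  A stage failure aborts with an error naming the stage.  The
#' result is a report bundle of plain tables, regenerable from the inputs
#' and config alone; the provenance block records the config, seed and
#' package version (no timestamps, so identical runs are identical
#' objects).
#'
#' @param config a [run_config()].
#' @return list of class `"report_bundle"`.
#' @export
run_pipeline <- function(config) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$simulate)) {
    roster <- run_stage("simulate",
      simulate_roster(config$simulate, stage_seed(config$seed, "simulate")))
    true_visits <- run_stage("simulate",
      simulate_visits(roster, config$simulate,
                      stage_seed(config$seed, "simulate")))
    detections <- run_stage("simulate",
      render_detections(true_visits, config$simulate,
                        stage_seed(config$seed, "render")))
  } else {
    roster <- run_stage("input", read_roster(config$roster))
    detections <- run_stage("input",
      read_detection_log(config$log, config$dialect))
  }
  report <- run_stage("validate", validate_detections(detections, roster))
  visits <- run_stage("visits",
    segment_visits(detections[detections$tag_id %in% roster$tag_id, ,
                              drop = FALSE], config$gap_max_s))
  summaries <- run_stage("visits", summarize_birds(visits, roster))
  ranking <- run_stage("visits", rank_feeders(visits))
  movement <- run_stage("visits", site_movement(visits, roster))
  diel <- run_stage("diel", {
    seasons <- unique(assign_season(as.Date(visits$start)))
    profs <- lapply(seasons, function(s) diel_profile(visits, s))
    names(profs) <- seasons
    profs
  })
  rayleigh <- run_stage("diel",
    if (nrow(visits) >= 2)
      rayleigh_test(clock_to_angle(visits$start)) else NULL)
  night <- run_stage("diel", night_activity(visits))
  interactions <- run_stage("network",
    detect_interactions(visits, config$long_overlap_s,
                        config$transient_gap_s))
  network <- run_stage("network", build_network(interactions, roster))
  cent <- run_stage("network", centralities(network))
  perm <- run_stage("network",
    if (nrow(cent) >= 4)
      permutation_glm(cent, network$nodes, n_perm = config$n_perm,
                      seed = stage_seed(config$seed, "network"))
    else NULL)
  survival <- NULL
  if (!is.null(config$survival_start)) {
    survival <- run_stage("survival", {
      hx <- build_encounter_histories(detections, roster,
                                      config$survival_start,
                                      config$survival_occasions,
                                      config$survival_cohort)
      model_selection_two_step(hx)
    })
  }
  structure(list(
    validation = report, visits = visits, summaries = summaries,
    ranking = ranking, primary_tally = primary_feeder_tally(ranking),
    movement = movement, diel = diel, rayleigh = rayleigh, night = night,
    interactions = interactions, network = network, centralities = cent,
    permutation = perm, survival = survival,
    headline = summarize_detections_raw(detections, visits, roster),
    provenance = list(seed = config$seed,
                      gap_max_s = config$gap_max_s,
                      n_perm = config$n_perm,
                      survival_stage = !is.null(config$survival_start),
                      package_version =
                        as.character(utils::packageVersion("perchwatch")))),
    class = "report_bundle")
}

summarize_detections_raw <- function(detections, visits, roster) {
  known <- detections$tag_id %in% roster$tag_id
  detected <- unique(detections$tag_id[known])
  r <- roster
  pct <- function(x, n) if (n > 0) 100 * x / n else 0
  by_level <- function(col) {
    lev <- sort(unique(r[[col]]))
    sapply(lev, function(v) {
      den <- sum(r[[col]] == v)
      pct(sum(r[[col]] == v & r$tag_id %in% detected), den)
    })
  }
  list(total_detections = nrow(detections),
       total_visits = nrow(visits),
       birds_detected = length(detected),
       roster_size = nrow(r),
       pct_detected = pct(length(detected), nrow(r)),
       pct_detected_by_species = by_level("species"),
       pct_detected_by_sex = by_level("sex"),
       pct_detected_by_age = by_level("age"),
       species_share_of_detected = if (length(detected))
         100 * table(r$species[r$tag_id %in% detected]) / length(detected)
       else table(character()))
}

#' Headline counts for a report bundle
#'
#' Total detections and visits, the number and percentage of tagged birds
#' detected at least once, and detected percentages by species, sex and
#' age (denominators from the roster).
#'
#' @param bundle a `"report_bundle"` from [run_pipeline()].
#' @return named list of counts and percentages.
#' @export
summarize_detections <- function(bundle) bundle$headline

#' @export
print.report_bundle <- function(x, ...) {
  h <- x$headline
  cat("perchwatch report bundle\n")
  cat(sprintf("  %d detections -> %d visits by %d of %d tagged birds (%.1f%%)\n",
              h$total_detections, h$total_visits, h$birds_detected,
              h$roster_size, h$pct_detected))
  cat("  interactions:", nrow(x$interactions),
      "| network:", nrow(x$network$nodes), "birds /",
      nrow(x$network$edges), "edges\n")
  if (!is.null(x$survival))
    cat("  survival top model:", x$survival$step2$Model[1L], "\n")
  invisible(x)
}
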