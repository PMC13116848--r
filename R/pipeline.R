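#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a [sim_config()]
#' (simulate mode) or a directory containing the four claim CSVs (ingest
#' mode), plus the analysis parameters.
#'
#' @param simulate A [sim_config()] to generate input tables, or `NULL`.
#' @param input_dir Directory with `patients.csv`, `providers.csv`,
#'   `hosp_claims.csv`, `outpatient_claims.csv` (ingest mode).
#' @param output_dir Where stage outputs are written; `NULL` skips writing.
#' @param study_start,study_end Study window; defaults come from the sim
#'   config in simulate mode and must be given in ingest mode.
#' @param horizon_days Episode length (default 90).
#' @param min_volume Provider minimum index-patient volume (default 30).
#' @param age_bands Standardization bands (see [fit_reference()]).
#' @param funnel_alphas Two-sided funnel significance levels.
#' @param currency_factor Multiplies every claim cost at ingest (default 1;
#'   e.g. a CZK-to-EUR factor for koruna-denominated claims).
#' @param seed Seed for simulate mode (overrides the sim config's).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            output_dir = NULL,
                            study_start = NULL, study_end = NULL,
                            horizon_days = 90L, min_volume = 30L,
                            age_bands = DEFAULT_AGE_BANDS,
                            funnel_alphas = c(0.05, 0.002),
                            currency_factor = 1.0, seed = NULL) {
  if (is.null(simulate) && is.null(input_dir))
    abort("Provide either `simulate` (a sim_config) or `input_dir`.",
          class = "stroke90_config_error")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    abort(paste0("Input directory does not exist: ", input_dir),
          class = "stroke90_config_error")
  if (horizon_days < 1L)
    abort("`horizon_days` must be at least 1.", class = "stroke90_config_error")
  if (!is.null(simulate)) {
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
    if (is.null(study_start)) study_start <- simulate$study_start
    if (is.null(study_end)) study_end <- simulate$study_end
  }
  if (is.null(study_start) || is.null(study_end))
    abort("`study_start` and `study_end` are required in ingest mode.",
          class = "stroke90_config_error")
  structure(list(simulate = simulate, input_dir = input_dir,
                 output_dir = output_dir,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end),
                 horizon_days = as.integer(horizon_days),
                 min_volume = as.integer(min_volume),
                 age_bands = age_bands, funnel_alphas = funnel_alphas,
                 currency_factor = currency_factor),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `simulate:`
#' block holds [sim_config()] overrides (scalar fields only; table-valued
#' defaults are kept).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    for (d in c("study_start", "study_end"))
      if (!is.null(sim_args[[d]])) sim_args[[d]] <- as.Date(sim_args[[d]])
    sim <- do.call(sim_config, sim_args)
  }
  pipeline_config(
    simulate = sim,
    input_dir = y$input_dir,
    output_dir = y$output_dir,
    study_start = if (!is.null(y$study_start)) as.Date(y$study_start),
    study_end = if (!is.null(y$study_end)) as.Date(y$study_end),
    horizon_days = y$horizon_days %||% 90L,
    min_volume = y$min_volume %||% 30L,
    age_bands = unlist(y$age_bands %||% DEFAULT_AGE_BANDS),
    funnel_alphas = unlist(y$funnel_alphas %||% c(0.05, 0.002)),
    currency_factor = y$currency_factor %||% 1.0,
    seed = y$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full claims-to-indicators pipeline
#'
#' Simulate (or ingest) claims, build the cohort, cost the 90-day
#' episodes, fit the reference mortality model, produce the group
#' summaries (by intervention, provider type and provider) and the funnel
#' points/limits for provider comparison, and reconcile row counts in a
#' manifest. When `output_dir` is set, every stage product is written as
#' CSV and the manifest as JSON.
#'
#' @param config A [pipeline_config()].
#' @return List with `world`, `events`, `rejects`, `episodes`,
#'   `ref_model`, `summaries` (by_intervention, by_provider_type,
#'   by_provider), `funnel` (points and limit curves for mortality, SMR
#'   and mean total cost), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  # stage 1: inputs
  if (!is.null(config$simulate)) {
    world <- generate_world(config$simulate)
  } else {
    world <- read_world(config$input_dir)
  }
  if (config$currency_factor != 1) {
    world$hosp_claims$cost <- world$hosp_claims$cost * config$currency_factor
    world$outpatient_claims$cost <- world$outpatient_claims$cost * config$currency_factor
  }

  # stage 2: cohort
  sel <- select_index_events(world$hosp_claims, world$patients,
                             config$study_start, config$study_end,
                             providers = world$providers)
  vol <- apply_volume_filter(sel$events, config$min_volume)
  rejects <- dplyr::bind_rows(
    sel$rejects,
    tibble::tibble(
      patient_id = sel$events$patient_id[
        sel$events$provider_id %in% vol$excluded_providers$provider_id],
      claim_id = sel$events$primary_claim_id[
        sel$events$provider_id %in% vol$excluded_providers$provider_id],
      reason = "LOW_VOLUME"))
  events <- vol$events

  # stage 3: episodes
  episodes <- build_episodes(events, world$hosp_claims,
                             world$outpatient_claims, world$patients,
                             config$horizon_days)

  # stage 4: standardization
  ref <- fit_reference(episodes, config$age_bands)

  # stage 5: summaries
  summaries <- list(
    by_intervention = summarize_groups(episodes, "intervention", ref),
    by_provider_type = summarize_groups(episodes, "provider_type", ref),
    by_provider = summarize_groups(episodes, c("provider_id", "provider_type"), ref)
  )

  # stage 6: funnels (mortality proportion, SMR, mean total cost)
  pts_mort <- funnel_points_proportion(episodes)
  pts_smr <- funnel_points_ratio(episodes, ref)
  if (any(pts_smr$precision <= 0)) {
    warn(paste0(sum(pts_smr$precision <= 0), " provider(s) with zero ",
                "expected deaths dropped from the standardized-ratio funnel."))
    pts_smr <- pts_smr[pts_smr$precision > 0, ]
  }
  pts_cost <- funnel_points_mean(episodes)
  grid_n <- grid_over(pts_mort$precision)
  curve_mort <- proportion_limits(grid_n, ref$overall_rate, config$funnel_alphas)
  curve_smr <- ratio_limits(grid_over(pts_smr$precision), config$funnel_alphas)
  curve_cost <- mean_limits(grid_n, mean(episodes$cost_total),
                            pooled_sd(episodes), config$funnel_alphas)
  funnel <- list(
    mortality = list(points = flag_units(pts_mort, curve_mort), curve = curve_mort),
    smr = list(points = flag_units(pts_smr, curve_smr), curve = curve_smr),
    cost = list(points = flag_units(pts_cost, curve_cost), curve = curve_cost)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("stroke90")),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    mode = if (!is.null(config$simulate)) "simulate" else "ingest",
    study_start = as.character(config$study_start),
    study_end = as.character(config$study_end),
    horizon_days = config$horizon_days,
    min_volume = config$min_volume,
    counts = list(
      patients_in = nrow(world$patients),
      hosp_claims_in = nrow(world$hosp_claims),
      outpatient_claims_in = nrow(world$outpatient_claims),
      index_events = nrow(sel$events),
      rejects = as.list(table(rejects$reason)),
      low_volume_providers = nrow(vol$excluded_providers),
      cohort = nrow(episodes),
      deaths_90d = sum(episodes$died_90d)
    ),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  # reconciliation: cohort = index events - low-volume exclusions
  stopifnot(manifest$counts$cohort ==
              manifest$counts$index_events - sum(rejects$reason == "LOW_VOLUME"))

  result <- list(world = world, events = events, rejects = rejects,
                 episodes = episodes, ref_model = ref,
                 summaries = summaries, funnel = funnel, manifest = manifest)

  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

grid_over <- function(x) {
  lo <- max(min(x), 1e-6)
  exp(seq(log(lo), log(max(x)), length.out = 100))
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_world(result$world, dir)
  readr::write_csv(result$events, file.path(dir, "index_events.csv"))
  readr::write_csv(result$rejects, file.path(dir, "rejects.csv"))
  readr::write_csv(result$episodes, file.path(dir, "episodes.csv"))
  write_reference(result$ref_model, file.path(dir, "reference_model.csv"))
  readr::write_csv(result$summaries$by_intervention,
                   file.path(dir, "summary_by_intervention.csv"))
  readr::write_csv(result$summaries$by_provider_type,
                   file.path(dir, "summary_by_provider_type.csv"))
  readr::write_csv(result$summaries$by_provider,
                   file.path(dir, "summary_by_provider.csv"))
  pts <- purrr::imap_dfr(result$funnel, function(f, nm)
    dplyr::mutate(f$points, indicator = nm, .before = 1))
  readr::write_csv(pts, file.path(dir, "funnel_points.csv"))
  lims <- purrr::imap_dfr(result$funnel, function(f, nm)
    dplyr::mutate(f$curve$grid, indicator = nm, target = f$curve$target,
                  .before = 1))
  readr::write_csv(lims, file.path(dir, "funnel_limits.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
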