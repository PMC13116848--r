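#' Calibration report for a synthetic claims world
#'
#' Runs the cohort and costing stages on generated tables and compares the
#' realized structure with the configuration: age mean/SD, female share,
#' intervention mix, per-component cost mean vs median (log-normal costs
#' must show median < mean), and realized 90-day crude mortality next to
#' the mortality implied by the logistic model evaluated on the realized
#' cohort (its exact conditional expectation).
#'
#' @param world A `claims_world` from [generate_world()].
#' @param config The [sim_config()] used (defaults to the one stored in
#'   `world`).
#' @return A list with `n_cohort`, `age_mean`, `age_sd`, `female_share`,
#'   `intervention_mix`, `cost_summary` (component, mean, median),
#'   `crude_mortality` and `implied_mortality`.
#' @export
calibration_report <- function(world, config = world$config) {
  if (nrow(world$patients) == 0L || nrow(world$hosp_claims) == 0L)
    abort("Cannot calibrate on empty tables.", class = "stroke90_empty_error")
  sel <- select_index_events(world$hosp_claims, world$patients,
                             config$study_start, config$study_end,
                             providers = world$providers)
  ep <- build_episodes(sel$events, world$hosp_claims,
                       world$outpatient_claims, world$patients)
  # exact (continuous) age at index, not the whole-year age of the episode
  ep <- dplyr::left_join(ep, world$patients[, c("patient_id", "birth_date")],
                         by = "patient_id")
  age_exact <- as.numeric(ep$index_date - ep$birth_date) / 365.25

  cost_summary <- tibble::tibble(
    component = c("primary", "other_hosp", "outpatient", "total"),
    mean = c(mean(ep$cost_primary), mean(ep$cost_other_hosp),
             mean(ep$cost_outpatient), mean(ep$cost_total)),
    median = c(median(ep$cost_primary), median(ep$cost_other_hosp),
               median(ep$cost_outpatient), median(ep$cost_total))
  )

  implied <- mean(death_probability(age_exact, as.character(ep$intervention),
                                    config$mortality_model))

  list(
    n_cohort = nrow(ep),
    age_mean = mean(age_exact),
    age_sd = sd(age_exact),
    female_share = mean(ep$sex == "F"),
    intervention_mix = prop.table(table(ep$intervention)),
    cost_summary = cost_summary,
    crude_mortality = mean(ep$died_90d),
    implied_mortality = implied
  )
}
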