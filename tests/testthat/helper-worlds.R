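# shared fixtures for the suite

# a small, fast world: cohort and provider network scaled down together so
# per-provider volumes stay above the default minimum-volume threshold
tiny_plan <- function() tibble::tibble(
  provider_type = c("CSC", "PSC", "SRH", "OTHER"),
  n_providers = c(2L, 3L, 3L, 1L),
  expected_volume = c(628, 340, 102, 57))

tiny_config <- function(seed = 101L, n_patients = 1500L,
                        provider_plan = tiny_plan(), ...) {
  sim_config(seed = seed, n_patients = n_patients,
             provider_plan = provider_plan, ...)
}

no_edge_cases <- function() {
  list(under18 = 0L, repeat_index = 0L, late_index = 0L,
       low_volume_provider = 0L)
}

toy_dir <- function() system.file("extdata", "toy", package = "stroke90")

toy_world <- function() read_world(toy_dir())

toy_pipeline_config <- function(min_volume = 3L, ...) {
  pipeline_config(input_dir = toy_dir(),
                  study_start = "2018-01-01", study_end = "2019-12-31",
                  min_volume = min_volume, ...)
}

# the 7-patient fixture has age bands without deaths, so grouped
# standardization legitimately warns about zero-expected groups; those
# warnings are asserted once in the standardization tests
run_toy <- function(...) suppressWarnings(run_pipeline(toy_pipeline_config(...)))

# episodes with known structure, built without the generator
manual_episodes <- function(ages, died, costs = rep(1000, length(ages)),
                            provider = rep("A", length(ages))) {
  tibble::tibble(
    patient_id = sprintf("M%03d", seq_along(ages)),
    provider_id = provider,
    age_at_index = ages,
    los = 7L,
    sex = "F",
    intervention = factor("other", levels = c("thrombectomy", "thrombolysis", "other")),
    died_90d = died,
    cost_primary = costs, cost_other_hosp = 0, cost_outpatient = 0,
    cost_total = costs
  )
}
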