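test_that("identical config and seed reproduce the world exactly", {
  cfg <- tiny_config(seed = 11)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$patients, w2$patients)
  expect_identical(w1$providers, w2$providers)
  expect_identical(w1$hosp_claims, w2$hosp_claims)
  expect_identical(w1$outpatient_claims, w2$outpatient_claims)

  w3 <- generate_world(tiny_config(seed = 12))
  expect_false(identical(w1$hosp_claims, w3$hosp_claims))
})

test_that("generated tables are internally consistent", {
  w <- generate_world(tiny_config(seed = 21))

  # referential integrity
  expect_true(all(w$hosp_claims$patient_id %in% w$patients$patient_id))
  expect_true(all(w$hosp_claims$provider_id %in% w$providers$provider_id))
  expect_true(all(w$outpatient_claims$patient_id %in% w$patients$patient_id))

  # record-level invariants
  expect_false(any(duplicated(w$patients$patient_id)))
  expect_false(any(duplicated(w$providers$provider_id)))
  expect_false(any(duplicated(w$hosp_claims$claim_id)))
  expect_true(all(w$hosp_claims$discharge_date >= w$hosp_claims$admission_date))
  expect_true(all(is.finite(w$hosp_claims$cost)) && all(w$hosp_claims$cost >= 0))
  expect_true(all(w$outpatient_claims$cost >= 0))
  has_death <- !is.na(w$patients$death_date)
  expect_true(all(w$patients$death_date[has_death] >=
                    w$patients$birth_date[has_death]))

  # every regular patient has at least one I63 hospitalization
  i63_pat <- unique(w$hosp_claims$patient_id[grepl("^I63", w$hosp_claims$main_dx)])
  regular <- w$patients$patient_id[grepl("^P\\d", w$patients$patient_id)]
  expect_true(all(regular %in% i63_pat))
})

test_that("injected edge cases appear in the configured numbers", {
  cfg <- tiny_config(seed = 31, edge_case_counts = list(
    under18 = 5L, repeat_index = 8L, late_index = 7L, low_volume_provider = 2L))
  w <- generate_world(cfg)

  # exactly 5 patients aged <18 at their (earliest) I63 admission
  sel <- select_index_events(w$hosp_claims, w$patients,
                             cfg$study_start, cfg$study_end)
  expect_identical(sum(sel$rejects$reason == "UNDER18"), 5L)
  expect_identical(sum(sel$rejects$reason == "LATE_INDEX"), 7L)

  # at least the injected number of patients has a repeated I63 admission
  i63 <- w$hosp_claims[grepl("^I63", w$hosp_claims$main_dx), ]
  expect_gte(sum(table(i63$patient_id) >= 2), 8L)

  # low-volume providers exist and are far below the default threshold
  vol <- apply_volume_filter(sel$events, 30L)
  expect_gte(nrow(vol$excluded_providers), 2L)
  expect_true(all(c("LV01", "LV02") %in% vol$excluded_providers$provider_id))
})

test_that("costs are right-skewed (median < mean) and collapse for point masses", {
  w <- generate_world(tiny_config(seed = 41, n_patients = 2500))
  cal <- calibration_report(w)
  expect_true(all(cal$cost_summary$median < cal$cost_summary$mean))

  # degenerate scale: all log-normal components become point masses;
  # deaths disabled so every patient keeps the full claim set
  cp <- default_cost_params()
  cp$sdlog <- 0
  cfg0 <- tiny_config(seed = 42, n_patients = 400, cost_params = cp,
                      p_secondary_hosp = 1,
                      mortality_model = list(intercept = -30, age_per_decade = 0,
                                             ref_age = 70,
                                             offsets = c(thrombectomy = 0,
                                                         thrombolysis = 0, other = 0)),
                      p_late_death = 0,
                      edge_case_counts = no_edge_cases())
  w0 <- generate_world(cfg0)
  # within one intervention each cost component is a point mass
  ep0 <- build_episodes(select_index_events(w0$hosp_claims, w0$patients,
                                            cfg0$study_start, cfg0$study_end,
                                            w0$providers)$events,
                        w0$hosp_claims, w0$outpatient_claims, w0$patients)
  for (iv in unique(ep0$intervention)) {
    x <- ep0$cost_primary[ep0$intervention == iv]
    expect_equal(stats::median(x), mean(x))
    y <- ep0$cost_other_hosp[ep0$intervention == iv]
    expect_equal(stats::median(y), mean(y))
  }
})

test_that("realized structure matches the configuration", {
  cfg <- tiny_config(seed = 51, n_patients = 5000,
                     edge_case_counts = no_edge_cases())
  cal <- calibration_report(generate_world(cfg))

  # binomial / normal sampling bounds at ~4 standard errors
  expect_lt(abs(cal$female_share - cfg$female_fraction),
            4 * sqrt(0.47 * 0.53 / 5000))
  expect_lt(abs(cal$age_mean - cfg$age_mean), 4 * cfg$age_sd / sqrt(5000))

  # realized mortality vs the closed-form marginal rate of the logistic
  # model integrated over the truncated-normal age distribution
  m <- cfg$mortality_model
  marginal <- function(offset) {
    dens <- function(a) stats::dnorm(a, cfg$age_mean, cfg$age_sd) /
      (1 - stats::pnorm(18, cfg$age_mean, cfg$age_sd))
    stats::integrate(function(a)
      plogis(m$intercept + m$age_per_decade * (a - m$ref_age) / 10 + offset) *
        dens(a), 18, 150)$value
  }
  mix <- as.numeric(cal$intervention_mix)
  implied_closed_form <- sum(mix * vapply(
    m$offsets[names(cal$intervention_mix)], marginal, numeric(1)))
  expect_lt(abs(cal$implied_mortality - implied_closed_form), 0.005)
  expect_lt(abs(cal$crude_mortality - implied_closed_form),
            4 * sqrt(implied_closed_form * (1 - implied_closed_form) / 5000))
})

test_that("invalid configurations and empty tables are rejected", {
  expect_error(sim_config(n_patients = 0), class = "stroke90_config_error")
  expect_error(sim_config(study_start = "2020-01-01", study_end = "2019-01-01"),
               class = "stroke90_config_error")
  bad_mix <- default_intervention_mix()
  bad_mix$other[1] <- 0.9
  expect_error(sim_config(intervention_mix = bad_mix),
               class = "stroke90_config_error")
  expect_error(sim_config(female_fraction = 1.2), class = "stroke90_config_error")
  expect_error(sim_config(edge_case_counts = list(under18 = -1L,
                                                  repeat_index = 0L,
                                                  late_index = 0L,
                                                  low_volume_provider = 0L)),
               class = "stroke90_config_error")

  w <- generate_world(tiny_config(seed = 61, n_patients = 50))
  w$patients <- w$patients[0, ]
  expect_error(calibration_report(w, tiny_config(seed = 61, n_patients = 50)),
               class = "stroke90_empty_error")
})
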