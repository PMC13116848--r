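#' Simulation configuration for the synthetic claims generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_world()]. The defaults emulate the statistical structure of a
#' nationwide ischemic-stroke claims cohort: 23,568 adult patients with mean
#' age 70.6 (SD 12.4) years, 47% female, an intervention mix of roughly 5.5%
#' thrombectomy / 17% thrombolysis / 77% other treatment concentrated in
#' comprehensive and primary stroke centres, right-skewed log-normal costs
#' (median well below the mean for every component), and 90-day mortality
#' rising with age and highest after thrombectomy.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration (including this seed).
#' @param n_patients Number of regular cohort patients (edge-case patients
#'   are generated in addition, see `edge_case_counts`).
#' @param study_start,study_end `Date` bounds of the claims extract. Index
#'   admissions for regular patients are placed so that at least 90
#'   follow-up days remain before `study_end`.
#' @param provider_plan Data frame with columns `provider_type`
#'   (CSC/PSC/SRH/OTHER), `n_providers` and `expected_volume` (expected
#'   index patients per provider; used as sampling weights).
#' @param age_mean,age_sd Normal age distribution in years, truncated below
#'   at 18 (except injected under-18 edge cases).
#' @param female_fraction Probability that a patient is female.
#' @param intervention_mix Data frame with columns `provider_type`,
#'   `thrombectomy`, `thrombolysis`, `other`; each row must sum to 1.
#' @param cost_params Data frame with columns `intervention`, `component`
#'   (`primary`, `other_hosp`, `outpatient`), `meanlog`, `sdlog`: log-normal
#'   parameters of EUR cost amounts. `other_hosp` parameters are
#'   conditional on a secondary hospitalization occurring; `outpatient` is
#'   the total in-window outpatient spend, split over 1-3 claims.
#' @param mortality_model List with `intercept` (log-odds of 90-day death at
#'   `ref_age` for the "other" group), `age_per_decade` (log-odds increase
#'   per 10 years of age), `ref_age` (centering age, years) and `offsets`
#'   (named log-odds offsets per intervention).
#' @param los_mean,los_sd Length of stay of the primary hospitalization in
#'   days (gamma-distributed, rounded to whole days).
#' @param p_secondary_hosp Probability of an in-window secondary
#'   hospitalization.
#' @param p_late_hosp Probability of an out-of-window (day 90+)
#'   hospitalization, used to exercise the episode window boundary.
#' @param p_late_death Probability that a 90-day survivor has a recorded
#'   death between day 90 and day 365 (exercises the mortality boundary).
#' @param currency_factor Multiplicative scale applied to every generated
#'   cost (1 = EUR; supply a conversion factor for other currencies).
#' @param edge_case_counts Named list of injected pathological cases:
#'   `under18` (patients younger than 18 at admission), `repeat_index`
#'   (patients with a second, later I63 admission), `late_index` (index
#'   admissions with fewer than 90 follow-up days), `low_volume_provider`
#'   (extra providers with only 10 index patients each).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 23568L,
                       study_start = as.Date("2017-01-01"),
                       study_end = as.Date("2020-10-02"),
                       provider_plan = default_provider_plan(),
                       age_mean = 70.6,
                       age_sd = 12.4,
                       female_fraction = 0.47,
                       intervention_mix = default_intervention_mix(),
                       cost_params = default_cost_params(),
                       mortality_model = default_mortality_model(),
                       los_mean = 8.8,
                       los_sd = 7.3,
                       p_secondary_hosp = 0.35,
                       p_late_hosp = 0.10,
                       p_late_death = 0.05,
                       currency_factor = 1.0,
                       edge_case_counts = list(under18 = 5L,
                                               repeat_index = 20L,
                                               late_index = 10L,
                                               low_volume_provider = 2L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    provider_plan = tibble::as_tibble(provider_plan),
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction,
    intervention_mix = tibble::as_tibble(intervention_mix),
    cost_params = tibble::as_tibble(cost_params),
    mortality_model = mortality_model,
    los_mean = los_mean, los_sd = los_sd,
    p_secondary_hosp = p_secondary_hosp,
    p_late_hosp = p_late_hosp,
    p_late_death = p_late_death,
    currency_factor = currency_factor,
    edge_case_counts = lapply(edge_case_counts, as.integer)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_provider_plan <- function() {
  tibble::tibble(
    provider_type = c("CSC", "PSC", "SRH", "OTHER"),
    n_providers = c(13L, 32L, 40L, 8L),
    expected_volume = c(628, 340, 102, 57)
  )
}

#' @rdname sim_config
#' @export
default_intervention_mix <- function() {
  # rows: probability of each intervention given the attributed provider type
  tibble::tribble(
    ~provider_type, ~thrombectomy, ~thrombolysis, ~other,
    "CSC",   0.1406, 0.2248, 0.6346,
    "PSC",   0.0134, 0.1936, 0.7930,
    "SRH",   0.0032, 0.0243, 0.9725,
    "OTHER", 0.0022, 0.0044, 0.9934
  )
}

#' @rdname sim_config
#' @export
default_cost_params <- function() {
  tibble::tribble(
    ~intervention,   ~component,   ~meanlog, ~sdlog,
    "thrombectomy",  "primary",    log(8482), 0.414,
    "thrombolysis",  "primary",    log(1920), 0.713,
    "other",         "primary",    log(791),  0.985,
    "thrombectomy",  "other_hosp", log(6671) - 0.5, 1.0,
    "thrombolysis",  "other_hosp", log(2709) - 0.5, 1.0,
    "other",         "other_hosp", log(2011) - 0.5, 1.0,
    "thrombectomy",  "outpatient", log(465),  1.78,
    "thrombolysis",  "outpatient", log(481),  1.04,
    "other",         "outpatient", log(433),  1.03
  )
}

#' @rdname sim_config
#' @export
default_mortality_model <- function() {
  # intercept/offsets solved so that the age-integrated (marginal) 90-day
  # mortality under the default truncated-normal age distribution is
  # 29.3% / 14.9% / 14.4% for thrombectomy / thrombolysis / other
  list(
    intercept = -2.0707,
    age_per_decade = 0.7,
    ref_age = 70,
    offsets = c(thrombectomy = 1.0102, thrombolysis = 0.0439, other = 0)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1L) abort("`n_patients` must be positive.", class = "stroke90_config_error")
  if (!cfg$study_start < cfg$study_end)
    abort("`study_start` must precede `study_end`.", class = "stroke90_config_error")
  if (as.integer(cfg$study_end - cfg$study_start) < 90L)
    abort("The study window must span at least 90 days.", class = "stroke90_config_error")
  pp <- cfg$provider_plan
  if (!all(c("provider_type", "n_providers", "expected_volume") %in% names(pp)))
    abort("`provider_plan` needs provider_type, n_providers, expected_volume.", class = "stroke90_config_error")
  if (any(pp$n_providers < 0) || any(pp$expected_volume < 0))
    abort("Provider counts and volumes must be non-negative.", class = "stroke90_config_error")
  if (!all(pp$provider_type %in% PROVIDER_TYPES))
    abort("Unknown provider type in `provider_plan`.", class = "stroke90_config_error")
  mix <- cfg$intervention_mix
  rs <- rowSums(mix[, INTERVENTIONS])
  if (any(abs(rs - 1) > 1e-9))
    abort("Each `intervention_mix` row must sum to 1.", class = "stroke90_config_error")
  if (any(mix[, INTERVENTIONS] < 0))
    abort("Intervention probabilities must be non-negative.", class = "stroke90_config_error")
  probs <- c(cfg$female_fraction, cfg$p_secondary_hosp, cfg$p_late_hosp, cfg$p_late_death)
  if (any(probs < 0 | probs > 1))
    abort("Fractions must lie in [0, 1].", class = "stroke90_config_error")
  if (any(cfg$cost_params$sdlog < 0))
    abort("`sdlog` must be non-negative.", class = "stroke90_config_error")
  if (any(unlist(cfg$edge_case_counts) < 0))
    abort("Edge-case counts must be non-negative.", class = "stroke90_config_error")
  invisible(cfg)
}

# normal truncated below at `lower`, via rejection (tail mass below 18 is
# ~2e-5 at the default parameters, so this loops essentially once)
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

death_probability <- function(age, intervention, model) {
  lp <- model$intercept +
    model$age_per_decade * (age - model$ref_age) / 10 +
    unname(model$offsets[as.character(intervention)])
  plogis(lp)
}

#' Generate a synthetic claims world
#'
#' Draws internally consistent patient, provider, hospitalization-claim and
#' outpatient-claim tables from a [sim_config()]. Every regular patient has
#' exactly one index-eligible I63 hospitalization; secondary
#' hospitalizations and outpatient claims are placed both inside and
#' outside the 90-day episode window; deaths follow a logistic model in age
#' and intervention; configured edge cases (under-18 admissions, repeated
#' I63 admissions, admissions with fewer than 90 follow-up days, low-volume
#' providers) are injected on top.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `claims_world` with tibbles `patients`
#'   (patient_id, birth_date, sex, death_date), `providers` (provider_id,
#'   provider_type), `hosp_claims` (claim_id, patient_id, provider_id,
#'   admission_date, discharge_date, main_dx, has_thrombectomy,
#'   has_thrombolysis, cost) and `outpatient_claims` (claim_id, patient_id,
#'   service_date, cost), plus the `config` used.
#' @export
generate_world <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  ec <- config$edge_case_counts
  providers <- make_providers(config$provider_plan, ec$low_volume_provider)

  # ---- regular patients -------------------------------------------------
  n <- config$n_patients
  reg <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = rnorm_trunc(n, config$age_mean, config$age_sd, 18),
    sex = ifelse(runif(n) < config$female_fraction, "F", "M")
  )
  regular_prov <- providers[!providers$low_volume, ]
  reg$provider_id <- sample(regular_prov$provider_id, n, replace = TRUE,
                            prob = regular_prov$expected_volume)
  last_index_day <- config$study_end - 90L
  reg$index_date <- config$study_start +
    floor(runif(n) * (as.integer(last_index_day - config$study_start) + 1L))

  # ---- injected edge cases ---------------------------------------------
  edge <- list()
  if (ec$under18 > 0L) {
    edge$under18 <- tibble::tibble(
      patient_id = sprintf("PU%05d", seq_len(ec$under18)),
      age = runif(ec$under18, 2, 17.5),
      sex = ifelse(runif(ec$under18) < config$female_fraction, "F", "M"),
      provider_id = sample(regular_prov$provider_id, ec$under18, replace = TRUE,
                           prob = regular_prov$expected_volume),
      index_date = config$study_start +
        floor(runif(ec$under18) * (as.integer(last_index_day - config$study_start) + 1L))
    )
  }
  if (ec$late_index > 0L) {
    edge$late_index <- tibble::tibble(
      patient_id = sprintf("PL%05d", seq_len(ec$late_index)),
      age = rnorm_trunc(ec$late_index, config$age_mean, config$age_sd, 18),
      sex = ifelse(runif(ec$late_index) < config$female_fraction, "F", "M"),
      provider_id = sample(regular_prov$provider_id, ec$late_index, replace = TRUE,
                           prob = regular_prov$expected_volume),
      # admission with < 90 follow-up days before study_end
      index_date = config$study_end - 89L +
        floor(runif(ec$late_index) * 89)
    )
  }
  if (ec$low_volume_provider > 0L) {
    lv <- providers[providers$low_volume, ]
    n_lv <- 10L * nrow(lv)
    edge$low_volume <- tibble::tibble(
      patient_id = sprintf("PV%05d", seq_len(n_lv)),
      age = rnorm_trunc(n_lv, config$age_mean, config$age_sd, 18),
      sex = ifelse(runif(n_lv) < config$female_fraction, "F", "M"),
      provider_id = rep(lv$provider_id, each = 10L),
      index_date = config$study_start +
        floor(runif(n_lv) * (as.integer(last_index_day - config$study_start) + 1L))
    )
  }
  pts <- dplyr::bind_rows(c(list(regular = reg), edge))

  pts <- dplyr::left_join(pts, providers[, c("provider_id", "provider_type")],
                          by = "provider_id")

  # intervention given provider type
  mix <- config$intervention_mix
  mix_m <- as.matrix(mix[, INTERVENTIONS])
  rownames(mix_m) <- mix$provider_type
  u <- runif(nrow(pts))
  cum <- t(apply(mix_m, 1, cumsum))
  row <- match(pts$provider_type, rownames(cum))
  pts$intervention <- INTERVENTIONS[
    1L + (u > cum[cbind(row, 1)]) + (u > cum[cbind(row, 2)])]

  # birth date consistent with the drawn (continuous) age at admission
  pts$birth_date <- pts$index_date - round(pts$age * 365.25)

  # 90-day vital status from the logistic mortality model
  p_die <- death_probability(pts$age, pts$intervention, config$mortality_model)
  died90 <- runif(nrow(pts)) < p_die
  death_offset <- rep(NA_integer_, nrow(pts))
  death_offset[died90] <- as.integer(floor(runif(sum(died90)) * 90))  # day 0..89
  late_death <- !died90 & runif(nrow(pts)) < config$p_late_death
  death_offset[late_death] <- as.integer(90 + floor(runif(sum(late_death)) * 276))
  pts$death_date <- pts$index_date + death_offset

  # ---- primary hospitalization claims ----------------------------------
  los <- pmax(0L, as.integer(round(rgamma(nrow(pts),
    shape = (config$los_mean / config$los_sd)^2,
    rate = config$los_mean / config$los_sd^2))))
  cp <- cost_lookup(config$cost_params)
  primary_cost <- rlnorm(nrow(pts),
                         cp$meanlog[paste(pts$intervention, "primary")],
                         cp$sdlog[paste(pts$intervention, "primary")])
  dx_codes <- c("I63.0", "I63.3", "I63.4", "I63.5", "I63.8", "I63.9")
  has_tby <- pts$intervention == "thrombectomy"
  # bridging thrombolysis before thrombectomy: both flags set
  has_lysis <- pts$intervention == "thrombolysis" | (has_tby & runif(nrow(pts)) < 0.4)

  hosp <- tibble::tibble(
    patient_id = pts$patient_id,
    provider_id = pts$provider_id,
    admission_date = pts$index_date,
    discharge_date = pts$index_date + los,
    main_dx = sample(dx_codes, nrow(pts), replace = TRUE,
                     prob = c(0.05, 0.10, 0.10, 0.15, 0.05, 0.55)),
    has_thrombectomy = has_tby,
    has_thrombolysis = has_lysis,
    cost = primary_cost * config$currency_factor
  )

  # ---- secondary hospitalizations (in and out of window) ---------------
  surv_days <- ifelse(is.na(death_offset), Inf, death_offset)
  sec <- runif(nrow(pts)) < config$p_secondary_hosp
  sec_offset <- 1L + as.integer(floor(runif(nrow(pts)) * 89))  # day 1..89
  sec <- sec & sec_offset <= surv_days
  if (any(sec)) {
    sec_cost <- rlnorm(sum(sec),
                       cp$meanlog[paste(pts$intervention[sec], "other_hosp")],
                       cp$sdlog[paste(pts$intervention[sec], "other_hosp")])
    sec_los <- pmax(0L, as.integer(round(rgamma(sum(sec), shape = 1.2, rate = 0.2))))
    hosp_sec <- tibble::tibble(
      patient_id = pts$patient_id[sec],
      provider_id = pts$provider_id[sec],
      admission_date = pts$index_date[sec] + sec_offset[sec],
      discharge_date = pts$index_date[sec] + sec_offset[sec] + sec_los,
      main_dx = sample(c("I69.3", "J18.9", "I63.9", "N39.0"), sum(sec),
                       replace = TRUE, prob = c(0.5, 0.2, 0.1, 0.2)),
      has_thrombectomy = FALSE, has_thrombolysis = FALSE,
      cost = sec_cost * config$currency_factor
    )
  } else hosp_sec <- NULL

  late <- runif(nrow(pts)) < config$p_late_hosp
  late_offset <- 90L + as.integer(floor(runif(nrow(pts)) * 181))  # day 90..270
  late <- late & late_offset <= surv_days &
    (pts$index_date + late_offset) <= config$study_end
  if (any(late)) {
    hosp_late <- tibble::tibble(
      patient_id = pts$patient_id[late],
      provider_id = pts$provider_id[late],
      admission_date = pts$index_date[late] + late_offset[late],
      discharge_date = pts$index_date[late] + late_offset[late] + 5L,
      main_dx = sample(c("I69.3", "J18.9"), sum(late), replace = TRUE),
      has_thrombectomy = FALSE, has_thrombolysis = FALSE,
      cost = rlnorm(sum(late), log(1500), 0.8) * config$currency_factor
    )
  } else hosp_late <- NULL

  # repeated I63 admission well after the index (earliest must win)
  if (ec$repeat_index > 0L) {
    eligible <- which(is.na(death_offset))
    take <- head(eligible, ec$repeat_index)
    off2 <- 100L + as.integer(floor(runif(length(take)) * 200))
    adm2 <- pmin(pts$index_date[take] + off2, config$study_end)
    hosp_rep <- tibble::tibble(
      patient_id = pts$patient_id[take],
      provider_id = pts$provider_id[take],
      admission_date = adm2,
      discharge_date = adm2 + 7L,
      main_dx = "I63.9",
      has_thrombectomy = FALSE, has_thrombolysis = FALSE,
      cost = rlnorm(length(take), log(1200), 0.7) * config$currency_factor
    )
  } else hosp_rep <- NULL

  hosp_claims <- dplyr::bind_rows(hosp, hosp_sec, hosp_late, hosp_rep)
  hosp_claims <- dplyr::bind_cols(
    tibble::tibble(claim_id = seq_len(nrow(hosp_claims))), hosp_claims)

  # ---- outpatient claims ------------------------------------------------
  outp_total <- rlnorm(nrow(pts),
                       cp$meanlog[paste(pts$intervention, "outpatient")],
                       cp$sdlog[paste(pts$intervention, "outpatient")])
  k <- 1L + as.integer(floor(runif(nrow(pts)) * 3))  # 1..3 claims in window
  idx <- rep(seq_len(nrow(pts)), k)
  w <- runif(length(idx))
  share <- w / rep(tapply(w, idx, sum)[as.character(seq_len(nrow(pts)))], k)
  max_day <- pmin(89, surv_days)[idx]
  outp <- tibble::tibble(
    patient_id = pts$patient_id[idx],
    service_date = pts$index_date[idx] +
      as.integer(floor(runif(length(idx)) * (max_day + 1))),
    cost = outp_total[idx] * share * config$currency_factor
  )
  post <- is.na(death_offset) & runif(nrow(pts)) < 0.5
  post_date <- pts$index_date + 90L + as.integer(floor(runif(nrow(pts)) * 91))
  post <- post & post_date <= config$study_end
  if (any(post)) {
    outp_post <- tibble::tibble(
      patient_id = pts$patient_id[post],
      service_date = post_date[post],
      cost = rlnorm(sum(post), log(120), 0.9) * config$currency_factor
    )
    outp <- dplyr::bind_rows(outp, outp_post)
  }
  outp <- dplyr::bind_cols(tibble::tibble(claim_id = seq_len(nrow(outp))), outp)

  world <- list(
    patients = pts[, c("patient_id", "birth_date", "sex", "death_date")],
    providers = providers[, c("provider_id", "provider_type")],
    hosp_claims = hosp_claims,
    outpatient_claims = outp,
    config = config
  )
  class(world) <- "claims_world"
  world
}

make_providers <- function(plan, n_low_volume) {
  regular <- purrr::pmap_dfr(plan, function(provider_type, n_providers, expected_volume) {
    if (n_providers == 0L) return(NULL)
    tibble::tibble(
      provider_id = sprintf("%s%02d", provider_type, seq_len(n_providers)),
      provider_type = provider_type,
      expected_volume = expected_volume,
      low_volume = FALSE
    )
  })
  if (n_low_volume > 0L) {
    lv <- tibble::tibble(
      provider_id = sprintf("LV%02d", seq_len(n_low_volume)),
      provider_type = "SRH",
      expected_volume = 0,
      low_volume = TRUE
    )
    regular <- dplyr::bind_rows(regular, lv)
  }
  regular
}

cost_lookup <- function(cost_params) {
  key <- paste(cost_params$intervention, cost_params$component)
  list(meanlog = setNames(cost_params$meanlog, key),
       sdlog = setNames(cost_params$sdlog, key))
}

#' @export
print.claims_world <- function(x, ...) {
  cat("<claims_world>\n")
  cat("  patients:          ", nrow(x$patients), "\n")
  cat("  providers:         ", nrow(x$providers), "\n")
  cat("  hosp claims:       ", nrow(x$hosp_claims), "\n")
  cat("  outpatient claims: ", nrow(x$outpatient_claims), "\n")
  invisible(x)
}
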