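#' Build 90-day episode records for a cohort
#'
#' Aggregates payer costs and vital status over the episode window for each
#' index event. The window is half-open: a claim belongs to the episode iff
#' its admission (or service) date falls in
#' `[index_date, index_date + horizon_days)`; day 1 is the admission day
#' itself. The full cost of an in-window hospitalization is counted even if
#' discharge falls after the window (claims are indivisible payer units).
#'
#' @param events Index-event tibble from [select_index_events()] /
#'   [apply_volume_filter()].
#' @param hosp_claims,outpatient_claims Claim tibbles (see
#'   [generate_world()] for the schema).
#' @param patients Patient tibble with `patient_id`, `death_date`.
#' @param horizon_days Episode length in days (default 90).
#' @return The `events` tibble with added columns `cost_primary`,
#'   `cost_other_hosp`, `cost_outpatient`, `cost_total` (their exact sum)
#'   and `died_90d`.
#' @export
build_episodes <- function(events, hosp_claims, outpatient_claims, patients,
                           horizon_days = 90L) {
  if (horizon_days < 1L)
    abort("`horizon_days` must be at least 1.", class = "stroke90_config_error")
  if (any(hosp_claims$cost < 0, na.rm = TRUE) ||
      any(outpatient_claims$cost < 0, na.rm = TRUE))
    abort("Negative claim costs are a data integrity violation.",
          class = "stroke90_integrity_error")

  primary <- hosp_claims[, c("claim_id", "cost")]
  names(primary) <- c("primary_claim_id", "cost_primary")
  ep <- dplyr::left_join(events, primary, by = "primary_claim_id")
  if (any(is.na(ep$cost_primary)))
    abort("Index event references a missing primary claim.",
          class = "stroke90_integrity_error")

  win <- events[, c("patient_id", "index_date", "primary_claim_id")]

  oh <- dplyr::inner_join(
    hosp_claims[, c("claim_id", "patient_id", "admission_date", "cost")],
    win, by = "patient_id", relationship = "many-to-many")
  oh <- oh[oh$claim_id != oh$primary_claim_id &
             oh$admission_date >= oh$index_date &
             oh$admission_date < oh$index_date + horizon_days, ]
  oh_sum <- dplyr::summarise(dplyr::group_by(oh, .data$patient_id),
                             cost_other_hosp = sum(.data$cost))

  op <- dplyr::inner_join(
    outpatient_claims[, c("patient_id", "service_date", "cost")],
    win, by = "patient_id", relationship = "many-to-many")
  op <- op[op$service_date >= op$index_date &
             op$service_date < op$index_date + horizon_days, ]
  op_sum <- dplyr::summarise(dplyr::group_by(op, .data$patient_id),
                             cost_outpatient = sum(.data$cost))

  ep <- dplyr::left_join(ep, oh_sum, by = "patient_id")
  ep <- dplyr::left_join(ep, op_sum, by = "patient_id")
  ep$cost_other_hosp[is.na(ep$cost_other_hosp)] <- 0
  ep$cost_outpatient[is.na(ep$cost_outpatient)] <- 0
  ep$cost_total <- ep$cost_primary + ep$cost_other_hosp + ep$cost_outpatient

  ep <- dplyr::left_join(ep, patients[, c("patient_id", "death_date")],
                         by = "patient_id")
  if (any(!is.na(ep$death_date) & ep$death_date < ep$index_date))
    abort("Death date precedes the index admission.",
          class = "stroke90_integrity_error")
  ep$died_90d <- compute_mortality_flag(ep$index_date, ep$death_date,
                                        horizon_days)
  ep$death_date <- NULL
  ep
}

#' Episode cost components for a single index event
#'
#' Convenience wrapper around the same window logic as [build_episodes()].
#'
#' @param index_event One-row tibble with `patient_id`, `index_date`,
#'   `primary_claim_id`.
#' @inheritParams build_episodes
#' @return Named list with `cost_primary`, `cost_other_hosp`,
#'   `cost_outpatient`, `cost_total`.
#' @export
compute_episode_costs <- function(index_event, hosp_claims, outpatient_claims,
                                  horizon_days = 90L) {
  stopifnot(nrow(index_event) == 1L)
  fake_patients <- tibble::tibble(patient_id = index_event$patient_id,
                                  death_date = as.Date(NA))
  ep <- build_episodes(index_event, hosp_claims, outpatient_claims,
                       fake_patients, horizon_days)
  as.list(ep[, c("cost_primary", "cost_other_hosp", "cost_outpatient",
                 "cost_total")])
}

#' 90-day all-cause mortality flag
#'
#' TRUE iff a death date exists and falls strictly within `horizon_days`
#' days of the index admission (half-open window: a death exactly at
#' offset `horizon_days` counts as survival). Death on the index day
#' (offset 0) counts as a 90-day death.
#'
#' @param index_date,death_date `Date` vectors (death may be `NA`).
#' @param horizon_days Episode length in days (default 90).
#' @return Logical vector.
#' @export
compute_mortality_flag <- function(index_date, death_date, horizon_days = 90L) {
  !is.na(death_date) &
    as.numeric(death_date - index_date) < horizon_days
}
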