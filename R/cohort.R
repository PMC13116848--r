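#' Select index events from hospitalization claims
#'
#' Applies the cohort operationalization: among each patient's
#' hospitalizations with a main diagnosis of ischemic stroke (ICD-10 "I63"
#' or any I63.x subcode) inside the study window, the earliest admission is
#' the index event and its admission day anchors the 90-day episode.
#' Patients younger than 18 at the index admission are excluded, as are
#' patients whose index admission leaves fewer than 90 follow-up days
#' before `study_end`. Same-day ties are broken by the lower claim id.
#'
#' Age at index is computed as `floor((index_date - birth_date) / 365.25)`
#' years; length of stay as `discharge_date - admission_date` in whole days.
#'
#' @param hosp_claims Tibble of hospitalization claims (`claim_id`,
#'   `patient_id`, `provider_id`, `admission_date`, `discharge_date`,
#'   `main_dx`, `has_thrombectomy`, `has_thrombolysis`, `cost`).
#' @param patients Tibble with `patient_id`, `birth_date`, `sex`.
#' @param study_start,study_end `Date` bounds of the study window.
#' @param providers Optional tibble with `provider_id`, `provider_type`;
#'   when supplied, the provider type is attached to each index event.
#' @return A list with `events` (one row per retained patient:
#'   `patient_id`, `index_date`, `primary_claim_id`, `provider_id`,
#'   `provider_type`, `age_at_index`, `sex`, `intervention`, `los`) and
#'   `rejects` (`patient_id`, `claim_id`, `reason` with codes `BAD_RECORD`,
#'   `UNDER18`, `LATE_INDEX`).
#' @export
select_index_events <- function(hosp_claims, patients, study_start, study_end,
                                providers = NULL) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  rejects <- tibble::tibble(patient_id = character(), claim_id = integer(),
                            reason = character())

  # malformed diagnosis codes cannot be classified: reject the claims
  malformed <- !grepl("^[A-Z][0-9]{2}", hosp_claims$main_dx) |
    is.na(hosp_claims$main_dx)
  if (any(malformed)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      patient_id = hosp_claims$patient_id[malformed],
      claim_id = hosp_claims$claim_id[malformed],
      reason = "BAD_RECORD"))
    hosp_claims <- hosp_claims[!malformed, ]
  }

  cand <- hosp_claims[grepl("^I63", hosp_claims$main_dx) &
                        hosp_claims$admission_date >= study_start &
                        hosp_claims$admission_date <= study_end, ]

  # earliest I63 admission per patient, ties to the lower claim id
  cand <- dplyr::arrange(cand, .data$patient_id, .data$admission_date,
                         .data$claim_id)
  idx <- dplyr::slice_head(dplyr::group_by(cand, .data$patient_id), n = 1L)
  idx <- dplyr::ungroup(idx)

  idx <- dplyr::left_join(
    idx, patients[, c("patient_id", "birth_date", "sex")], by = "patient_id")

  no_birth <- is.na(idx$birth_date)
  if (any(no_birth)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      patient_id = idx$patient_id[no_birth],
      claim_id = idx$claim_id[no_birth],
      reason = "BAD_RECORD"))
    idx <- idx[!no_birth, ]
  }

  idx$age_at_index <- floor(as.numeric(idx$admission_date - idx$birth_date) / 365.25)
  under18 <- idx$age_at_index < 18
  if (any(under18)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      patient_id = idx$patient_id[under18],
      claim_id = idx$claim_id[under18],
      reason = "UNDER18"))
    idx <- idx[!under18, ]
  }

  # full 90-day follow-up must fit inside the study window
  late <- idx$admission_date + 90L > study_end
  if (any(late)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      patient_id = idx$patient_id[late],
      claim_id = idx$claim_id[late],
      reason = "LATE_INDEX"))
    idx <- idx[!late, ]
  }

  events <- tibble::tibble(
    patient_id = idx$patient_id,
    index_date = idx$admission_date,
    primary_claim_id = idx$claim_id,
    provider_id = idx$provider_id,
    age_at_index = as.integer(idx$age_at_index),
    sex = idx$sex,
    intervention = classify_intervention(idx$has_thrombectomy,
                                         idx$has_thrombolysis),
    los = as.integer(idx$discharge_date - idx$admission_date)
  )
  if (!is.null(providers)) {
    events <- dplyr::left_join(
      events, providers[, c("provider_id", "provider_type")], by = "provider_id")
    events <- dplyr::relocate(events, "provider_type", .after = "provider_id")
  }
  list(events = events, rejects = rejects)
}

#' Classify the reperfusion intervention of an index hospitalization
#'
#' Thrombectomy takes precedence over thrombolysis when both procedure
#' flags are set (bridging therapy); patients with neither flag are the
#' "other treatment" (no reperfusion) group, so the three labels partition
#' any cohort.
#'
#' @param has_thrombectomy,has_thrombolysis Logical vectors (NA treated as
#'   FALSE).
#' @return Factor with levels `thrombectomy`, `thrombolysis`, `other`.
#' @export
classify_intervention <- function(has_thrombectomy, has_thrombolysis) {
  tby <- !is.na(has_thrombectomy) & has_thrombectomy
  lys <- !is.na(has_thrombolysis) & has_thrombolysis
  factor(ifelse(tby, "thrombectomy", ifelse(lys, "thrombolysis", "other")),
         levels = INTERVENTIONS)
}

#' Exclude low-volume providers
#'
#' Removes all index events attributed to providers with fewer than
#' `min_volume` index patients. Counts are taken once on the input (no
#' iterative re-filtering).
#'
#' @param events Index-event tibble from [select_index_events()].
#' @param min_volume Minimum number of index patients a provider must have
#'   (default 30); providers with fewer are dropped entirely.
#' @return List with `events` (kept rows) and `excluded_providers`
#'   (`provider_id`, `n`).
#' @export
apply_volume_filter <- function(events, min_volume = 30L) {
  if (min_volume < 1L)
    abort("`min_volume` must be at least 1.", class = "stroke90_config_error")
  counts <- dplyr::count(events, .data$provider_id)
  low <- counts[counts$n < min_volume, ]
  list(
    events = events[!events$provider_id %in% low$provider_id, ],
    excluded_providers = low
  )
}
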