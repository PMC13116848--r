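#' Read and write claim tables as CSV
#'
#' The on-disk interchange format is four CSV files with ISO-8601 dates:
#' `patients.csv` (patient_id, birth_date, sex, death_date),
#' `providers.csv` (provider_id, provider_type), `hosp_claims.csv`
#' (claim_id, patient_id, provider_id, admission_date, discharge_date,
#' main_dx, has_thrombectomy, has_thrombolysis, cost) and
#' `outpatient_claims.csv` (claim_id, patient_id, service_date, cost).
#'
#' @param world A `claims_world` from [generate_world()], or any list with
#'   the four tables.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_world()` returns the file paths invisibly;
#'   `read_world()` returns a `claims_world`-shaped list.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "providers.csv",
                            "hosp_claims.csv", "outpatient_claims.csv"))
  readr::write_csv(world$patients, paths[1], na = "")
  readr::write_csv(world$providers, paths[2], na = "")
  readr::write_csv(world$hosp_claims, paths[3], na = "")
  readr::write_csv(world$outpatient_claims, paths[4], na = "")
  invisible(paths)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  world <- list(
    patients = readr::read_csv(
      file.path(dir, "patients.csv"),
      col_types = readr::cols(patient_id = "c", birth_date = "D",
                              sex = "c", death_date = "D")),
    providers = readr::read_csv(
      file.path(dir, "providers.csv"),
      col_types = readr::cols(provider_id = "c", provider_type = "c")),
    hosp_claims = readr::read_csv(
      file.path(dir, "hosp_claims.csv"),
      col_types = readr::cols(claim_id = "i", patient_id = "c",
                              provider_id = "c", admission_date = "D",
                              discharge_date = "D", main_dx = "c",
                              has_thrombectomy = "l", has_thrombolysis = "l",
                              cost = "d")),
    outpatient_claims = readr::read_csv(
      file.path(dir, "outpatient_claims.csv"),
      col_types = readr::cols(claim_id = "i", patient_id = "c",
                              service_date = "D", cost = "d"))
  )
  class(world) <- "claims_world"
  world
}

#' Serialize a reference model to/from CSV
#'
#' @param model A [fit_reference()] object (stratum method only).
#' @param path CSV path.
#' @return `read_reference()` returns a `ref_model`.
#' @export
write_reference <- function(model, path) {
  stopifnot(inherits(model, "ref_model"))
  out <- model$bands
  out$overall_rate <- model$overall_rate
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  bands <- readr::read_csv(path, col_types = readr::cols(
    lower = "d", upper = "d", n = "d", deaths = "d", rate = "d",
    overall_rate = "d"))
  model <- list(
    bands = bands[, c("lower", "upper", "n", "deaths", "rate")],
    overall_rate = bands$overall_rate[1],
    age_bands = c(bands$lower, Inf),
    method = "strata"
  )
  class(model) <- "ref_model"
  model
}
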