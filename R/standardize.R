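#' Fit the reference mortality model for indirect age standardization
#'
#' The reference population is the whole analyzed cohort. The default
#' estimator tabulates the 90-day death rate within half-open age bands;
#' strata with no members fall back to the overall rate. A logistic
#' alternative (`method = "logistic"`, death ~ age) is available for users
#' who prefer a smooth risk curve; the stratum estimator is the default
#' for transparency.
#'
#' @param episodes Episode tibble with `age_at_index` and `died_90d`.
#' @param age_bands Increasing numeric vector of band lower bounds starting
#'   at 18 and ending with `Inf`; band `[b_k, b_{k+1})` is half-open.
#' @param method `"strata"` (default) or `"logistic"`.
#' @return Object of class `ref_model`: `bands` (lower, upper, n, deaths,
#'   rate), `overall_rate`, `age_bands`, `method` and, for the logistic
#'   variant, the fitted `glm`.
#' @export
fit_reference <- function(episodes, age_bands = DEFAULT_AGE_BANDS,
                          method = c("strata", "logistic")) {
  method <- match.arg(method)
  if (nrow(episodes) == 0L)
    abort("Cannot fit a reference model on an empty cohort.",
          class = "stroke90_empty_error")
  stopifnot(is.numeric(age_bands), !is.unsorted(age_bands, strictly = TRUE),
            is.infinite(age_bands[length(age_bands)]))
  if (any(episodes$age_at_index < age_bands[1]))
    abort("Ages below the first band bound; cohort filters were not applied.",
          class = "stroke90_integrity_error")

  band <- findInterval(episodes$age_at_index, age_bands)
  k <- length(age_bands) - 1L
  n <- tabulate(band, nbins = k)
  deaths <- as.numeric(tapply(episodes$died_90d, factor(band, levels = seq_len(k)),
                              sum, default = 0))
  overall <- sum(episodes$died_90d) / nrow(episodes)
  rate <- ifelse(n > 0, deaths / n, overall)

  model <- list(
    bands = tibble::tibble(lower = age_bands[-length(age_bands)],
                           upper = age_bands[-1],
                           n = n, deaths = deaths, rate = rate),
    overall_rate = overall,
    age_bands = age_bands,
    method = method
  )
  if (method == "logistic") {
    model$fit <- glm(died_90d ~ age_at_index, family = binomial(),
                     data = episodes)
  }
  class(model) <- "ref_model"
  model
}

#' Expected probability of 90-day death given age
#'
#' Looks up the reference rate of the (half-open) age band containing each
#' age — ages on a band's lower bound belong to that band — or, for a
#' logistic reference model, evaluates the fitted risk curve.
#'
#' @param age Numeric vector of ages (years), all at least 18.
#' @param model A [fit_reference()] object.
#' @return Probabilities in \[0, 1\].
#' @export
expected_probability <- function(age, model) {
  stopifnot(inherits(model, "ref_model"))
  if (any(age < model$age_bands[1]))
    abort("Age below the reference model's support; under-18 patients must be excluded upstream.",
          class = "stroke90_integrity_error")
  if (model$method == "logistic") {
    p <- predict(model$fit, newdata = data.frame(age_at_index = age),
                 type = "response")
    return(unname(pmin(1, pmax(0, p))))
  }
  model$bands$rate[findInterval(age, model$age_bands)]
}

#' Indirectly age-standardized 90-day mortality
#'
#' For each group, observed deaths O are compared with expected deaths
#' E = sum of the reference probabilities of the group's patients, and the
#' standardized rate is (O / E) x overall reference rate. When a group's
#' age mix equals the reference mix the standardized rate equals the crude
#' rate. Rates above 1 (possible for small groups with large O/E) are not
#' truncated; a warning is emitted.
#'
#' @param episodes Episode tibble (`age_at_index`, `died_90d`, plus any
#'   grouping columns).
#' @param model A [fit_reference()] object.
#' @param by Character vector of grouping columns; `NULL` summarizes the
#'   whole input as one group.
#' @return Tibble with the grouping columns plus `n`, `observed`,
#'   `expected`, `crude`, `standardized`.
#' @export
standardized_mortality <- function(episodes, model, by = NULL) {
  if (nrow(episodes) == 0L)
    abort("Cannot standardize an empty group.", class = "stroke90_empty_error")
  if (!is.null(by) && !all(by %in% names(episodes)))
    abort(paste0("Unknown grouping column(s): ",
                 paste(setdiff(by, names(episodes)), collapse = ", ")),
          class = "stroke90_config_error")
  episodes$.p_exp <- expected_probability(episodes$age_at_index, model)
  grouped <- dplyr::group_by(episodes, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    observed = sum(.data$died_90d),
    expected = sum(.data$.p_exp),
    crude = .data$observed / .data$n,
    .groups = "drop")
  zero_e <- out$expected <= 0
  if (any(zero_e)) {
    # a single-group call has no rate to report at all; in grouped use the
    # offending groups get NA so the remaining providers are still usable
    if (is.null(by))
      abort("The group has zero expected deaths; the standardized rate is undefined.",
            class = "stroke90_undefined_error")
    warn(paste0(sum(zero_e), " group(s) with zero expected deaths; ",
                "standardized rate set to NA."))
  }
  out$standardized <- ifelse(zero_e, NA_real_,
                             out$observed / out$expected * model$overall_rate)
  if (any(out$standardized > 1, na.rm = TRUE))
    warn("Standardized mortality exceeds 1 for at least one (small) group.")
  out
}
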