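#' Effective cost per survivor (ECPS)
#'
#' ECPS = sum(C_i) / (N - D): the total 90-day cost of a group divided by
#' its number of 90-day survivors. With no deaths it equals the mean cost;
#' it is strictly increasing in D for a fixed positive total cost. It is
#' undefined when nobody survives.
#'
#' @param costs Numeric vector of per-patient total 90-day costs (EUR).
#' @param deaths Number of 90-day deaths D, `0 <= D <= length(costs)`.
#' @return ECPS in EUR.
#' @export
compute_ecps <- function(costs, deaths) {
  n <- length(costs)
  if (n < 1L) abort("ECPS needs at least one patient.", class = "stroke90_empty_error")
  if (any(costs < 0)) abort("Costs must be non-negative.", class = "stroke90_integrity_error")
  if (deaths < 0 || deaths != round(deaths))
    abort("`deaths` must be a non-negative integer.", class = "stroke90_integrity_error")
  if (deaths > n)
    abort("More deaths than patients.", class = "stroke90_integrity_error")
  if (deaths == n)
    abort("ECPS is undefined when there are no survivors.",
          class = "stroke90_undefined_error")
  sum(costs) / (n - deaths)
}

#' Group summary table (cohort characteristics, costs, mortality, ECPS)
#'
#' One row per group with patient count, deaths, mean age and length of
#' stay, crude (and optionally age-standardized) 90-day mortality, cost
#' statistics for every component and the total (mean, SD, median,
#' quartiles; quartiles by linear interpolation between order statistics,
#' R quantile type 7), and ECPS computed from actual 90-day deaths.
#' Single-patient groups report SD 0. All proportions are returned as
#' 0-1 values; use [format_group_summary()] for display rounding.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param by Character vector of grouping columns (e.g. `"intervention"`,
#'   `"provider_type"`, `"provider_id"`); `NULL` summarizes everything as
#'   one group.
#' @param ref_model Optional [fit_reference()] model; adds
#'   `standardized_mortality`.
#' @return Tibble of group summaries.
#' @export
summarize_groups <- function(episodes, by = NULL, ref_model = NULL) {
  if (nrow(episodes) == 0L)
    abort("Cannot summarize an empty cohort.", class = "stroke90_empty_error")
  if (!is.null(by) && !all(by %in% names(episodes)))
    abort(paste0("Unknown grouping column(s): ",
                 paste(setdiff(by, names(episodes)), collapse = ", ")),
          class = "stroke90_config_error")

  cost_stats <- function(x, prefix) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    out <- list(mean(x), if (length(x) > 1L) sd(x) else 0,
                q[2], q[1], q[3])
    names(out) <- paste0(prefix, c("_mean", "_sd", "_median", "_q25", "_q75"))
    out
  }

  grouped <- dplyr::group_by(episodes, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    deaths = sum(.data$died_90d),
    mean_age = mean(.data$age_at_index),
    mean_los = mean(.data$los),
    crude_mortality = deaths / n,
    tibble::as_tibble(cost_stats(.data$cost_total, "cost_total")),
    tibble::as_tibble(cost_stats(.data$cost_primary, "cost_primary")),
    tibble::as_tibble(cost_stats(.data$cost_other_hosp, "cost_other_hosp")),
    tibble::as_tibble(cost_stats(.data$cost_outpatient, "cost_outpatient")),
    ecps = if (deaths < n) sum(.data$cost_total) / (n - deaths) else NA_real_,
    .groups = "drop")

  if (!is.null(ref_model)) {
    std <- standardized_mortality(episodes, ref_model, by = by)
    if (is.null(by)) {
      out$standardized_mortality <- std$standardized
    } else {
      out <- dplyr::left_join(
        out, std[, c(by, "standardized")], by = by)
      out <- dplyr::rename(out, standardized_mortality = "standardized")
    }
    out <- dplyr::relocate(out, "standardized_mortality",
                           .after = "crude_mortality")
  }
  out
}

#' Display formatting for counts, shares and summary tables
#'
#' `format_count_pct()` renders "11,076 (47%)"-style cells: percentages
#' below 0.1% print as "<0.1%", below 10% with one decimal, otherwise as
#' whole percent. `format_group_summary()` rounds costs to whole EUR and
#' mortality to one decimal percent; internal values keep full precision.
#'
#' @param count,total Non-negative counts.
#' @return Character vector.
#' @export
format_count_pct <- function(count, total) {
  paste0(formatC(count, format = "d", big.mark = ","),
         " (", format_pct(count / total), ")")
}

#' @rdname format_count_pct
#' @param p Proportion in \[0, 1\].
#' @export
format_pct <- function(p) {
  pct <- 100 * p
  dplyr::case_when(
    pct > 0 & pct < 0.1 ~ "<0.1%",
    pct < 10 ~ paste0(formatC(pct, format = "f", digits = 1), "%"),
    TRUE ~ paste0(formatC(round(pct), format = "d"), "%")
  )
}

#' @rdname format_count_pct
#' @param summary A [summarize_groups()] tibble.
#' @export
format_group_summary <- function(summary) {
  out <- summary
  for (col in names(out)) {
    if (grepl("^(cost_|ecps)", col)) {
      out[[col]] <- formatC(round(out[[col]]), format = "d", big.mark = ",")
    } else if (grepl("mortality$", col)) {
      out[[col]] <- paste0(formatC(100 * out[[col]], format = "f", digits = 1), "%")
    } else if (col %in% c("mean_age", "mean_los")) {
      out[[col]] <- formatC(out[[col]], format = "f", digits = 1)
    }
  }
  out
}
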