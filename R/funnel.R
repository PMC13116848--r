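#' Funnel-plot control limits
#'
#' Control limits around a common target, plotted against a precision
#' parameter, following Spiegelhalter's construction for institutional
#' comparison. Three indicator families are supported:
#'
#' * `proportion_limits()`: exact binomial limits for event proportions
#'   (e.g. crude 90-day mortality) around target `theta0`, with the
#'   continuity interpolation that makes nominal coverage approximately
#'   `1 - alpha` rather than conservative. For tail target `p` the
#'   interpolated quantile is `r - lambda`, where `r` is the smallest
#'   integer with binomial CDF `F(r) >= p` and
#'   `lambda = (F(r) - p) / (F(r) - F(r - 1))`; the limit is this quantile
#'   divided by `n`.
#' * `ratio_limits()`: exact interpolated Poisson limits for standardized
#'   event ratios O/E around target 1, against expected count `E`.
#' * `mean_limits()`: normal-theory limits `mu0 +/- z * sigma0 / sqrt(n)`
#'   for continuous indicators (mean 90-day cost) around the cohort grand
#'   mean, with `sigma0` the pooled within-unit SD; optionally computed on
#'   the log scale and exponentiated.
#'
#' Default alpha levels are two-sided 0.05 and 0.002 (the 95% and 99.8%
#' bands). Limits are clamped to the indicator's support (proportions to
#' \[0, 1\], ratios to non-negative values).
#'
#' @param n_grid,E_grid Precisions at which to evaluate the curves: unit
#'   sizes (`n >= 1`) or expected event counts (`E > 0`).
#' @param theta0 Target proportion, strictly inside (0, 1).
#' @param mu0,sigma0 Target mean and between-patient SD (`sigma0 > 0`).
#' @param alphas Two two-sided significance levels in (0, 1).
#' @param phi Multiplicative overdispersion factor (default 1 = none, the
#'   basic in-control scenario). Values above 1 widen the bands by
#'   `sqrt(phi)`; for the discrete families this switches the limits to
#'   the normal approximation with inflated standard error, since exact
#'   binomial/Poisson quantiles have no overdispersed analogue. Estimate
#'   it from the data with [dispersion_phi()].
#' @param log_scale For `mean_limits()`: treat `mu0`/`sigma0` as log-scale
#'   parameters and exponentiate the limits.
#' @return Object of class `funnel_limits` with a long-format `grid`
#'   (`level`, `precision`, `lower`, `upper`), the `target`, and the family
#'   parameters needed to recompute limits at any precision.
#' @name funnel_limits
NULL

check_alphas <- function(alphas) {
  if (length(alphas) != 2L || any(alphas <= 0 | alphas >= 1))
    abort("`alphas` must be two two-sided levels strictly inside (0, 1).",
          class = "stroke90_config_error")
  sort(alphas, decreasing = TRUE)  # inner band first
}

# interpolated quantile of a discrete CDF, applied to both tail targets:
# r = smallest integer with F(r) >= p, lambda = (F(r) - p)/(F(r) - F(r-1)),
# quantile = r - lambda. This continuity interpolation makes the achieved
# coverage of the band approximately the nominal level instead of
# conservative; for a symmetric distribution the two quantiles satisfy
# q(p) + q(1-p) = n - 1 exactly (symmetry up to the 1/n discreteness
# offset of a count scale).
interp_quantile <- function(p, qfun, cdf) {
  r <- qfun(p)
  f_r <- cdf(r)
  f_rm1 <- cdf(r - 1)
  r - (f_r - p) / (f_r - f_rm1)
}

#' @rdname funnel_limits
#' @export
proportion_limits <- function(n_grid, theta0, alphas = c(0.05, 0.002),
                              phi = 1) {
  if (theta0 <= 0 || theta0 >= 1)
    abort("`theta0` must lie strictly inside (0, 1).", class = "stroke90_config_error")
  if (any(n_grid < 1))
    abort("Unit sizes must be at least 1.", class = "stroke90_config_error")
  if (phi < 1)
    abort("`phi` must be at least 1.", class = "stroke90_config_error")
  n_grid <- unique(pmax(1, round(n_grid)))  # binomial denominators are counts
  alphas <- check_alphas(alphas)
  grid <- purrr::map_dfr(alphas, function(a) {
    if (phi > 1) {
      half <- qnorm(1 - a / 2) * sqrt(phi * theta0 * (1 - theta0) / n_grid)
      lo <- n_grid * (theta0 - half)
      hi <- n_grid * (theta0 + half)
    } else {
      lo <- interp_quantile(a / 2, function(p) qbinom(p, n_grid, theta0),
                            function(r) pbinom(r, n_grid, theta0))
      hi <- interp_quantile(1 - a / 2, function(p) qbinom(p, n_grid, theta0),
                            function(r) pbinom(r, n_grid, theta0))
    }
    tibble::tibble(level = 1 - a, precision = n_grid,
                   lower = pmax(0, lo / n_grid),
                   upper = pmin(1, hi / n_grid))
  })
  new_funnel_limits("proportion", target = theta0, alphas = alphas,
                    grid = grid, params = list(theta0 = theta0, phi = phi))
}

#' @rdname funnel_limits
#' @export
ratio_limits <- function(E_grid, alphas = c(0.05, 0.002), phi = 1) {
  if (any(E_grid <= 0))
    abort("Expected counts must be positive.", class = "stroke90_config_error")
  if (phi < 1)
    abort("`phi` must be at least 1.", class = "stroke90_config_error")
  alphas <- check_alphas(alphas)
  grid <- purrr::map_dfr(alphas, function(a) {
    if (phi > 1) {
      half <- qnorm(1 - a / 2) * sqrt(phi * E_grid)
      lo <- E_grid - half
      hi <- E_grid + half
    } else {
      lo <- interp_quantile(a / 2, function(p) qpois(p, E_grid),
                            function(r) ppois(r, E_grid))
      hi <- interp_quantile(1 - a / 2, function(p) qpois(p, E_grid),
                            function(r) ppois(r, E_grid))
    }
    tibble::tibble(level = 1 - a, precision = E_grid,
                   lower = pmax(0, lo / E_grid),
                   upper = hi / E_grid)
  })
  new_funnel_limits("ratio", target = 1, alphas = alphas, grid = grid,
                    params = list(phi = phi))
}

#' @rdname funnel_limits
#' @export
mean_limits <- function(n_grid, mu0, sigma0, alphas = c(0.05, 0.002),
                        phi = 1, log_scale = FALSE) {
  if (sigma0 <= 0)
    abort("`sigma0` must be positive.", class = "stroke90_config_error")
  if (any(n_grid < 1))
    abort("Unit sizes must be at least 1.", class = "stroke90_config_error")
  if (phi < 1)
    abort("`phi` must be at least 1.", class = "stroke90_config_error")
  alphas <- check_alphas(alphas)
  grid <- purrr::map_dfr(alphas, function(a) {
    z <- qnorm(1 - a / 2)
    half <- z * sqrt(phi) * sigma0 / sqrt(n_grid)
    lo <- mu0 - half
    hi <- mu0 + half
    if (log_scale) { lo <- exp(lo); hi <- exp(hi) }
    tibble::tibble(level = 1 - a, precision = n_grid, lower = lo, upper = hi)
  })
  new_funnel_limits("mean", target = if (log_scale) exp(mu0) else mu0,
                    alphas = alphas, grid = grid,
                    params = list(mu0 = mu0, sigma0 = sigma0, phi = phi,
                                  log_scale = log_scale))
}

#' Overdispersion factor from winsorized z-scores
#'
#' Estimates the multiplicative overdispersion of funnel points as the
#' mean squared winsorized z-score: each unit's naive z-score
#' `(value - target) / SE(precision)` is winsorized at the `winsor` and
#' `1 - winsor` quantiles (so genuine outliers do not inflate the
#' estimate), squared and averaged. Values near 1 indicate the basic
#' in-control model fits; pass values above 1 to the `phi` argument of
#' the limit constructors to widen the bands accordingly.
#'
#' @param points Tibble with `precision` and `value` (see [flag_units()]).
#' @param curve A `funnel_limits` object supplying target and dispersion.
#' @param winsor Winsorization tail fraction (default 0.1).
#' @return A single number; below 1 means underdispersion.
#' @export
dispersion_phi <- function(points, curve, winsor = 0.1) {
  se <- switch(curve$family,
    proportion = sqrt(curve$params$theta0 * (1 - curve$params$theta0) /
                        points$precision),
    ratio = sqrt(1 / points$precision),
    mean = curve$params$sigma0 / sqrt(points$precision))
  z <- (points$value - curve$target) / se
  q <- quantile(z, c(winsor, 1 - winsor), type = 7)
  z <- pmin(pmax(z, q[1]), q[2])
  mean(z^2)
}

new_funnel_limits <- function(family, target, alphas, grid, params) {
  structure(list(family = family, target = target, alphas = alphas,
                 grid = grid, params = params),
            class = "funnel_limits")
}

#' @export
print.funnel_limits <- function(x, ...) {
  cat("<funnel_limits>", x$family, "funnel around target",
      format(x$target), "\n")
  cat("  levels:", paste0(100 * (1 - x$alphas), "%", collapse = ", "),
      " grid:", length(unique(x$grid$precision)), "precisions\n")
  invisible(x)
}

# exact limits of an existing curve at arbitrary precisions (the plotting
# grid is cosmetic; flagging always recomputes at the unit's own precision)
limits_at <- function(curve, precision) {
  switch(curve$family,
    proportion = proportion_limits(precision, curve$params$theta0,
                                   curve$alphas, phi = curve$params$phi),
    ratio = ratio_limits(precision, curve$alphas, phi = curve$params$phi),
    mean = mean_limits(precision, curve$params$mu0, curve$params$sigma0,
                       curve$alphas, phi = curve$params$phi,
                       log_scale = curve$params$log_scale)
  )$grid
}

level_tag <- function(alpha) gsub("[.]", "", sprintf("%g", 100 * (1 - alpha)))

#' Flag units against funnel control limits
#'
#' Each unit is compared with limits computed exactly at its own precision
#' (the curve's grid is extended as needed, never extrapolated). Points on
#' a limit count as inside (closed band); falling outside the outer band
#' implies being outside the inner one.
#'
#' @param points Tibble with columns `unit`, `precision`, `value` (and any
#'   extras, e.g. a `label` for coloring).
#' @param curve A `funnel_limits` object.
#' @return `points` with added `flag` (`inside`, `outside_95`,
#'   `outside_998` for the default levels) and `direction` (`high`/`low`,
#'   `NA` when inside).
#' @export
flag_units <- function(points, curve) {
  stopifnot(all(c("unit", "precision", "value") %in% names(points)))
  if (any(points$precision <= 0))
    abort("Point precisions must be positive.", class = "stroke90_config_error")
  inner_a <- curve$alphas[1]
  outer_a <- curve$alphas[2]
  key <- if (curve$family == "proportion")
    pmax(1, round(points$precision)) else points$precision
  lims <- limits_at(curve, key)
  inner <- lims[lims$level == 1 - inner_a, ]
  outer <- lims[lims$level == 1 - outer_a, ]
  ii <- match(key, inner$precision)
  oi <- match(key, outer$precision)

  out_outer_hi <- points$value > outer$upper[oi]
  out_outer_lo <- points$value < outer$lower[oi]
  out_inner_hi <- points$value > inner$upper[ii]
  out_inner_lo <- points$value < inner$lower[ii]

  flag <- rep("inside", nrow(points))
  flag[out_inner_hi | out_inner_lo] <- paste0("outside_", level_tag(inner_a))
  flag[out_outer_hi | out_outer_lo] <- paste0("outside_", level_tag(outer_a))
  direction <- rep(NA_character_, nrow(points))
  direction[out_inner_hi] <- "high"
  direction[out_inner_lo] <- "low"

  points$flag <- factor(flag, levels = c("inside",
                                         paste0("outside_", level_tag(inner_a)),
                                         paste0("outside_", level_tag(outer_a))))
  points$direction <- direction
  points
}

#' Build funnel points from episode data
#'
#' Helpers that aggregate an episode table into one point per unit for the
#' three indicator families: crude mortality proportion against unit size,
#' standardized mortality ratio O/E against expected deaths, and mean cost
#' against unit size.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param unit Column identifying the compared units (default provider).
#' @param label Optional column carried along for coloring (e.g. provider
#'   type); `NULL` to omit.
#' @param model A [fit_reference()] object (ratio family only).
#' @param cost_col Cost column for the mean family.
#' @return Tibble with `unit`, `label`, `precision`, `value`.
#' @name funnel_points
NULL

#' @rdname funnel_points
#' @export
funnel_points_proportion <- function(episodes, unit = "provider_id",
                                     label = "provider_type") {
  pts <- dplyr::summarise(
    dplyr::group_by(episodes, unit = .data[[unit]],
                    label = if (is.null(label)) NA_character_ else .data[[label]]),
    precision = dplyr::n(),
    value = sum(.data$died_90d) / dplyr::n(),
    .groups = "drop")
  pts
}

#' @rdname funnel_points
#' @export
funnel_points_ratio <- function(episodes, model, unit = "provider_id",
                                label = "provider_type") {
  episodes$.p_exp <- expected_probability(episodes$age_at_index, model)
  dplyr::summarise(
    dplyr::group_by(episodes, unit = .data[[unit]],
                    label = if (is.null(label)) NA_character_ else .data[[label]]),
    precision = sum(.data$.p_exp),
    value = sum(.data$died_90d) / sum(.data$.p_exp),
    .groups = "drop")
}

#' @rdname funnel_points
#' @export
funnel_points_mean <- function(episodes, cost_col = "cost_total",
                               unit = "provider_id", label = "provider_type") {
  dplyr::summarise(
    dplyr::group_by(episodes, unit = .data[[unit]],
                    label = if (is.null(label)) NA_character_ else .data[[label]]),
    precision = dplyr::n(),
    value = mean(.data[[cost_col]]),
    .groups = "drop")
}

#' Pooled within-unit standard deviation
#'
#' Dispersion parameter for cost funnels: the square root of the
#' (n_j - 1)-weighted mean of within-unit variances.
#'
#' @inheritParams funnel_points_mean
#' @return A single non-negative number.
#' @export
pooled_sd <- function(episodes, cost_col = "cost_total", unit = "provider_id") {
  w <- dplyr::summarise(
    dplyr::group_by(episodes, unit = .data[[unit]]),
    n = dplyr::n(), v = if (dplyr::n() > 1) stats::var(.data[[cost_col]]) else 0,
    .groups = "drop")
  sqrt(sum((w$n - 1) * w$v) / sum(pmax(w$n - 1, 0)))
}

#' Plot a funnel
#'
#' Renders points and dotted control-limit curves with ggplot2 (points
#' colored by `label` when present).
#'
#' @param points Output of [flag_units()] or a `funnel_points_*()` helper.
#' @param curve A `funnel_limits` object.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_funnel <- function(points, curve, xlab = "precision", ylab = "indicator") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("`ggplot2` is required for plotting.")
  grid <- dplyr::arrange(curve$grid, .data$level, .data$precision)
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = grid,
      ggplot2::aes(x = .data$precision, y = .data$lower,
                   group = factor(.data$level), color = factor(.data$level)),
      linetype = "dotted") +
    ggplot2::geom_line(data = grid,
      ggplot2::aes(x = .data$precision, y = .data$upper,
                   group = factor(.data$level), color = factor(.data$level)),
      linetype = "dotted") +
    ggplot2::geom_hline(yintercept = curve$target, linewidth = 0.3) +
    ggplot2::labs(x = xlab, y = ylab, color = "level", shape = NULL) +
    ggplot2::theme_minimal()
  if ("label" %in% names(points) && !all(is.na(points$label))) {
    p <- p + ggplot2::geom_point(data = points,
      ggplot2::aes(x = .data$precision, y = .data$value, shape = .data$label))
  } else {
    p <- p + ggplot2::geom_point(data = points,
      ggplot2::aes(x = .data$precision, y = .data$value))
  }
  p
}
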