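# independent brute-force oracle: cumulative sums of the mass function and
# a linear scan for the smallest r with F(r) >= p, then the same
# continuity interpolation
brute_limits <- function(pmf_vals, p) {
  F <- cumsum(pmf_vals)           # F[k] = P(X <= k-1)
  r <- which(F >= p)[1] - 1
  f_r <- F[r + 1]
  f_rm1 <- if (r == 0) 0 else F[r]
  r - (f_r - p) / (f_r - f_rm1)
}

test_that("binomial limits match exhaustive CDF enumeration for all n <= 50", {
  theta0 <- 0.15
  for (a in c(0.05, 0.002)) {
    for (n in 1:50) {
      pmf <- dbinom(0:n, n, theta0)
      lo <- max(0, brute_limits(pmf, a / 2)) / n
      hi <- min(n, brute_limits(pmf, 1 - a / 2)) / n
      g <- proportion_limits(n, theta0, c(0.05, 0.002))$grid
      row <- g[g$level == 1 - a, ]
      expect_equal(row$lower, max(0, lo), tolerance = 1e-9)
      expect_equal(row$upper, min(1, hi), tolerance = 1e-9)
    }
  }
})

test_that("Poisson ratio limits match exhaustive CDF enumeration for all E <= 50", {
  for (a in c(0.05, 0.002)) {
    for (E in c(0.5, 1:50)) {
      pmf <- dpois(0:400, E)
      lo <- max(0, brute_limits(pmf, a / 2)) / E
      hi <- brute_limits(pmf, 1 - a / 2) / E
      g <- ratio_limits(E, c(0.05, 0.002))$grid
      row <- g[g$level == 1 - a, ]
      expect_equal(row$lower, lo, tolerance = 1e-9)
      expect_equal(row$upper, hi, tolerance = 1e-9)
    }
  }
})

test_that("exact limits converge to the normal approximation at large n", {
  n <- 1e5
  th <- 0.15
  g <- proportion_limits(n, th)$grid
  z95 <- qnorm(0.975); z998 <- qnorm(0.999)
  se <- sqrt(th * (1 - th) / n)
  expect_equal(g$upper[g$level == 0.95], th + z95 * se, tolerance = 1e-3)
  expect_equal(g$lower[g$level == 0.95], th - z95 * se, tolerance = 1e-3)
  expect_equal(g$upper[g$level == 0.998], th + z998 * se, tolerance = 1e-3)

  E <- 1e5
  r <- ratio_limits(E)$grid
  expect_equal(r$upper[r$level == 0.95], 1 + z95 / sqrt(E), tolerance = 1e-3)
  expect_equal(r$lower[r$level == 0.95], 1 - z95 / sqrt(E), tolerance = 1e-3)
})

test_that("even-odds limits are symmetric up to the count-scale discreteness offset", {
  # the interpolated binomial quantiles satisfy q(p) + q(1-p) = n - 1
  # exactly when theta0 = 0.5, so limits mirror about (n-1)/(2n) wherever
  # the lower limit is not clamped at the 0 boundary
  for (n in c(7, 20, 37, 101, 250)) {
    g <- proportion_limits(n, 0.5)$grid
    free <- g$lower > 0
    expect_equal(g$lower[free] + g$upper[free],
                 rep((n - 1) / n, sum(free)), tolerance = 1e-12)
    expect_equal(g$lower[!free], rep(0, sum(!free)))
    expect_gt(sum(free), 0)
  }
})

test_that("mean-cost limits follow the z / sqrt(n) law, on raw and log scales", {
  g1 <- mean_limits(1, mu0 = 100, sigma0 = 10)$grid
  expect_equal(g1$upper[g1$level == 0.95], 100 + qnorm(0.975) * 10,
               tolerance = 1e-9)
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)

  g <- mean_limits(c(25, 100), mu0 = 100, sigma0 = 10)$grid
  w25 <- with(g[g$level == 0.95 & g$precision == 25, ], upper - lower)
  w100 <- with(g[g$level == 0.95 & g$precision == 100, ], upper - lower)
  expect_equal(w25, 2 * w100)   # quadrupling n halves the half-width

  gl <- mean_limits(16, mu0 = 7, sigma0 = 0.8, log_scale = TRUE)
  expect_equal(gl$grid$upper[gl$grid$level == 0.95],
               exp(7 + qnorm(0.975) * 0.8 / 4), tolerance = 1e-9)
  expect_equal(gl$target, exp(7))

  expect_error(mean_limits(10, 100, 0), class = "stroke90_config_error")
})

test_that("in-control units fall outside the mean-cost band at the nominal rate", {
  set.seed(808)
  n_units <- 1e4
  n_per <- 30
  mu0 <- 3000; sigma0 <- 900
  means <- rnorm(n_units, mu0, sigma0 / sqrt(n_per))
  pts <- tibble::tibble(unit = seq_len(n_units), precision = n_per,
                        value = means)
  fl <- flag_units(pts, mean_limits(n_per, mu0, sigma0))
  out95 <- mean(fl$flag != "inside")
  expect_lt(abs(out95 - 0.05), 0.01)
  expect_lt(mean(fl$flag == "outside_998"), 0.006)
})

test_that("flags agree with pointwise limit recomputation and boundary convention", {
  # a point exactly on a limit is inside (closed band)
  lim <- mean_limits(25, 100, 10)
  g95 <- lim$grid[lim$grid$level == 0.95, ]
  on_limit <- tibble::tibble(unit = 1, precision = 25, value = g95$upper)
  expect_identical(as.character(flag_units(on_limit, lim)$flag), "inside")

  above998 <- tibble::tibble(unit = 1, precision = 25, value = 1e6)
  fl <- flag_units(above998, lim)
  expect_identical(as.character(fl$flag), "outside_998")
  expect_identical(fl$direction, "high")

  # randomized fixture vs direct comparison at each point's own precision
  set.seed(909)
  ns <- sample(10:500, 150, replace = TRUE)
  vals <- rbinom(150, ns, 0.2) / ns
  pts <- tibble::tibble(unit = seq_len(150), precision = ns, value = vals)
  curve <- proportion_limits(c(10, 500), 0.2)
  fl <- flag_units(pts, curve)
  for (i in seq_len(150)) {
    g <- proportion_limits(ns[i], 0.2)$grid
    l95 <- g[g$level == 0.95, ]; l998 <- g[g$level == 0.998, ]
    want <- if (vals[i] > l998$upper || vals[i] < l998$lower) "outside_998"
      else if (vals[i] > l95$upper || vals[i] < l95$lower) "outside_95"
      else "inside"
    expect_identical(as.character(fl$flag[i]), want)
  }
  # outside the outer band implies outside the inner band
  outer <- fl[fl$flag == "outside_998", ]
  if (nrow(outer) > 0) {
    lims95 <- proportion_limits(outer$precision, 0.2)$grid
    l95 <- lims95[lims95$level == 0.95, ]
    m <- match(outer$precision, l95$precision)
    expect_true(all(outer$value > l95$upper[m] | outer$value < l95$lower[m]))
  }
})

test_that("bands nest and narrow monotonically in precision", {
  for (curve in list(proportion_limits(5:300, 0.15),
                     ratio_limits(seq(0.5, 60, by = 0.5)),
                     mean_limits(1:300, 1000, 300))) {
    g95 <- curve$grid[curve$grid$level == min(curve$grid$level), ]
    g998 <- curve$grid[curve$grid$level == max(curve$grid$level), ]
    # inner band within outer band, target within both
    expect_true(all(g998$lower <= g95$lower + 1e-12))
    expect_true(all(g95$upper <= g998$upper + 1e-12))
    expect_true(all(g95$lower <= curve$target & curve$target <= g95$upper))
    # monotone narrowing along the precision grid; for the discrete
    # families this holds exactly once the lower limit leaves the clamped
    # zero boundary (below it, the band is one-sided and its width follows
    # the upper limit's discreteness)
    for (g in list(g95, g998)) {
      g <- g[order(g$precision), ]
      g <- g[g$lower > 0, ]
      expect_true(all(diff(g$upper - g$lower) <= 1e-9))
    }
  }
})

test_that("overdispersion estimation and inflation behave as documented", {
  set.seed(1010)
  ns <- rep(200, 400)
  # in-control proportions: phi near 1
  pts_ok <- tibble::tibble(unit = seq_along(ns), precision = ns,
                           value = rbinom(length(ns), ns, 0.15) / ns)
  curve <- proportion_limits(200, 0.15)
  phi_ok <- dispersion_phi(pts_ok, curve)
  expect_lt(abs(phi_ok - 1), 0.35)

  # true between-unit heterogeneity inflates phi well above 1
  theta_j <- plogis(rnorm(length(ns), qlogis(0.15), 0.4))
  pts_od <- tibble::tibble(unit = seq_along(ns), precision = ns,
                           value = rbinom(length(ns), ns, theta_j) / ns)
  phi_od <- dispersion_phi(pts_od, curve)
  expect_gt(phi_od, 2)

  # inflated limits widen by sqrt(phi) and still nest
  infl <- proportion_limits(200, 0.15, phi = phi_od)
  base <- proportion_limits(200, 0.15)
  for (lev in c(0.95, 0.998)) {
    bi <- infl$grid[infl$grid$level == lev, ]
    bb <- base$grid[base$grid$level == lev, ]
    expect_gt(bi$upper - bi$lower, bb$upper - bb$lower)
  }
  g95 <- infl$grid[infl$grid$level == 0.95, ]
  g998 <- infl$grid[infl$grid$level == 0.998, ]
  expect_true(g998$lower <= g95$lower && g95$upper <= g998$upper)
  # with phi, limits follow the inflated normal approximation exactly
  expect_equal(g95$upper,
               0.15 + qnorm(0.975) * sqrt(phi_od * 0.15 * 0.85 / 200),
               tolerance = 1e-12)

  # flagging through a phi-inflated curve recomputes inflated limits
  fl <- flag_units(pts_od, infl)
  expect_true(mean(fl$flag == "inside") > mean(
    flag_units(pts_od, base)$flag == "inside"))

  expect_error(proportion_limits(10, 0.5, phi = 0.8),
               class = "stroke90_config_error")
  expect_error(mean_limits(10, 100, 10, phi = 0.5),
               class = "stroke90_config_error")
  gm <- mean_limits(25, 100, 10, phi = 4)$grid
  gm1 <- mean_limits(25, 100, 10)$grid
  expect_equal(gm$upper - gm$lower, 2 * (gm1$upper - gm1$lower))
})

test_that("invalid funnel parameters are rejected", {
  expect_error(proportion_limits(10, 0), class = "stroke90_config_error")
  expect_error(proportion_limits(10, 1.2), class = "stroke90_config_error")
  expect_error(proportion_limits(0, 0.5), class = "stroke90_config_error")
  expect_error(proportion_limits(10, 0.5, alphas = c(0.05, 1.2)),
               class = "stroke90_config_error")
  expect_error(ratio_limits(0), class = "stroke90_config_error")
})
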