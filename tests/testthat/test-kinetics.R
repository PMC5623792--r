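test_that("specific growth rate is the log-OD slope over the window", {
  s <- od_series(c(0, 1), c(0.1, 0.2))
  expect_equal(specific_growth_rate(s, 0, 1), log(2))

  flat <- od_series(0:5, rep(0.4, 6))
  expect_equal(specific_growth_rate(flat, 0, 5), 0)

  # only OD ratios matter: uniform scaling leaves mu unchanged
  t <- seq(0, 10, by = 0.25)
  grow <- od_series(t, 0.1 * exp(0.3 * t))
  scaled <- od_series(t, 5 * 0.1 * exp(0.3 * t))
  expect_equal(specific_growth_rate(grow, 1, 9),
               specific_growth_rate(scaled, 1, 9))

  # endpoints between samples are interpolated in log space
  expect_equal(specific_growth_rate(grow, 1.1, 8.9), 0.3, tolerance = 1e-9)

  expect_error(specific_growth_rate(s, 1, 1), "exceed")
  expect_error(specific_growth_rate(s, -1, 1), "outside")
  withzero <- od_series(0:5, c(0.1, 0.2, 0, 0.4, 0.8, 1.6))
  expect_error(specific_growth_rate(withzero, 0, 5), "OD <= 0")
})

test_that("od_series validates its contract", {
  expect_error(od_series(c(0, 1), c(0.1)), "lengths differ")
  expect_error(od_series(c(0), c(0.1)), "at least 2")
  expect_error(od_series(c(1, 0), c(0.1, 0.2)), "increasing")
  expect_error(od_series(c(-1, 0), c(0.1, 0.2)), "non-negative")
  expect_error(od_series(c(0, 1), c(-0.1, 0.2)), "non-negative")
})

test_that("log-phase detection recovers planted phase boundaries", {
  s <- sim_growth_curve(mu = 0.3, lag_h = 3, od0 = 0.1, plateau = 1.5,
                        interval_h = 0.25, duration_h = 24, noise_sd = 0)
  lp <- detect_log_phase(s)
  win <- attr(s, "log_window")
  expect_lte(abs(lp$t_start - win[1]), 0.25)
  expect_lte(abs(lp$t_end - win[2]), 0.25)
  expect_equal(lp$mu, 0.3, tolerance = 1e-9)
  # deterministic for fixed input and params
  expect_identical(lp, detect_log_phase(s))

  flat <- od_series(seq(0, 5, 0.5), rep(0.4, 11))
  expect_error(detect_log_phase(flat), "exponential phase")
  expect_error(detect_log_phase(od_series(0:4, rep(1, 5))), "at least 6")
})

test_that("generation time inverts the growth rate", {
  expect_equal(generation_time(log(2)), 1)
  expect_equal(generation_time(0.6931 / 2), 2, tolerance = 1e-4)
  expect_equal(generation_time(0.30), log(2) / 0.30)
  expect_error(generation_time(0), "mu > 0")
})

test_that("volumetric productivity reproduces endpoint-table arithmetic", {
  expect_equal(volumetric_productivity(12.2, 96), 0.127)
  expect_equal(volumetric_productivity(4.04, 96), 0.042)
  expect_equal(volumetric_productivity(0, 96), 0)
  expect_equal(volumetric_productivity(12.2, 96, digits = NULL), 12.2 / 96)
  expect_error(volumetric_productivity(1, 0), "positive")
})

test_that("lipid content is percent of cell dry weight", {
  expect_equal(lipid_content_pct(6.31, 13.5), 100 * 6.31 / 13.5)
  expect_gt(lipid_content_pct(6.31, 13.5), 46)
  expect_equal(lipid_content_pct(13.5, 13.5), 100)
  expect_equal(round(lipid_content_pct(2.80, 11.4), 1), 24.6)
  expect_error(lipid_content_pct(1, 0), "positive")
  expect_error(lipid_content_pct(2, 1), "exceed")
})

test_that("C:N:P ratios normalize to nitrogen and format stably", {
  expect_equal(cnp_ratio(c(C = 6.45, N = 1, P = 0.93))$label, "6.45 : 1 : 0.93")
  expect_equal(cnp_ratio(c(C = 24.6, N = 2, P = 0.408))$label, "12.3 : 1 : 0.204")
  expect_equal(cnp_ratio(c(C = 2, N = 2, P = 2))$label, "1 : 1 : 1")
  expect_error(cnp_ratio(c(C = 1, N = 0, P = 1)), "N must be positive")
  expect_error(cnp_ratio(c(C = 1, P = 1)), "must name")
})

test_that("the kinetics table flags and excludes impossible rows", {
  tab <- tibble::tibble(strain = c("a", "b"), medium = "m",
                        biomass_g_l = c(10, 5), lipids_g_l = c(2, 6),
                        duration_h = 96)
  expect_warning(out <- kinetics_table(tab), "lipids > biomass")
  expect_equal(out$strain, "a")
  expect_equal(out$qx_g_l_h, round(10 / 96, 3))
  expect_equal(out$lipid_pct_cdw, 20)
})
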