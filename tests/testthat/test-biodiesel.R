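test_that("unsaturation degree follows the mono/di/tri weighting", {
  sat <- fa_profile(c("C16:0" = 60, "C18:0" = 40))
  expect_equal(unsaturation_degree(sat), 0)

  p <- fa_profile(c("C16:0" = 40, "C18:1" = 30, "C18:2" = 20, "C18:3 n-3" = 10))
  expect_equal(unsaturation_degree(p), (30 + 2 * 20 + 3 * 10) / 100)

  # acids with >= 4 double bonds do not enter UD (no quad term in the formula)
  q <- fa_profile(c("C16:0" = 50, "C20:4 n-6" = 50))
  expect_equal(unsaturation_degree(q), 0)

  # invariant under normalization / uniform rescaling
  off <- suppressWarnings(fa_profile(c("C18:1" = 49.8, "C18:2" = 49.8)))
  expect_equal(unsaturation_degree(off),
               unsaturation_degree(normalize_profile(off)))
})

test_that("chain length is the weight-weighted mean carbon count", {
  expect_equal(chain_length(fa_profile(c("C16:0" = 100))), 16)
  p <- fa_profile(c("C16:0" = 25, "C18:1" = 75))
  expect_equal(chain_length(p), (16 * 25 + 18 * 75) / 100)
  off <- suppressWarnings(fa_profile(c("C16:0" = 10, "C18:1" = 30), sum_tol = 1e6))
  expect_equal(chain_length(off), (16 * 10 + 18 * 30) / 40)  # normalized first
  empty <- fa_profile(setNames(numeric(0), character(0)))
  expect_error(chain_length(empty), "empty")
})

test_that("cetane number is linear in the per-ester table", {
  tab <- tibble::tibble(label = c("C18:1", "C16:0"), cn_me = c(61, 50))
  one <- fa_profile(c("C18:1" = 100))
  expect_equal(as.numeric(cetane_number(one, tab)), 61)
  mix <- fa_profile(c("C18:1" = 50, "C16:0" = 50))
  expect_equal(as.numeric(cetane_number(mix, tab)), 55.5)

  miss <- fa_profile(c("C18:1" = 50, "C22:2" = 50))
  expect_error(cetane_number(miss, tab), "C22:2")

  # packaged default table covers the whole composition fixture and tags results
  profs <- table5_profiles()
  cn <- cetane_number(profs[[4]])
  expect_equal(attr(cn, "cetane_table_version"), "fame_cetane_v1")
  expect_equal(as.numeric(cn), oracle_cn(profs[[4]], default_cetane_table()),
               tolerance = 1e-12)
})

test_that("LCV and viscosity evaluate their stated polynomials", {
  expect_equal(low_calorific_value(0, 0), 29385.4)
  expect_equal(kinematic_viscosity(0, 0), -1.8327)
  expect_equal(low_calorific_value(17.8864, 0.8033),
               29385.4 + 486.866 * 17.8864 - 387.766 * 0.8033)
  lc <- 17.8864; ud <- 0.8033
  expect_equal(kinematic_viscosity(lc, ud),
               -1.8327 + 0.209794 * lc + 0.738911 * ud + 0.0166791 * lc^2 -
                 0.16336 * lc * ud + 0.335547 * ud^2)
})

test_that("rounding discipline: 2-dp-rounded intermediates shift LCV", {
  p <- table5_profiles()[["Debaryomyces hansenii IG 01/YPGlc"]]
  lc <- chain_length(p); ud <- unsaturation_degree(p)
  full <- low_calorific_value(lc, ud)
  from_rounded <- low_calorific_value(round(lc, 2), round(ud, 2))
  # the unrounded route lands on the published value; the rounded one does not
  expect_lte(abs(full - 37782.18), 0.01)
  expect_gt(abs(from_rounded - 37782.18), 0.5)
})

test_that("UD/LC monotonicity under composition shifts", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_profile(8)
    ud0 <- unsaturation_degree(p)
    # adding weight to a tri-unsaturated acid (then renormalizing implicitly
    # via the internal total) never decreases UD
    tri <- "C18:3"
    e <- p$entries
    e[tri] <- (if (tri %in% names(e)) e[[tri]] else 0) + 10
    bumped <- suppressWarnings(fa_profile(e, sum_tol = 1e6))
    expect_gte(unsaturation_degree(bumped) + 1e-12, ud0)
  }
  # shifting weight from C16 to C18 acids never decreases LC
  p <- fa_profile(c("C16:0" = 60, "C18:0" = 40))
  for (shift in c(0, 10, 30, 60)) {
    p2 <- suppressWarnings(fa_profile(c("C16:0" = 60 - shift,
                                        "C18:0" = 40 + shift)))
    expect_gte(chain_length(p2) + 1e-12, chain_length(p))
  }
})

test_that("flash point models are explicit and never mixed", {
  p <- table5_profiles()[[1]]
  none <- flash_point(p, model = "none")
  expect_true(is.na(none))
  expect_equal(attr(none, "fp_model"), "none")

  tab <- tibble::tibble(label = "C18:1", fp_c = 163)
  one <- fa_profile(c("C18:1" = 100))
  expect_equal(as.numeric(flash_point(one, fp_table = tab)), 163)
  expect_error(flash_point(p, model = "quadratic"), "arg")
})

test_that("the full panel runs on the packaged fixture and renders reports", {
  profs <- table5_profiles()
  panel <- biodiesel_panel(profs)
  expect_equal(nrow(panel), 7)
  expect_true(all(panel$LCV_kJ_per_kg > 0))
  expect_true(all(panel$UD >= 0))
  # LC within the carbon range of each profile's acids
  for (i in seq_along(profs)) {
    rng <- range(profs[[i]]$acids$carbons)
    expect_gte(panel$LC[i], rng[1]); expect_lte(panel$LC[i], rng[2])
  }
  empty <- fa_profile(setNames(numeric(0), character(0)))
  expect_error(biodiesel_properties(empty), "empty")

  rep <- format_fuel_report(panel, decimal = ",")
  dh <- rep[rep$strain == "Debaryomyces hansenii IG 01", ]
  expect_equal(dh$UD, "0,80")
  expect_equal(dh$viscosity_mm2_s, "5,72")
})
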