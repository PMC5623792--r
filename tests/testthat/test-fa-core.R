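test_that("fatty-acid labels parse, classify and round-trip", {
  fa <- parse_fa_label("C16:0")
  expect_equal(fa$carbons, 16L)
  expect_equal(fa$double_bonds, 0L)
  expect_true(is.na(fa$omega))

  fa <- parse_fa_label("C20:3 n-6")
  expect_equal(fa$carbons, 20L)
  expect_equal(fa$double_bonds, 3L)
  expect_equal(fa$omega, 6L)

  # round-trip on every label used in the packaged composition table
  labels <- c("C12:0", "C14:0", "C16:0", "C16:1", "C17:1", "C18:0", "C18:1",
              "C18:2", "C18:3 n-3", "C20:1 n-9", "C20:3 n-6", "C20:4 n-6",
              "C22:2", "C22:4", "C24:0")
  parsed <- parse_fa_label(labels)
  expect_identical(parsed$label, labels)
  expect_identical(
    format_fa_label(parsed$carbons, parsed$double_bonds, parsed$omega), labels)

  expect_error(parse_fa_label("oleic"), "malformed")
  expect_error(parse_fa_label("C18:18"), "double-bond")
  expect_error(parse_fa_label("C2:0"), "at least 4 carbons")

  expect_equal(as.character(classify_unsaturation("C18:1")), "MUFA")
  expect_equal(as.character(classify_unsaturation("C22:4")), "PUFA4")
  expect_equal(as.character(classify_unsaturation("C24:0")), "SFA")
  # the five classes partition double-bond counts exhaustively
  expect_identical(as.character(classify_unsaturation(0:6)),
                   c("SFA", "MUFA", "DUFA", "TUFA", rep("PUFA4", 3)))
})

test_that("profiles validate composition and support grouping/normalizing", {
  p <- fa_profile(c("C16:0" = 50, "C18:1" = 50))
  expect_equal(profile_total(p), 100)
  expect_equal(unname(group_totals(p)["SFA"]), 50)

  expect_error(fa_profile(c("C16:0" = -1, "C18:1" = 101)), "negative")
  expect_warning(fa_profile(c("C16:0" = 90)), "outside 100")
  expect_error(fa_profile(c("C16:0" = 90), strict = TRUE), "outside 100")

  single <- suppressWarnings(fa_profile(c("C16:0" = 99.6)))
  norm <- normalize_profile(single)
  expect_equal(unname(norm$entries), 100)
  # idempotent
  expect_equal(normalize_profile(norm)$entries, norm$entries)
  # proportions preserved
  two <- suppressWarnings(fa_profile(c("C16:0" = 1, "C18:1" = 1), sum_tol = 1000))
  expect_equal(unname(normalize_profile(two)$entries), c(50, 50))
  empty <- fa_profile(setNames(numeric(0), character(0)))
  expect_error(normalize_profile(empty), "zero total")

  # mass conservation of group totals on random compositions
  set.seed(11)
  for (i in 1:25) {
    rp <- random_profile(sample(3:12, 1))
    expect_equal(sum(group_totals(rp)), profile_total(rp), tolerance = 1e-9)
  }
})

test_that("the packaged composition table reads as seven valid profiles", {
  profs <- table5_profiles(strict = TRUE)
  expect_length(profs, 7)
  # strict mode passes: every row sums to 100 within 0.5
  sums <- vapply(profs, profile_total, numeric(1))
  expect_true(all(abs(sums - 100) <= 0.5))

  dh01 <- profs[["Debaryomyces hansenii IG 01/YPGlc"]]
  expect_equal(profile_total(dh01), 14.04 + 1.80 + 11.23 + 60.25 + 8.68 + 0.92 + 3.08)
  expect_equal(unname(group_totals(dh01)["MUFA"]), 1.80 + 60.25 + 0.92)

  # "n.d." cells become absent entries
  ku <- profs[["Kazachstania unispora IG 16/YPGlc"]]
  expect_length(ku$entries, 10)

  zf <- profs[["Zygotorulaspora florentina IG 12/YPGlc"]]
  expect_equal(unname(group_totals(zf)["TUFA"]), 0.54)
})

test_that("the reader handles comma decimals, n.d.-only rows and bad cells", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain,medium,C16:0,C18:1,C18:2",
               "a,m,\"40,5\",\"59,5\",n.d.",
               "b,m,n.d.,n.d.,n.d."), tmp)
  profs <- read_fa_profiles(tmp, decimal = ",")
  expect_equal(unname(profs[[1]]$entries), c(40.5, 59.5))
  expect_length(profs[[2]]$entries, 0)            # all n.d. -> empty profile
  expect_error(read_fa_profiles(tmp, decimal = ",", strict = TRUE),
               "no detected fatty acids")

  writeLines(c("strain,C16:0", "a,forty"), tmp)
  expect_error(suppressWarnings(read_fa_profiles(tmp)), "cannot parse")
})
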