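#' Unsaturation degree of a FAME mixture
#'
#' Weighted count of double bonds per unit weight,
#' \deqn{UD = (1\,\%MU + 2\,\%DU + 3\,\%TU)/100,}
#' where \%MU, \%DU and \%TU are the weight percentages of mono-, di- and
#' tri-unsaturated methyl esters. Acids with four or more double bonds do
#' not enter the sum: the defining formula has only mono/di/tri terms, and
#' the package stays literal to it. Profiles are normalized internally, so
#' UD is invariant under uniform rescaling of the composition.
#'
#' @param profile An [fa_profile()].
#' @return Dimensionless unsaturation degree (>= 0).
#' @examples
#' p <- fa_profile(c("C16:0" = 40, "C18:1" = 50, "C18:2" = 10))
#' unsaturation_degree(p)
#' @export
unsaturation_degree <- function(profile) {
  total <- profile_total(profile)
  if (total <= 0) stop("empty profile", call. = FALSE)
  gt <- group_totals(profile)
  unname((gt["MUFA"] + 2 * gt["DUFA"] + 3 * gt["TUFA"]) / total)
}

#' Mean chain length of a FAME mixture
#'
#' Weight-%-weighted mean carbon number,
#' \deqn{LC = \sum_n nC_n \, c_n / 100,}
#' with \eqn{nC_n} the carbon count of each fatty acid and \eqn{c_n} its
#' weight-%. Profiles not summing to 100 are normalized first.
#'
#' @param profile An [fa_profile()].
#' @return Mean chain length in carbon atoms.
#' @export
chain_length <- function(profile) {
  total <- profile_total(profile)
  if (total <= 0) stop("empty profile", call. = FALSE)
  sum(profile$acids$carbons * unname(profile$entries)) / total
}

#' Default per-ester cetane-number lookup table
#'
#' Cetane numbers of individual fatty acid methyl esters, computed from the
#' published structural correlation \eqn{CN = -7.8 + 0.302\,MW - 20\,DB}
#' (molecular weight of the methyl ester in g/mol, DB the double-bond
#' count), which tracks measured FAME cetane numbers across the chain
#' lengths used here. Shipped as a versioned plain-text file
#' (`fame_cetane_v1.csv`) and fully overridable via [read_cetane_table()].
#'
#' @return Tibble with columns `label`, `mw_fame`, `cn_me` and attribute
#'   `version`.
#' @export
default_cetane_table <- function() {
  read_cetane_table(sco_extdata("fame_cetane_v1.csv"), version = "fame_cetane_v1")
}

#' Read a per-ester cetane table
#'
#' @param path CSV with at least columns `label` and `cn_me`.
#' @param version Version tag attached to results computed with the table.
#' @return Tibble with attribute `version`.
#' @export
read_cetane_table <- function(path, version = basename(path)) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("label", "cn_me") %in% names(tab))) {
    stop("cetane table needs 'label' and 'cn_me' columns", call. = FALSE)
  }
  if (any(tab$cn_me <= 0)) stop("per-ester cetane numbers must be positive", call. = FALSE)
  tab$label <- parse_fa_label(tab$label)$label
  attr(tab, "version") <- version
  tab
}

#' Cetane number of a FAME mixture
#'
#' Weight-fraction-weighted sum of per-ester cetane numbers,
#' \eqn{CN = \sum X_{ME} CN_{ME} / 100}. The lookup must cover every acid
#' in the profile; a missing entry fails loudly naming the acid.
#'
#' @param profile An [fa_profile()].
#' @param cetane_table Lookup from [default_cetane_table()] or
#'   [read_cetane_table()].
#' @return Mixture cetane number, carrying the table's version tag as
#'   attribute `cetane_table_version`.
#' @export
cetane_number <- function(profile, cetane_table = default_cetane_table()) {
  total <- profile_total(profile)
  if (total <= 0) stop("empty profile", call. = FALSE)
  idx <- match(profile$acids$label, cetane_table$label)
  if (anyNA(idx)) {
    stop("no cetane number for: ",
         paste(sQuote(profile$acids$label[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  cn <- sum(cetane_table$cn_me[idx] * unname(profile$entries)) / total
  attr(cn, "cetane_table_version") <- attr(cetane_table, "version")
  cn
}

#' Low calorific value from chain length and unsaturation degree
#'
#' \deqn{LCV = 29385.4 + 486.866\,LC - 387.766\,UD \quad [kJ\,kg^{-1}]}
#' Both inputs must be the unrounded values computed from the same profile;
#' feeding 2-dp-rounded intermediates visibly shifts the result.
#'
#' @param lc Mean chain length (carbon atoms).
#' @param ud Unsaturation degree.
#' @return Low calorific value in kJ/kg.
#' @export
low_calorific_value <- function(lc, ud) {
  stopifnot(is.finite(lc), is.finite(ud))
  29385.4 + 486.866 * lc - 387.766 * ud
}

#' Kinematic viscosity from chain length and unsaturation degree
#'
#' Quadratic correlation in LC and UD:
#' \deqn{\mu = -1.8327 + 0.209794\,LC + 0.738911\,UD + 0.0166791\,LC^2
#'       - 0.16336\,LC\,UD + 0.335547\,UD^2 \quad [mm^2 s^{-1}]}
#'
#' @inheritParams low_calorific_value
#' @return Kinematic viscosity in mm^2/s. Named `kinematic_viscosity` to
#'   avoid the symbol clash with the specific growth rate, which shares the
#'   Greek letter mu in the bioprocess literature.
#' @export
kinematic_viscosity <- function(lc, ud) {
  stopifnot(is.finite(lc), is.finite(ud))
  -1.8327 + 0.209794 * lc + 0.738911 * ud + 0.0166791 * lc^2 -
    0.16336 * lc * ud + 0.335547 * ud^2
}

#' Default per-ester flash-point lookup
#'
#' Approximate literature flash points of individual FAMEs (degrees C),
#' shipped as `fame_flashpoint_v1.csv`. Values are vendor/safety-data-sheet
#' magnitudes intended for the mixture model of [flash_point()]; they carry
#' more uncertainty than the cetane correlations and are reported for
#' orientation only.
#'
#' @return Tibble with columns `label`, `fp_c` and attribute `version`.
#' @export
default_fp_table <- function() {
  tab <- readr::read_csv(sco_extdata("fame_flashpoint_v1.csv"),
                         show_col_types = FALSE, progress = FALSE)
  tab$label <- parse_fa_label(tab$label)$label
  attr(tab, "version") <- "fame_flashpoint_v1"
  tab
}

#' Flash point of a FAME mixture
#'
#' The package prints no single canonical flash-point equation; instead the
#' estimator is pluggable. The default `"ester_mixture"` model is the
#' weight-fraction-weighted mean of per-ester flash points from a lookup
#' table; `"none"` returns `NA` (no estimate). The result is tagged with
#' the model used, and models are never mixed silently.
#'
#' @param profile An [fa_profile()].
#' @param model `"ester_mixture"` (default) or `"none"`.
#' @param fp_table Per-ester lookup, see [default_fp_table()].
#' @return Flash point in degrees C (`NA` for model `"none"`), with
#'   attribute `fp_model`.
#' @export
flash_point <- function(profile, model = c("ester_mixture", "none"),
                        fp_table = default_fp_table()) {
  model <- match.arg(model)
  if (model == "none") {
    return(structure(NA_real_, fp_model = "none"))
  }
  total <- profile_total(profile)
  if (total <= 0) stop("empty profile", call. = FALSE)
  idx <- match(profile$acids$label, fp_table$label)
  if (anyNA(idx)) {
    stop("no flash point for: ",
         paste(sQuote(profile$acids$label[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  fp <- sum(fp_table$fp_c[idx] * unname(profile$entries)) / total
  structure(fp, fp_model = model)
}

#' Full biodiesel property panel for one profile
#'
#' Computes UD, CN, LC, LCV, FP and kinematic viscosity from a single
#' fatty-acid profile. LCV and viscosity are evaluated from the *same
#' unrounded* LC and UD; rounding happens only at reporting time
#' (round-half-to-even at 2 dp in [format_fuel_report()]).
#'
#' @param profile An [fa_profile()].
#' @param cetane_table Per-ester cetane lookup.
#' @param fp_model,fp_table Passed to [flash_point()].
#' @return One-row tibble: `strain`, `medium`, `UD`, `CN`, `LC`,
#'   `LCV_kJ_per_kg`, `FP_C`, `viscosity_mm2_s`.
#' @examples
#' p <- read_fa_profiles(sco_extdata("table5_fatty_acids.csv"))[[4]]
#' biodiesel_properties(p)
#' @export
biodiesel_properties <- function(profile, cetane_table = default_cetane_table(),
                                 fp_model = "ester_mixture",
                                 fp_table = default_fp_table()) {
  ud <- unsaturation_degree(profile)
  lc <- chain_length(profile)
  tibble::tibble(
    strain = profile$strain,
    medium = profile$medium,
    UD = ud,
    CN = as.numeric(cetane_number(profile, cetane_table)),
    LC = lc,
    LCV_kJ_per_kg = low_calorific_value(lc, ud),
    FP_C = as.numeric(flash_point(profile, fp_model, fp_table)),
    viscosity_mm2_s = kinematic_viscosity(lc, ud)
  )
}

#' Biodiesel property panel for a set of profiles
#'
#' @param profiles List of [fa_profile()] objects (e.g. from
#'   [read_fa_profiles()]).
#' @inheritParams biodiesel_properties
#' @return Tibble with one row per profile.
#' @export
biodiesel_panel <- function(profiles, cetane_table = default_cetane_table(),
                            fp_model = "ester_mixture",
                            fp_table = default_fp_table()) {
  if (inherits(profiles, "fa_profile")) profiles <- list(profiles)
  dplyr::bind_rows(lapply(profiles, biodiesel_properties,
                          cetane_table = cetane_table,
                          fp_model = fp_model, fp_table = fp_table))
}

#' Render a property panel the way fuel-property tables are printed
#'
#' Formats all properties at 2 dp (round-half-to-even after full-precision
#' computation), optionally with comma decimal separators to mirror
#' European-locale tables. CN is additionally annotated against the two
#' biodiesel-standard minima (EN 14214: 54; ASTM D6751: 47).
#'
#' @param panel Output of [biodiesel_panel()].
#' @param decimal `"."` or `","`.
#' @param digits Decimal places (default 2).
#' @return Tibble of character columns plus `CN_standards` annotation.
#' @export
format_fuel_report <- function(panel, decimal = c(".", ","), digits = 2) {
  decimal <- match.arg(decimal)
  fmt <- function(x) {
    s <- formatC(round(x, digits), format = "f", digits = digits)
    s[is.na(x)] <- ""
    if (decimal == ",") s <- gsub(".", ",", s, fixed = TRUE)
    s
  }
  tibble::tibble(
    strain = panel$strain,
    medium = panel$medium,
    UD = fmt(panel$UD),
    CN = fmt(panel$CN),
    LC = fmt(panel$LC),
    LCV_kJ_per_kg = fmt(panel$LCV_kJ_per_kg),
    FP_C = fmt(panel$FP_C),
    viscosity_mm2_s = fmt(panel$viscosity_mm2_s),
    CN_standards = ifelse(panel$CN >= 54, "EN 14214 & ASTM D6751",
                          ifelse(panel$CN >= 47, "ASTM D6751", "below both"))
  )
}
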