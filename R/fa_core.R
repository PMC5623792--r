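#' Parse fatty-acid shorthand labels
#'
#' Parses labels of the form `"C<carbons>:<double bonds>"` with an optional
#' omega-class suffix `"n-<x>"` (e.g. `"C18:3 n-3"`), the nomenclature used
#' in gas-chromatographic fatty-acid composition tables.
#'
#' Comparison of acids is by the parsed triple (carbons, double bonds,
#' omega), never by raw string, so `"C18:1"` and `"C18:1 "` refer to the
#' same acid. Odd-chain acids (e.g. `C17:1`) are first-class.
#'
#' @param label Character vector of labels.
#' @return A tibble with one row per label: `label` (canonical form),
#'   `carbons`, `double_bonds`, `omega` (`NA` when the label carries no
#'   `n-x` suffix).
#' @examples
#' parse_fa_label(c("C16:0", "C20:3 n-6"))
#' @seealso [format_fa_label()], [classify_unsaturation()]
#' @export
parse_fa_label <- function(label) {
  label <- as.character(label)
  m <- regmatches(label, regexec("^\\s*C([0-9]+):([0-9]+)(?:\\s+n-([0-9]+))?\\s*$", label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed fatty-acid label(s): ",
         paste(sQuote(label[bad]), collapse = ", "),
         " (expected 'C<carbons>:<double bonds>' with optional ' n-<x>')",
         call. = FALSE)
  }
  carbons <- vapply(m, function(x) as.integer(x[2]), integer(1))
  dbl <- vapply(m, function(x) as.integer(x[3]), integer(1))
  omega <- vapply(m, function(x) if (nzchar(x[4])) as.integer(x[4]) else NA_integer_, integer(1))
  if (any(carbons < 4)) {
    stop("fatty acids must have at least 4 carbons; offending label(s): ",
         paste(sQuote(label[carbons < 4]), collapse = ", "), call. = FALSE)
  }
  if (any(dbl > carbons / 2)) {
    off <- dbl > carbons / 2
    stop("double-bond count exceeds carbons/2 in label(s): ",
         paste(sQuote(label[off]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    label = format_fa_label(carbons, dbl, omega),
    carbons = carbons,
    double_bonds = dbl,
    omega = omega
  )
}

#' Format a fatty acid as its canonical label
#'
#' Inverse of [parse_fa_label()]: `parse -> format` round-trips on all
#' canonical labels.
#'
#' @param carbons,double_bonds Integer vectors.
#' @param omega Optional omega class (3, 6, 9, ...); `NA` omits the suffix.
#' @return Character vector of canonical labels.
#' @export
format_fa_label <- function(carbons, double_bonds, omega = NA_integer_) {
  n <- max(length(carbons), length(double_bonds), length(omega))
  carbons <- rep_len(as.integer(carbons), n)
  double_bonds <- rep_len(as.integer(double_bonds), n)
  omega <- rep_len(as.integer(omega), n)
  base <- sprintf("C%d:%d", carbons, double_bonds)
  out <- base
  out[!is.na(omega)] <- sprintf("%s n-%d", base[!is.na(omega)], omega[!is.na(omega)])
  out
}

#' Unsaturation classes
#'
#' The exhaustive, mutually exclusive partition of fatty acids by
#' double-bond count used throughout the package: saturated (SFA, 0),
#' monounsaturated (MUFA, 1), di- (DUFA, 2), tri- (TUFA, 3), and
#' polyunsaturated with four or more double bonds (PUFA4, >= 4).
#'
#' @return Character vector of the five class names, in order.
#' @export
unsat_classes <- function() c("SFA", "MUFA", "DUFA", "TUFA", "PUFA4")

#' Classify fatty acids by unsaturation
#'
#' @param x Either an integer vector of double-bond counts, a character
#'   vector of labels (parsed with [parse_fa_label()]), or a tibble with a
#'   `double_bonds` column.
#' @return Factor with levels `SFA`, `MUFA`, `DUFA`, `TUFA`, `PUFA4`.
#' @examples
#' classify_unsaturation(c("C18:1", "C22:4", "C24:0"))
#' @export
classify_unsaturation <- function(x) {
  if (is.character(x)) x <- parse_fa_label(x)
  if (is.data.frame(x)) x <- x$double_bonds
  db <- as.integer(x)
  if (any(is.na(db)) || any(db < 0)) {
    stop("double-bond counts must be non-negative integers", call. = FALSE)
  }
  cls <- unsat_classes()[pmin(db, 4L) + 1L]
  factor(cls, levels = unsat_classes())
}

#' Construct a fatty-acid profile
#'
#' A profile is a compositional vector of weight-% of total fatty acids,
#' keyed by fatty-acid label, for one strain in one medium. Entries absent
#' from the vector are "not detected" and count as exactly 0 in every sum.
#'
#' The reported sum is validated against 100 with a configurable tolerance
#' (default 0.5 percentage points, since published tables usually sum to
#' 100.00 but user data may not); outside the tolerance a warning is
#' emitted, or an error in strict mode.
#'
#' @param percent Named numeric vector; names are fatty-acid labels
#'   understood by [parse_fa_label()], values are weight-% (>= 0).
#' @param strain,medium Free-text identifiers.
#' @param sum_tol Allowed deviation of the total from 100.
#' @param strict Logical; if `TRUE`, a sum outside the tolerance (or an
#'   empty profile) is an error rather than a warning.
#' @return An object of class `fa_profile`.
#' @examples
#' p <- fa_profile(c("C16:0" = 50, "C18:1" = 50), strain = "demo")
#' profile_total(p)
#' group_totals(p)
#' @export
fa_profile <- function(percent, strain = NA_character_, medium = NA_character_,
                       sum_tol = 0.5, strict = FALSE) {
  stopifnot(is.numeric(percent))
  percent <- percent[!is.na(percent)]
  if (is.null(names(percent)) && length(percent) > 0) {
    stop("'percent' must be a named vector of weight-% keyed by fatty-acid label",
         call. = FALSE)
  }
  if (any(percent < 0)) {
    stop("negative weight-% for: ",
         paste(sQuote(names(percent)[percent < 0]), collapse = ", "),
         call. = FALSE)
  }
  acids <- if (length(percent)) parse_fa_label(names(percent)) else
    parse_fa_label(character(0))
  if (anyDuplicated(acids$label)) {
    stop("duplicate fatty-acid entries: ",
         paste(sQuote(unique(acids$label[duplicated(acids$label)])), collapse = ", "),
         call. = FALSE)
  }
  names(percent) <- acids$label
  total <- sum(percent)
  if (length(percent) == 0L || total == 0) {
    msg <- sprintf("profile %s: no detected fatty acids", strain %||% "?")
    if (strict) stop(msg, call. = FALSE)
  } else if (abs(total - 100) > sum_tol) {
    msg <- sprintf("profile %s/%s: reported sum %.3f%% is outside 100 +/- %.3g",
                   strain %||% "?", medium %||% "?", total, sum_tol)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    list(entries = percent, acids = acids,
         strain = as.character(strain), medium = as.character(medium)),
    class = "fa_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %s | %s | %d acids, total %.2f%%\n",
              x$strain %||% "?", x$medium %||% "?",
              length(x$entries), profile_total(x)))
  if (length(x$entries)) {
    print(tibble::tibble(label = names(x$entries), pct = unname(x$entries)), ...)
  }
  invisible(x)
}

#' Total weight-% of a profile
#' @param profile An [fa_profile()].
#' @return Numeric scalar (0 for an empty profile).
#' @export
profile_total <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  sum(profile$entries)
}

#' Profile entries with parsed acid identity
#'
#' @param profile An [fa_profile()].
#' @return Tibble with columns `label`, `carbons`, `double_bonds`, `omega`,
#'   `class`, `pct`.
#' @export
profile_entries <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  out <- profile$acids
  out$class <- classify_unsaturation(out$double_bonds)
  out$pct <- unname(profile$entries)
  out
}

#' Rescale a profile to sum to exactly 100
#'
#' Relative proportions are preserved; the operation is idempotent.
#'
#' @param profile An [fa_profile()].
#' @return A new `fa_profile` whose entries sum to 100 (to floating
#'   tolerance).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  total <- profile_total(profile)
  if (total <= 0) stop("cannot normalize a profile with zero total", call. = FALSE)
  profile$entries <- profile$entries / total * 100
  profile
}

#' Weight-% totals per unsaturation class
#'
#' Sums profile entries within each of the five unsaturation classes
#' ([unsat_classes()]). The totals partition the profile: their sum equals
#' [profile_total()] exactly.
#'
#' @param profile An [fa_profile()].
#' @return Named numeric vector over `SFA`, `MUFA`, `DUFA`, `TUFA`,
#'   `PUFA4` (classes with no detected acid are 0).
#' @examples
#' p <- fa_profile(c("C16:0" = 30, "C18:1" = 60, "C18:2" = 10))
#' group_totals(p)
#' @export
group_totals <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  cls <- classify_unsaturation(profile$acids$double_bonds)
  out <- setNames(numeric(length(unsat_classes())), unsat_classes())
  if (length(profile$entries)) {
    agg <- tapply(unname(profile$entries), cls, sum)
    out[names(agg)[!is.na(agg)]] <- agg[!is.na(agg)]
  }
  out
}

#' Read fatty-acid profiles from a delimited table
#'
#' Reads a wide table with one row per strain-by-medium combination and one
#' column per fatty-acid label (plus `strain` and `medium` identifier
#' columns). Cells may be numeric weight-% or the sentinel `"n.d."` (not
#' detected), which becomes an absent entry treated as exactly 0 downstream.
#'
#' @param path CSV (or TSV) file; delimiter inferred from the extension.
#' @param decimal Decimal separator in the file, `"."` (default) or `","`
#'   for tables typeset with comma decimals. Never auto-detected.
#' @param sum_tol,strict Passed to [fa_profile()].
#' @return Named list of [fa_profile()] objects (names `strain/medium`).
#' @examples
#' profiles <- read_fa_profiles(sco_extdata("table5_fatty_acids.csv"))
#' names(profiles)
#' @export
read_fa_profiles <- function(path, decimal = c(".", ","), sum_tol = 0.5,
                             strict = FALSE) {
  decimal <- match.arg(decimal)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  id_cols <- intersect(c("strain", "medium"), names(raw))
  if (!"strain" %in% id_cols) {
    stop("profile table must have a 'strain' column", call. = FALSE)
  }
  fa_cols <- setdiff(names(raw), id_cols)
  if (length(fa_cols) == 0) stop("no fatty-acid columns found", call. = FALSE)
  parse_fa_label(fa_cols)  # validate headers up front
  profiles <- lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, fa_cols, drop = TRUE]
    vals <- vapply(unlist(row), .parse_pct_cell, numeric(1), decimal = decimal)
    fa_profile(vals[!is.na(vals)],
               strain = raw$strain[i],
               medium = if ("medium" %in% id_cols) raw$medium[i] else NA_character_,
               sum_tol = sum_tol, strict = strict)
  })
  names(profiles) <- vapply(profiles, function(p) {
    paste(p$strain, p$medium, sep = "/")
  }, character(1))
  profiles
}

# One cell of a composition table: weight-% number or the n.d. sentinel.
.parse_pct_cell <- function(x, decimal = ".") {
  x <- trimws(x)
  if (is.na(x) || x == "" || tolower(gsub("[. ]", "", x)) == "nd") return(NA_real_)
  if (decimal == ",") x <- gsub(",", ".", x, fixed = TRUE)
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) stop("cannot parse composition cell ", sQuote(x), call. = FALSE)
  val
}
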