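#' Load a run configuration file
#'
#' YAML or JSON (by extension). Recognized keys: `cetane_table` (path to a
#' per-ester CN table or an inline label -> CN map), `fp_model`,
#' `sum_tol`, `gel_tol_bp`, `decimal`. Unknown keys are kept and ignored
#' by the runners.
#'
#' @param path Config file.
#' @return Named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  num_keys <- intersect(c("sum_tol", "gel_tol_bp"), names(cfg))
  for (k in num_keys) {
    if (cfg[[k]] < 0) stop("config key '", k, "' must be >= 0", call. = FALSE)
  }
  cfg
}

.resolve_cetane <- function(config) {
  ct <- config$cetane_table
  if (is.null(ct)) return(default_cetane_table())
  if (is.character(ct) && length(ct) == 1) return(read_cetane_table(ct))
  # inline label -> CN mapping
  tab <- tibble::tibble(label = names(ct), cn_me = as.numeric(unlist(ct)))
  tab$label <- parse_fa_label(tab$label)$label
  attr(tab, "version") <- "inline"
  tab
}

#' Compute a biodiesel property panel from a profile table
#'
#' End-to-end runner: reads a wide fatty-acid composition table
#' ([read_fa_profiles()]), computes the property panel
#' ([biodiesel_panel()]), and optionally writes it as tidy CSV and/or a
#' 2-dp report rendering. Profiles failing the sum tolerance produce
#' warnings (errors in strict mode).
#'
#' @param input Profile CSV (one row per strain-by-medium, columns = fatty
#'   acid labels).
#' @param output Optional path for the tidy CSV output.
#' @param config Optional list from [load_run_config()].
#' @param decimal Decimal separator of the *input* ("." or ",").
#' @param report If `TRUE`, also return (and write, as
#'   `<output>_report.csv`) the 2-dp comma-decimal rendering.
#' @param strict Passed to [read_fa_profiles()].
#' @return Tibble (the panel), invisibly when `output` is given.
#' @examples
#' run_biodiesel(sco_extdata("table5_fatty_acids.csv"))
#' @export
run_biodiesel <- function(input, output = NULL, config = list(),
                          decimal = c(".", ","), report = FALSE,
                          strict = FALSE) {
  decimal <- match.arg(decimal)
  if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
  profiles <- read_fa_profiles(input, decimal = decimal,
                               sum_tol = config$sum_tol %||na% 0.5,
                               strict = strict)
  if (length(profiles) == 0) stop("no profiles in input", call. = FALSE)
  panel <- biodiesel_panel(profiles,
                           cetane_table = .resolve_cetane(config),
                           fp_model = config$fp_model %||na% "ester_mixture")
  if (!is.null(output)) {
    readr::write_csv(panel, output)
    if (report) {
      readr::write_csv(format_fuel_report(panel, decimal = ","),
                       sub("(\\.[^.]+)?$", "_report\\1", output))
    }
    return(invisible(panel))
  }
  if (report) format_fuel_report(panel, decimal = ",") else panel
}

#' Compute productivities and lipid content from a culture table
#'
#' Runner over [read_culture_table()] + [kinetics_table()]: Q_x, Q_L
#' (3 dp) and lipid %CDW (1 dp) per row; impossible rows (lipids >
#' biomass) are excluded with a warning.
#'
#' @param input Culture endpoint CSV.
#' @param output Optional CSV path.
#' @return Tibble, invisibly when `output` is given.
#' @examples
#' head(run_kinetics(sco_extdata("table4_culture.csv")))
#' @export
run_kinetics <- function(input, output = NULL) {
  if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
  out <- kinetics_table(read_culture_table(input))
  if (!is.null(output)) {
    readr::write_csv(out, output)
    return(invisible(out))
  }
  out
}

#' Identify a strain from an observed fragment pattern
#'
#' Reads an observed pattern (JSON object with `strain`, `amplicon_bp`,
#' `fragments`), matches it against a reference database with
#' [match_pattern()], and reports the ranked candidates.
#'
#' @param pattern Path to the observed-pattern JSON, or a
#'   [digest_pattern()].
#' @param db Path to the reference database JSON (default: the packaged
#'   seven-strain kefir set), or a list of [digest_pattern()]s.
#' @param tol_bp Gel tolerance in bp.
#' @param output Optional path for the ranked matches (JSON).
#' @return Tibble of ranked matches, invisibly when `output` is given.
#' @examples
#' obs <- digest_pattern("unknown", 460,
#'                       list(HaeIII = c(290, 90, 80), RsaI = c(360, 100)))
#' run_identify(obs)
#' @export
run_identify <- function(pattern, db = sco_extdata("table2_patterns.json"),
                         tol_bp = 20, output = NULL) {
  if (is.character(pattern)) {
    pattern <- read_pattern_db(pattern)[[1]]
  }
  if (is.character(db)) db <- read_pattern_db(db)
  matches <- match_pattern(pattern, db, tol_bp = tol_bp)
  message(sprintf("top hit: %s (score %g%s)", matches$strain[1],
                  matches$score[1],
                  if (matches$consistent[1]) ", consistent" else ""))
  if (!is.null(output)) {
    jsonlite::write_json(matches, output, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(matches))
  }
  matches
}

#' Digest FASTA sequences with a set of enzymes
#'
#' @param input FASTA file of amplicon sequences.
#' @param enzymes Named list of [restriction_enzyme()]s.
#' @param output Optional CSV path.
#' @return Tibble: `id`, `length_bp`, `enzyme`, `fragments` (bp,
#'   descending, "+"-separated), `n_fragments`, `fragment_sum_bp`.
#' @examples
#' run_digest(sco_extdata("table1_its.fasta"))
#' @export
run_digest <- function(input, enzymes = builtin_enzymes(), output = NULL) {
  seqs <- read_its_fasta(input)
  rows <- lapply(names(seqs), function(id) {
    dplyr::bind_rows(lapply(enzymes, function(e) {
      f <- digest_fragments(seqs[[id]], e)
      tibble::tibble(id = id, length_bp = nchar(seqs[[id]]), enzyme = e$name,
                     fragments = paste(f, collapse = "+"),
                     n_fragments = length(f), fragment_sum_bp = sum(f))
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(output)) {
    readr::write_csv(out, output)
    return(invisible(out))
  }
  out
}

#' Write simulated inputs in the package's own file formats
#'
#' Generates synthetic fatty-acid profiles (CSV readable by
#' [read_fa_profiles()]), growth curves (long CSV readable by
#' [read_od_series()]) and sequences with planted restriction sites
#' (FASTA readable by [read_its_fasta()]), so every reader in the package
#' can be exercised round-trip without external data.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_profiles,n_curves,n_sequences How many of each to generate.
#' @param seed Integer seed; fixed seed gives identical files.
#' @param template Profile template (default: a packaged composition row).
#' @param mu,lag_h,noise_sd Growth-curve parameters (see
#'   [sim_growth_curve()]).
#' @param seq_length_bp Length of simulated sequences.
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(out_dir, n_profiles = 3, n_curves = 3,
                         n_sequences = 3, seed = 1, template = NULL,
                         mu = 0.25, lag_h = 2, noise_sd = 0.02,
                         seq_length_bp = 600) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(template)) {
    template <- read_fa_profiles(sco_extdata("table5_fatty_acids.csv"))[[4]]
  }
  files <- character(0)

  profs <- sim_fa_profiles(n_profiles, template)
  wide <- dplyr::bind_rows(lapply(seq_along(profs), function(i) {
    p <- profs[[i]]
    tibble::as_tibble(c(list(strain = sprintf("sim_%02d", i), medium = "sim"),
                        as.list(p$entries)))
  }))
  files["profiles"] <- file.path(out_dir, "sim_profiles.csv")
  readr::write_csv(wide, files["profiles"])

  curves <- dplyr::bind_rows(lapply(seq_len(n_curves), function(i) {
    s <- sim_growth_curve(mu = mu, lag_h = lag_h, noise_sd = noise_sd)
    tibble::tibble(well = sprintf("well_%02d", i), time_h = s$time_h, od = s$od)
  }))
  files["growth"] <- file.path(out_dir, "sim_growth.csv")
  readr::write_csv(curves, files["growth"])

  seqs <- vapply(seq_len(n_sequences), function(i) {
    sim_site_sequence(seq_length_bp,
                      cuts = list(HaeIII = round(seq_length_bp / 3),
                                  RsaI = round(2 * seq_length_bp / 3)))
  }, character(1))
  names(seqs) <- sprintf("sim_seq_%02d", seq_len(n_sequences))
  files["sequences"] <- file.path(out_dir, "sim_sequences.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), files["sequences"])

  invisible(files)
}
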