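#' Restriction enzyme definition
#'
#' @param name Enzyme name (e.g. `"HaeIII"`).
#' @param site Recognition site over the unambiguous DNA alphabet, length
#'   at least 4.
#' @param cut_offset Cut position within the site on the top strand: a site
#'   occurrence starting at base `s` cuts after base `s + cut_offset - 1`.
#' @return Object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HaeIII", "GGCC", 2)  # GG^CC
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- .check_dna(site, what = "recognition site")
  if (nchar(site) < 4) stop("recognition site must be at least 4 bp", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' HaeIII (GG^CC) and RsaI (GT^AC), the two blunt, palindromic cutters used
#' for ITS-amplicon yeast typing. Recognition sequences follow the standard
#' REBASE definitions (the typing protocol itself names only the enzymes).
#'
#' @return Named list of [restriction_enzyme()] objects.
#' @export
builtin_enzymes <- function() {
  list(
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2),
    RsaI   = restriction_enzyme("RsaI", "GTAC", 2)
  )
}

# Validate and uppercase an unambiguous DNA string.
.check_dna <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq)[1])
  if (is.na(seq) || !nzchar(seq)) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(what, " contains non-ACGT character(s): ",
         paste(sQuote(bad), collapse = ", "),
         " (ambiguity codes are not supported)", call. = FALSE)
  }
  seq
}

#' Find restriction cut positions in a sequence
#'
#' Scans the top strand for every (possibly overlapping) occurrence of the
#' enzyme's recognition site. Positions are between-base coordinates: a cut
#' at position `k` splits the sequence into `[1, k]` and `[k+1, n]`. Cuts
#' falling on the sequence ends (which would produce empty fragments) are
#' dropped. Scanning only the top strand is complete for palindromic sites
#' such as GGCC and GTAC.
#'
#' @param seq DNA string over A/C/G/T (case-insensitive).
#' @param enzyme A [restriction_enzyme()].
#' @return Strictly increasing integer vector of cut positions.
#' @examples
#' find_cut_sites("AAGGCCAA", builtin_enzymes()$HaeIII)  # 4
#' @export
find_cut_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  seq <- .check_dna(seq)
  n <- nchar(seq)
  k <- nchar(enzyme$site)
  if (n < k) return(integer(0))
  starts <- which(vapply(seq_len(n - k + 1L),
                         function(i) substr(seq, i, i + k - 1L) == enzyme$site,
                         logical(1)))
  cuts <- starts - 1L + enzyme$cut_offset
  sort(unique(cuts[cuts > 0L & cuts < n]))
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts at all recognition sites and returns fragment lengths in
#' descending order. Fragment lengths always sum to the input length; an
#' uncut sequence yields a single full-length fragment.
#'
#' @inheritParams find_cut_sites
#' @return Integer vector of fragment lengths, descending.
#' @examples
#' digest_fragments("AAGGCCAA", builtin_enzymes()$HaeIII)  # 4 4
#' @export
digest_fragments <- function(seq, enzyme) {
  seq <- .check_dna(seq)
  cuts <- find_cut_sites(seq, enzyme)
  sort(diff(c(0L, cuts, nchar(seq))), decreasing = TRUE)
}

#' Fragment pattern of one strain
#'
#' Bundles an amplicon size with per-enzyme fragment-length lists. For
#' in-silico digests the fragments sum exactly to the amplicon length; for
#' gel-derived reference patterns the sum may deviate by gel-estimation
#' error, which is what [pattern_consistency()] quantifies.
#'
#' @param strain Strain identifier.
#' @param amplicon_bp PCR product length in bp (> 0).
#' @param fragments Named list, one sorted-descending integer vector of
#'   fragment lengths (> 0) per enzyme.
#' @return Object of class `digest_pattern`.
#' @export
digest_pattern <- function(strain, amplicon_bp, fragments) {
  amplicon_bp <- as.integer(amplicon_bp)
  if (is.na(amplicon_bp) || amplicon_bp <= 0) stop("amplicon_bp must be positive", call. = FALSE)
  if (!is.list(fragments) || is.null(names(fragments)) || any(!nzchar(names(fragments)))) {
    stop("fragments must be a named list keyed by enzyme", call. = FALSE)
  }
  fragments <- lapply(fragments, function(f) {
    f <- as.integer(f)
    if (any(is.na(f)) || any(f <= 0)) stop("fragment lengths must be positive", call. = FALSE)
    sort(f, decreasing = TRUE)
  })
  structure(list(strain = as.character(strain), amplicon_bp = amplicon_bp,
                 fragments = fragments),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("<digest_pattern> %s, amplicon %d bp\n", x$strain, x$amplicon_bp))
  for (enz in names(x$fragments)) {
    cat(sprintf("  %s: %s\n", enz, paste(x$fragments[[enz]], collapse = " + ")))
  }
  invisible(x)
}

#' In-silico fragment pattern of a sequence
#'
#' @param seq DNA string.
#' @param strain Identifier stored on the pattern.
#' @param enzymes Named list of [restriction_enzyme()]s
#'   (default [builtin_enzymes()]).
#' @return A [digest_pattern()] whose amplicon length is `nchar(seq)`.
#' @export
digest_pattern_from_sequence <- function(seq, strain = "query",
                                         enzymes = builtin_enzymes()) {
  seq <- .check_dna(seq)
  frags <- lapply(enzymes, function(e) digest_fragments(seq, e))
  names(frags) <- vapply(enzymes, `[[`, character(1), "name")
  digest_pattern(strain, nchar(seq), frags)
}

#' Internal consistency of a fragment pattern
#'
#' For each enzyme, checks that the fragment lengths sum to the amplicon
#' length within a tolerance. Gel-derived patterns routinely miss a few bp
#' per band, so the package default elsewhere is 20 bp.
#'
#' @param pattern A [digest_pattern()].
#' @param tol_bp Allowed absolute deviation in bp (>= 0).
#' @return Named logical vector, one element per enzyme.
#' @export
pattern_consistency <- function(pattern, tol_bp = 20) {
  stopifnot(inherits(pattern, "digest_pattern"), tol_bp >= 0)
  vapply(pattern$fragments,
         function(f) abs(sum(f) - pattern$amplicon_bp) <= tol_bp,
         logical(1))
}

#' Match an observed fragment pattern against a reference database
#'
#' Formalizes the visual gel comparison used for strain identification:
#' for each candidate and enzyme, observed and reference fragments are
#' greedily paired largest-to-largest; the score is the summed absolute bp
#' discrepancy over paired fragments, plus a penalty of `tol_bp` plus the
#' fragment length for every unmatched fragment on either side. Candidates
#' are ranked by ascending score (score 0 iff identical patterns; exact
#' ties keep database order — strains sharing one RFLP pattern, like the
#' three D. hansenii isolates of the packaged set, are genuinely
#' indistinguishable by this method). A
#' candidate is flagged `consistent` when, for every enzyme, fragment
#' counts agree and every paired difference is at most `tol_bp`. Greedy
#' assignment is transparent and adequate for gel-resolution data; it is
#' deliberately simple and could be swapped for optimal matching.
#'
#' @param observed A [digest_pattern()].
#' @param db List of reference [digest_pattern()]s (non-empty).
#' @param tol_bp Gel tolerance in bp (default 20, typical band-size
#'   estimation error).
#' @return Tibble ranked by score: `strain`, `score`, `consistent`,
#'   `amplicon_bp`, `rank`.
#' @examples
#' db <- read_pattern_db(sco_extdata("table2_patterns.json"))
#' obs <- digest_pattern("unknown", 460,
#'                       list(HaeIII = c(290, 90, 80), RsaI = c(360, 100)))
#' match_pattern(obs, db)
#' @export
match_pattern <- function(observed, db, tol_bp = 20) {
  stopifnot(inherits(observed, "digest_pattern"))
  if (inherits(db, "digest_pattern")) db <- list(db)
  if (length(db) == 0) stop("reference database is empty", call. = FALSE)
  stopifnot(all(vapply(db, inherits, logical(1), "digest_pattern")), tol_bp >= 0)

  score_one <- function(ref) {
    enzymes <- union(names(observed$fragments), names(ref$fragments))
    score <- 0
    consistent <- TRUE
    for (enz in enzymes) {
      o <- observed$fragments[[enz]] %||na% integer(0)
      r <- ref$fragments[[enz]] %||na% integer(0)
      m <- min(length(o), length(r))
      diffs <- if (m > 0) abs(o[seq_len(m)] - r[seq_len(m)]) else numeric(0)
      unmatched <- c(o[-seq_len(m)], r[-seq_len(m)])
      if (m == 0) unmatched <- c(o, r)
      score <- score + sum(diffs) + sum(tol_bp + unmatched)
      if (length(o) != length(r) || any(diffs > tol_bp)) consistent <- FALSE
    }
    list(score = score, consistent = consistent)
  }
  scored <- lapply(db, score_one)
  out <- tibble::tibble(
    strain = vapply(db, `[[`, character(1), "strain"),
    score = vapply(scored, `[[`, numeric(1), "score"),
    consistent = vapply(scored, `[[`, logical(1), "consistent"),
    amplicon_bp = vapply(db, `[[`, integer(1), "amplicon_bp")
  )
  out <- out[order(out$score), ]
  out$rank <- seq_len(nrow(out))
  out
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a fragment-pattern database
#'
#' JSON array of objects `{strain, amplicon_bp, fragments: {enzyme: [bp,
#' ...]}}`. The packaged `table2_patterns.json` holds the seven-strain
#' kefir-isolate reference set.
#'
#' @param path JSON file.
#' @return List of [digest_pattern()]s.
#' @export
read_pattern_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) stop("pattern database is empty", call. = FALSE)
  lapply(raw, function(x) {
    if (!all(c("strain", "amplicon_bp", "fragments") %in% names(x))) {
      stop("pattern entry must have fields strain, amplicon_bp, fragments",
           call. = FALSE)
    }
    digest_pattern(x$strain, x$amplicon_bp,
                   lapply(x$fragments, function(f) unlist(f)))
  })
}

#' @rdname read_pattern_db
#' @param db List of [digest_pattern()]s.
#' @export
write_pattern_db <- function(db, path) {
  if (inherits(db, "digest_pattern")) db <- list(db)
  payload <- lapply(db, function(p) {
    list(strain = p$strain, amplicon_bp = p$amplicon_bp, fragments = p$fragments)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read ITS amplicon sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' uppercase character vectors, the representation the digestion functions
#' consume. The packaged `table1_its.fasta` carries the seven partial ITS
#' amplicon sequences of the kefir isolates (note these are *partial*
#' reads, shorter than the gel-estimated PCR products, so their in-silico
#' digests are not expected to equal the gel reference patterns).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_its_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
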