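#' Simulate a fatty-acid profile around a template
#'
#' Draws a compositional perturbation of a template profile. Fatty-acid
#' percentages live on a simplex, so noise is Dirichlet-style: each
#' detected entry i is drawn as Gamma(concentration * template_i / 100)
#' and the draws are rescaled to sum to 100. Additive Gaussian noise would
#' break the sum-to-100 invariant; the Dirichlet construction preserves it
#' by design. Entries absent from the template (not detected) stay absent.
#' Larger `concentration` means tighter scatter around the template;
#' `concentration = Inf` returns the template exactly.
#'
#' @param template An [fa_profile()] (or named numeric of weight-%)
#'   summing to 100 within the profile tolerance.
#' @param concentration Dirichlet concentration parameter (> 0, may be
#'   `Inf`). Default 500 gives the few-percent relative scatter typical of
#'   replicate GC-FID composition measurements.
#' @param seed Optional integer; fixed seed gives identical output.
#' @return An [fa_profile()] with the same strain/medium tags.
#' @examples
#' tmpl <- read_fa_profiles(sco_extdata("table5_fatty_acids.csv"))[[4]]
#' sim_fa_profile(tmpl, concentration = 500, seed = 1)
#' @export
sim_fa_profile <- function(template, concentration = 500, seed = NULL) {
  if (!inherits(template, "fa_profile")) {
    template <- fa_profile(template)
  }
  if (length(template$entries) == 0 || profile_total(template) <= 0) {
    stop("template profile is empty", call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1 || concentration <= 0) {
    stop("concentration must be a single positive number (or Inf)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- template$entries / profile_total(template)
  if (is.infinite(concentration)) {
    draws <- p
  } else {
    draws <- rgamma(length(p), shape = concentration * p, rate = 1)
    if (sum(draws) <= 0) draws <- p  # degenerate draw at tiny concentration
  }
  out <- template
  out$entries <- setNames(100 * draws / sum(draws), names(template$entries))
  out
}

#' Simulate a batch of fatty-acid profiles
#'
#' @inheritParams sim_fa_profile
#' @param n Number of profiles.
#' @return List of [fa_profile()]s.
#' @export
sim_fa_profiles <- function(n, template, concentration = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) sim_fa_profile(template, concentration))
}

#' Simulate a lag / exponential / stationary growth curve
#'
#' Piecewise growth model sampled on a regular grid (default every 0.25 h,
#' the cadence of plate-reader growth screens): constant `od0` during the
#' lag, exact exponential growth at the planted rate `mu` afterwards, and a
#' hard plateau once the curve reaches `plateau` (set `plateau = Inf` for
#' pure exponential growth). Noise is multiplicative log-normal
#' (`od * exp(rnorm(0, noise_sd))`) because OD measurement error scales
#' with signal. With `noise_sd = 0` the log-slope inside the exponential
#' phase equals `mu` exactly, which is what makes the generator usable as
#' a round-trip oracle for [specific_growth_rate()] and
#' [detect_log_phase()].
#'
#' @param mu Planted specific growth rate in 1/h (> 0).
#' @param lag_h Lag-phase duration in hours (>= 0).
#' @param od0 Initial OD (> 0).
#' @param plateau Stationary-phase OD (> `od0`; may be `Inf`).
#' @param interval_h Sampling interval in hours (default 0.25).
#' @param duration_h Total sampled time in hours.
#' @param noise_sd Log-normal noise sigma (>= 0).
#' @param seed Optional integer seed.
#' @return An [od_series()] with attributes `log_window` (true exponential
#'   window, clipped to the sampled range) and `mu_true`.
#' @examples
#' s <- sim_growth_curve(mu = 0.3, lag_h = 2, duration_h = 12, seed = 1)
#' attr(s, "log_window")
#' @export
sim_growth_curve <- function(mu = 0.25, lag_h = 2, od0 = 0.1, plateau = 1.5,
                             interval_h = 0.25, duration_h = 24,
                             noise_sd = 0, seed = NULL) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (od0 <= 0) stop("od0 must be positive", call. = FALSE)
  if (plateau <= od0) stop("plateau must exceed od0", call. = FALSE)
  if (lag_h < 0 || interval_h <= 0 || duration_h <= interval_h) {
    stop("invalid lag/interval/duration", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_h, by = interval_h)
  t_plateau <- lag_h + log(plateau / od0) / mu
  od <- ifelse(t <= lag_h, od0,
               ifelse(t < t_plateau, od0 * exp(mu * (t - lag_h)), plateau))
  if (noise_sd > 0) od <- od * exp(rnorm(length(od), 0, noise_sd))
  out <- od_series(t, od)
  # true exponential window, snapped to sampled times so that the noiseless
  # round-trip through specific_growth_rate() is exact
  t_exp <- t[t >= lag_h & t <= t_plateau]
  attr(out, "log_window") <- if (length(t_exp) >= 2) range(t_exp) else
    c(lag_h, min(t_plateau, duration_h))
  attr(out, "mu_true") <- mu
  out
}

#' Simulate a DNA sequence with planted restriction sites
#'
#' Builds a random A/C/G/T sequence that contains each enzyme's
#' recognition site exactly at the requested cut positions and nowhere
#' else: after stamping the planted sites onto a uniform background, any
#' accidental occurrence of any enzyme's site is patched by mutating one of
#' its bases outside the planted spans, and the scan repeats until clean
#' (bounded retries). Digesting the result therefore recovers exactly the
#' planted fragment lengths — the property that makes the generator a
#' round-trip oracle for [digest_fragments()].
#'
#' @param length_bp Sequence length (> 0).
#' @param cuts Named list, one integer vector of planted *cut positions*
#'   (between-base coordinates, `0 < k < length_bp`) per enzyme name in
#'   `enzymes`. A cut at `k` places the recognition site so the enzyme
#'   cleaves after base `k`. Site spans must not overlap.
#' @param enzymes Named list of [restriction_enzyme()]s
#'   (default [builtin_enzymes()]).
#' @param seed Optional integer seed.
#' @param max_tries Patching iterations before giving up (positions too
#'   dense to avoid accidental sites).
#' @return Uppercase DNA string with attribute `planted_cuts`.
#' @examples
#' s <- sim_site_sequence(400, list(HaeIII = 100), seed = 1)
#' digest_fragments(s, builtin_enzymes()$HaeIII)  # 300 100
#' @export
sim_site_sequence <- function(length_bp, cuts = list(), enzymes = builtin_enzymes(),
                              seed = NULL, max_tries = 200) {
  length_bp <- as.integer(length_bp)
  if (length_bp <= 0) stop("length_bp must be positive", call. = FALSE)
  if (length(cuts) && (is.null(names(cuts)) ||
                       !all(names(cuts) %in% names(enzymes)))) {
    stop("cuts must be named after enzymes in 'enzymes'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")

  # planted spans: site start/end for each requested cut
  spans <- list()
  for (enz_name in names(cuts)) {
    e <- enzymes[[enz_name]]
    k <- nchar(e$site)
    for (cut in as.integer(cuts[[enz_name]])) {
      if (cut <= 0 || cut >= length_bp) {
        stop("cut position ", cut, " outside (0, length_bp)", call. = FALSE)
      }
      start <- cut - e$cut_offset + 1L
      if (start < 1L || start + k - 1L > length_bp) {
        stop("site for cut at ", cut, " does not fit in the sequence", call. = FALSE)
      }
      spans[[length(spans) + 1L]] <- list(start = start, end = start + k - 1L,
                                          site = e$site)
    }
  }
  if (length(spans) > 1) {
    ord <- order(vapply(spans, `[[`, integer(1), "start"))
    spans <- spans[ord]
    starts <- vapply(spans, `[[`, integer(1), "start")
    ends <- vapply(spans, `[[`, integer(1), "end")
    if (any(starts[-1] <= ends[-length(ends)])) {
      stop("planted site spans overlap", call. = FALSE)
    }
  }
  planted_start <- vapply(spans, `[[`, integer(1), "start")
  in_planted <- rep(FALSE, length_bp)
  for (sp in spans) in_planted[sp$start:sp$end] <- TRUE

  chars <- sample(bases, length_bp, replace = TRUE)
  for (sp in spans) {
    chars[sp$start:sp$end] <- strsplit(sp$site, "")[[1]]
  }

  for (try in seq_len(max_tries)) {
    seq <- paste(chars, collapse = "")
    accidental <- list()
    for (e in enzymes) {
      k <- nchar(e$site)
      if (length_bp < k) next
      hits <- which(vapply(seq_len(length_bp - k + 1L),
                           function(i) substr(seq, i, i + k - 1L) == e$site,
                           logical(1)))
      hits <- hits[!(hits %in% planted_start)]
      for (h in hits) accidental[[length(accidental) + 1L]] <- c(h, h + k - 1L)
    }
    if (length(accidental) == 0) {
      return(structure(seq, planted_cuts = cuts))
    }
    for (occ in accidental) {
      mutable <- setdiff(occ[1]:occ[2], which(in_planted))
      if (length(mutable) == 0) {
        stop("planted sites too dense: accidental site at ", occ[1],
             " cannot be patched", call. = FALSE)
      }
      pos <- if (length(mutable) == 1) mutable else sample(mutable, 1)
      chars[pos] <- sample(setdiff(bases, chars[pos]), 1)
    }
  }
  stop("could not eliminate accidental recognition sites after ",
       max_tries, " patching rounds", call. = FALSE)
}
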