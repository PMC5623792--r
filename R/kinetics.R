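#' Optical-density time series
#'
#' Validated container for microwell growth readings (nominal cadence one
#' reading every 15 min, i.e. 0.25 h, though any strictly increasing grid
#' is accepted).
#'
#' @param time_h Non-negative, strictly increasing times in hours.
#' @param od Optical-density readings (>= 0), same length.
#' @return Tibble of class `od_series` with columns `time_h`, `od`.
#' @export
od_series <- function(time_h, od) {
  time_h <- as.numeric(time_h)
  od <- as.numeric(od)
  if (length(time_h) != length(od)) stop("time_h and od lengths differ", call. = FALSE)
  if (length(time_h) < 2) stop("an OD series needs at least 2 points", call. = FALSE)
  if (any(time_h < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("OD readings must be non-negative", call. = FALSE)
  out <- tibble::tibble(time_h = time_h, od = od)
  class(out) <- c("od_series", class(out))
  out
}

#' Specific growth rate over a time window
#'
#' \deqn{\mu = (\ln OD_f - \ln OD_i) / (t_f - t_i)}
#' with the endpoint ODs read from the series (linearly interpolated in
#' log-OD when an endpoint falls between samples). Only OD ratios matter,
#' so the result is invariant under uniform scaling of the readings.
#'
#' @param series An [od_series()].
#' @param t_start,t_end Window endpoints in hours (`t_end > t_start`), both
#'   within the sampled range.
#' @return Specific growth rate in 1/h (0 for constant OD).
#' @examples
#' s <- od_series(c(0, 1), c(0.1, 0.2))
#' specific_growth_rate(s, 0, 1)  # ln 2
#' @export
specific_growth_rate <- function(series, t_start, t_end) {
  stopifnot(inherits(series, "od_series"))
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  rng <- range(series$time_h)
  if (t_start < rng[1] || t_end > rng[2]) {
    stop("window outside the sampled time range", call. = FALSE)
  }
  in_win <- series$time_h >= t_start & series$time_h <= t_end
  if (any(series$od[in_win] <= 0)) {
    stop("OD <= 0 inside the window; growth rate undefined", call. = FALSE)
  }
  # bracketing samples must be positive too for log-interpolation
  idx <- which(series$time_h <= t_start)
  idx <- c(utils::tail(idx, 1), which(series$time_h >= t_end)[1])
  if (any(series$od[idx] <= 0)) {
    stop("OD <= 0 at the samples bracketing the window", call. = FALSE)
  }
  lod <- approx(series$time_h, log(series$od), xout = c(t_start, t_end))$y
  (lod[2] - lod[1]) / (t_end - t_start)
}

#' Detect the exponential (log) phase of a growth curve
#'
#' The source data for growth screens give no algorithm ("curves were
#' inspected"), so the package uses an explicit, deterministic procedure: a
#' sliding-window least-squares fit of log(OD) on time. Among all windows
#' of at least `min_points` samples with positive slope, the window with
#' the highest coefficient of determination is returned (R-squared grows
#' with window length inside a truly exponential stretch and drops as soon
#' as the window swallows lag or plateau points, so maximizing it trims the
#' phase boundaries); ties are broken in favour of longer, then earlier
#' windows. If the best window falls short of `r2_min` the series is
#' deemed to lack an exponential phase and an error is raised.
#'
#' @param series An [od_series()] with at least 6 points.
#' @param min_points Minimum window length in samples (default 5).
#' @param r2_min Linearity threshold on R-squared (default 0.98).
#' @return List with `t_start`, `t_end`, `mu` (window slope, 1/h), `r2`,
#'   `n_points`.
#' @export
detect_log_phase <- function(series, min_points = 5, r2_min = 0.98) {
  stopifnot(inherits(series, "od_series"))
  n <- nrow(series)
  if (n < 6) stop("need at least 6 points to detect a log phase", call. = FALSE)
  if (min_points < 3) stop("min_points must be at least 3", call. = FALSE)
  pos <- series$od > 0
  x <- series$time_h
  y <- ifelse(pos, log(pmax(series$od, .Machine$double.xmin)), NA_real_)

  # prefix sums for O(1) window regression statistics
  cx <- cumsum(ifelse(pos, x, 0)); cy <- cumsum(ifelse(pos, y, 0))
  cxx <- cumsum(ifelse(pos, x^2, 0)); cyy <- cumsum(ifelse(pos, y^2, 0))
  cxy <- cumsum(ifelse(pos, x * y, 0)); cn <- cumsum(as.numeric(pos))
  win_stat <- function(i, j) {
    m <- cn[j] - if (i > 1) cn[i - 1] else 0
    if (m != j - i + 1) return(NULL)  # window contains a non-positive OD
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    ssx <- sxx - sx^2 / m
    ssy <- syy - sy^2 / m
    sxy0 <- sxy - sx * sy / m
    slope <- sxy0 / ssx
    r2 <- if (ssy <= .Machine$double.eps * max(1, abs(syy))) 0 else sxy0^2 / (ssx * ssy)
    list(slope = slope, r2 = r2)
  }

  best <- NULL
  for (len in seq(n, min_points)) {  # longer windows first, so ties keep them
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1
      st <- win_stat(i, j)
      if (is.null(st) || !is.finite(st$slope) || st$slope <= 0) next
      if (is.null(best) || st$r2 > best$r2 + 1e-12) {
        best <- list(i = i, j = j, mu = st$slope, r2 = st$r2)
      }
    }
  }
  if (is.null(best) || best$r2 < r2_min) {
    stop(sprintf(paste0("no window of >= %d points with positive slope and ",
                        "R^2 >= %.3g found; the series may lack an exponential phase"),
                 min_points, r2_min), call. = FALSE)
  }
  list(t_start = x[best$i], t_end = x[best$j], mu = best$mu, r2 = best$r2,
       n_points = best$j - best$i + 1L)
}

#' Generation (doubling) time from a specific growth rate
#'
#' @param mu Specific growth rate in 1/h (> 0).
#' @return `log(2)/mu`, in hours.
#' @export
generation_time <- function(mu) {
  if (any(mu <= 0)) stop("generation time requires mu > 0", call. = FALSE)
  log(2) / mu
}

#' Volumetric productivity
#'
#' Final concentration divided by culture duration (Q_x for biomass, Q_L
#' for lipids), rounded half-to-even at 3 dp for endpoint-table-style
#' reporting (`digits = NULL` returns the unrounded quotient).
#'
#' @param final_conc Final concentration in g/L (>= 0).
#' @param duration_h Culture duration in hours (> 0).
#' @param digits Decimal places for reporting (default 3).
#' @return Productivity in g/(L h).
#' @examples
#' volumetric_productivity(12.2, 96)  # 0.127
#' @export
volumetric_productivity <- function(final_conc, duration_h, digits = 3) {
  if (any(duration_h <= 0)) stop("duration must be positive", call. = FALSE)
  if (any(final_conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  q <- final_conc / duration_h
  if (!is.null(digits)) q <- round(q, digits)
  q
}

#' Lipid content as percent of cell dry weight
#'
#' @param lipids Lipid concentration in g/L.
#' @param biomass Biomass (cell dry weight) concentration in g/L (> 0).
#' @return `100 * lipids / biomass` (% CDW).
#' @examples
#' lipid_content_pct(6.31, 13.5)  # > 46 % CDW
#' @export
lipid_content_pct <- function(lipids, biomass) {
  if (any(biomass <= 0)) stop("biomass must be positive", call. = FALSE)
  if (any(lipids < 0)) stop("lipids must be non-negative", call. = FALSE)
  if (any(lipids > biomass)) stop("lipids cannot exceed biomass", call. = FALSE)
  100 * lipids / biomass
}

#' Carbon : nitrogen : phosphorus ratio of a medium
#'
#' Normalizes elemental masses to nitrogen = 1 and formats with 3
#' significant figures, the convention used when relating media composition
#' to lipid accumulation.
#'
#' @param composition Named numeric vector of elemental masses in g/L;
#'   must contain `C`, `N` and `P`, with `N > 0`.
#' @return List with `ratio` (named numeric `C`, `N`, `P`) and `label`
#'   (e.g. `"12.3 : 1 : 0.204"`).
#' @examples
#' cnp_ratio(c(C = 24.6, N = 2, P = 0.408))$label
#' @export
cnp_ratio <- function(composition) {
  if (!all(c("C", "N", "P") %in% names(composition))) {
    stop("composition must name at least C, N and P", call. = FALSE)
  }
  if (any(composition < 0)) stop("elemental masses must be non-negative", call. = FALSE)
  if (composition[["N"]] <= 0) stop("N must be positive to normalize", call. = FALSE)
  r <- c(C = composition[["C"]] / composition[["N"]], N = 1,
         P = composition[["P"]] / composition[["N"]])
  fmt <- function(x) format(signif(x, 3), trim = TRUE, scientific = FALSE)
  list(ratio = r, label = paste(fmt(r["C"]), "1", fmt(r["P"]), sep = " : "))
}

#' Read a culture endpoint table
#'
#' Long format, one row per strain-by-medium culture: columns `strain`,
#' `medium`, `biomass_g_l`, `lipids_g_l`, `duration_h` (extra columns are
#' kept untouched).
#'
#' @param path CSV file.
#' @return Tibble.
#' @examples
#' head(read_culture_table(sco_extdata("table4_culture.csv")))
#' @export
read_culture_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("strain", "medium", "biomass_g_l", "lipids_g_l", "duration_h")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("culture table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Read OD time series in long format
#'
#' Columns `well`, `time_h`, `od`; one [od_series()] is built per well.
#'
#' @param path CSV file.
#' @return Named list of [od_series()].
#' @export
read_od_series <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("well", "time_h", "od")
  if (!all(need %in% names(tab))) {
    stop("OD table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(tab[order(tab$time_h), ], tab$well[order(tab$time_h)]),
         function(d) od_series(d$time_h, d$od))
}

#' Productivity and lipid-content summary of a culture table
#'
#' Adds Q_x and Q_L (3 dp) and lipid content in % CDW (1 dp) to each row.
#' Rows where lipids exceed biomass are physically impossible, so they are
#' flagged, excluded and reported via a warning rather than propagated.
#'
#' @param culture Tibble from [read_culture_table()].
#' @return Tibble with added `qx_g_l_h`, `ql_g_l_h`, `lipid_pct_cdw`.
#' @export
kinetics_table <- function(culture) {
  bad <- !is.na(culture$lipids_g_l) & culture$lipids_g_l > culture$biomass_g_l
  if (any(bad)) {
    warning(sum(bad), " row(s) with lipids > biomass excluded: ",
            paste(culture$strain[bad], culture$medium[bad], collapse = "; "),
            call. = FALSE)
    culture <- culture[!bad, ]
  }
  dplyr::mutate(
    culture,
    qx_g_l_h = volumetric_productivity(.data$biomass_g_l, .data$duration_h),
    ql_g_l_h = ifelse(is.na(.data$lipids_g_l), NA_real_,
                      volumetric_productivity(ifelse(is.na(.data$lipids_g_l), 0,
                                                     .data$lipids_g_l),
                                              .data$duration_h)),
    lipid_pct_cdw = ifelse(is.na(.data$lipids_g_l), NA_real_,
                           round(100 * .data$lipids_g_l / .data$biomass_g_l, 1))
  )
}
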