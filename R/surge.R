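#' Winter-surge calendar
#'
#' The 90-day winter surge: daily admissions ramp up linearly over
#' `ramp_days` days before `peak_start`, stay at `peak_ratio` times the
#' non-surge level throughout the closed peak window
#' `[peak_start, peak_end]`, and ramp back down to the non-surge level over
#' `ramp_days` days after `peak_end`.
#'
#' @param peak_start,peak_end Month-day strings (`"MM-DD"`) delimiting the
#'   peak window (defaults Jan 15 and Feb 13, a 30-day window).
#' @param ramp_days Length of each linear ramp in days.
#' @param peak_ratio Peak level as a multiple of the non-surge level,
#'   `>= 1`.
#' @return A `surge_calendar` object.
#' @export
surge_calendar <- function(peak_start = "01-15", peak_end = "02-13",
                           ramp_days = 30, peak_ratio = 1.196) {
  stopifnot(grepl("^\\d{2}-\\d{2}$", peak_start),
            grepl("^\\d{2}-\\d{2}$", peak_end))
  if (ramp_days <= 0) stop("ramp_days must be > 0", call. = FALSE)
  if (peak_ratio < 1) stop("peak_ratio must be >= 1", call. = FALSE)
  structure(list(peak_start = peak_start, peak_end = peak_end,
                 ramp_days = as.integer(ramp_days),
                 peak_ratio = as.numeric(peak_ratio)),
            class = "surge_calendar")
}

# peak window of the surge season containing/nearest date d: the season is
# anchored on the peak_start belonging to the same winter as d
surge_anchor_year <- function(dates, calendar) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  start_month <- as.integer(substr(calendar$peak_start, 1, 2))
  # dates late in the year belong to next January's peak
  ifelse(m > 6 & start_month <= 6, y + 1L, y)
}

#' Surge multiplier for calendar dates
#'
#' Piecewise-linear multiplier applied to the non-surge daily admission
#' level: 1 outside the surge window, `peak_ratio` inside the closed peak
#' window, and linear in time on the two ramps (continuous at all four
#' breakpoints).
#'
#' @param dates `Date` vector (or coercible).
#' @param calendar A [surge_calendar()].
#' @return Numeric vector of multipliers in `[1, peak_ratio]`.
#' @examples
#' cal <- surge_calendar()
#' surge_multiplier(as.Date(c("2015-07-01", "2015-01-20", "2014-12-31")), cal)
#' @export
surge_multiplier <- function(dates, calendar = surge_calendar()) {
  dates <- as.Date(dates)
  ay <- surge_anchor_year(dates, calendar)
  ps <- as.Date(sprintf("%d-%s", ay, calendar$peak_start))
  pe <- as.Date(sprintf("%d-%s", ay, calendar$peak_end))
  pe <- ifelse(pe < ps, as.Date(sprintf("%d-%s", ay + 1L, calendar$peak_end)),
               pe)
  pe <- as.Date(pe, origin = "1970-01-01")
  r <- calendar$peak_ratio
  n <- calendar$ramp_days
  up0 <- ps - n      # multiplier 1 here, rising to r at ps
  dn1 <- pe + n      # multiplier back to 1 here
  d <- as.numeric(dates)
  m <- rep(1, length(dates))
  on_up <- d >= as.numeric(up0) & d < as.numeric(ps)
  on_peak <- d >= as.numeric(ps) & d <= as.numeric(pe)
  on_dn <- d > as.numeric(pe) & d <= as.numeric(dn1)
  m[on_up] <- 1 + (r - 1) * (d[on_up] - as.numeric(up0)[on_up]) / n
  m[on_peak] <- r
  m[on_dn] <- r - (r - 1) * (d[on_dn] - as.numeric(pe)[on_dn]) / n
  m
}

# fiscal year label (April 1 -> March 31) for a vector of dates
fiscal_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m < 4L, y - 1L, y)
}

natural_year <- function(dates) as.integer(format(dates, "%Y"))

# look up an annual series at dates under its year convention; linear mode
# interpolates between mid-year anchor points
annual_lookup <- function(dates, inputs, var, interpolate = FALSE) {
  conv <- attr(inputs, "year_convention")[[var]]
  lab <- if (identical(conv, "natural")) natural_year(dates) else
    fiscal_year(dates)
  idx <- match(lab, inputs$year)
  if (anyNA(idx)) {
    bad <- dates[which(is.na(idx))[1]]
    stop(sprintf("date %s (year label %d for '%s') outside annual coverage",
                 format(bad), lab[which(is.na(idx))[1]], var), call. = FALSE)
  }
  if (!interpolate) return(inputs[[var]][idx])
  # anchors at the midpoint of each labelled year
  anchor <- if (identical(conv, "natural")) {
    as.numeric(as.Date(sprintf("%d-07-02", inputs$year)))
  } else {
    as.numeric(as.Date(sprintf("%d-10-01", inputs$year)))
  }
  stats::approx(anchor, inputs[[var]], xout = as.numeric(dates),
                rule = 2)$y
}

#' Daily admission demand
#'
#' The active year's non-surge daily level (under the fiscal-year
#' convention of the admission series) times the surge multiplier of the
#' date. During the peak window this reproduces the year's surge level up
#' to the rounding of the printed annual pairs.
#'
#' @param dates `Date` vector.
#' @param inputs An [annual_inputs()] object covering the dates.
#' @param calendar A [surge_calendar()].
#' @param interpolate Use linear interpolation between year midpoints
#'   instead of the default piecewise-constant convention.
#' @return Admissions/day.
#' @export
daily_admissions <- function(dates, inputs, calendar = surge_calendar(),
                             interpolate = FALSE) {
  base <- annual_lookup(as.Date(dates), inputs, "inpt_nonsurge",
                        interpolate = interpolate)
  base * surge_multiplier(dates, calendar)
}

#' Convert between annual admission totals and the non-surge daily level
#'
#' The annual total implied by a non-surge daily level `x` with a surge of
#' peak ratio `r`, a 30-day peak and two 30-day trapezoidal ramps is
#' `(days - 90) x + 30 r x + 2 * 30 * (x + r x) / 2`. `nonsurge_from_annual()`
#' inverts this in closed form.
#'
#' @param annual_total Total admissions in the year.
#' @param peak_ratio Surge peak ratio `r >= 1`.
#' @param days_in_year Number of days in the year (365 or 366; the leap day
#'   counts as a non-surge day).
#' @param calendar Optionally a [surge_calendar()] from which the peak
#'   length, ramp length and ratio are taken.
#' @return Non-surge admissions/day (`annual_from_nonsurge()` returns the
#'   annual total).
#' @examples
#' nonsurge_from_annual(376.76, 1.196, 365)  # 1
#' annual_from_nonsurge(3945, 1.196, 365)
#' @export
nonsurge_from_annual <- function(annual_total, peak_ratio = 1.196,
                                 days_in_year = 365, calendar = NULL) {
  if (any(annual_total <= 0)) stop("annual_total must be > 0", call. = FALSE)
  annual_total / surge_year_factor(peak_ratio, days_in_year, calendar)
}

#' @rdname nonsurge_from_annual
#' @param nonsurge_daily Non-surge admissions/day.
#' @export
annual_from_nonsurge <- function(nonsurge_daily, peak_ratio = 1.196,
                                 days_in_year = 365, calendar = NULL) {
  if (any(nonsurge_daily <= 0)) stop("nonsurge_daily must be > 0",
                                     call. = FALSE)
  nonsurge_daily * surge_year_factor(peak_ratio, days_in_year, calendar)
}

surge_year_factor <- function(peak_ratio, days_in_year, calendar = NULL) {
  peak_len <- 30
  ramp <- 30
  r <- peak_ratio
  if (!is.null(calendar)) {
    ps <- as.Date(sprintf("2001-%s", calendar$peak_start))
    pe <- as.Date(sprintf("2001-%s", calendar$peak_end))
    peak_len <- as.numeric(pe - ps) + 1
    ramp <- calendar$ramp_days
    r <- calendar$peak_ratio
  }
  if (any(r < 1) || days_in_year <= 2 * ramp + peak_len) {
    stop("invalid surge geometry for the year length", call. = FALSE)
  }
  (days_in_year - 2 * ramp - peak_len) + peak_len * r + ramp * (1 + r)
}
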