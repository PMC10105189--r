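#' Split daily admission demand between the public and private sectors
#'
#' Insured patients use private care with probability `use_hi`; uninsured
#' patients self-pay for private care with probability `selfpay`; everyone
#' else is admitted publicly. The two sector flows always sum exactly to
#' the total demand.
#'
#' @param inpt_num Total admission demand (admissions/day), non-negative.
#' @param hi Current insurance penetration, fraction in `[0, 1]`.
#' @param use_hi,selfpay Behavioural fractions in `[0, 1]`.
#' @return A list with numeric elements `pu_admit`, `pr_admit`.
#' @examples
#' split_admissions(3945, 0.36, 0.57, 0.06)
#' @export
split_admissions <- function(inpt_num, hi, use_hi, selfpay) {
  if (any(hi < 0 | hi > 1) || any(use_hi < 0 | use_hi > 1) ||
      any(selfpay < 0 | selfpay > 1)) {
    stop("hi, use_hi and selfpay must lie in [0, 1]", call. = FALSE)
  }
  if (any(inpt_num < 0)) stop("inpt_num must be >= 0", call. = FALSE)
  pu <- inpt_num * (hi * (1 - use_hi) + (1 - hi) * (1 - selfpay))
  list(pu_admit = pu, pr_admit = inpt_num - pu)
}

#' Sector bed-occupancy rates
#'
#' Occupancy is admissions times length of stay over beds (the Little's-law
#' flow form); private length of stay is the public one scaled by the
#' severity ratio. Values above 1 represent over-capacity and are allowed.
#'
#' @param pu_admit,pr_admit Daily admissions into each sector.
#' @param pu_los Public average length of stay (days).
#' @param pu_beds,pr_beds Bed counts (`> 0`).
#' @param severity_ftr Severity adjustment ratio (`> 0`).
#' @return Occupancy fraction(s).
#' @export
occupancy_public <- function(pu_admit, pu_los, pu_beds) {
  if (any(pu_beds <= 0)) stop("pu_beds must be > 0", call. = FALSE)
  pu_admit * pu_los / pu_beds
}

#' @rdname occupancy_public
#' @export
occupancy_private <- function(pr_admit, pu_los, severity_ftr, pr_beds) {
  if (any(pr_beds <= 0)) stop("pr_beds must be > 0", call. = FALSE)
  pr_admit * pu_los * severity_ftr / pr_beds
}

#' Signed occupancy gap between the sectors
#'
#' @param pu_occu,pr_occu Sector occupancy rates.
#' @param orientation `"public_minus_private"` (default; a positive gap
#'   means the public sector is the more crowded one and raises insurance
#'   demand) or `"private_minus_public"`.
#' @return Signed fraction.
#' @export
occupancy_gap <- function(pu_occu, pr_occu,
                          orientation = c("public_minus_private",
                                          "private_minus_public")) {
  orientation <- match.arg(orientation)
  if (orientation == "public_minus_private") pu_occu - pr_occu
  else pr_occu - pu_occu
}

#' Insurance penetration from its baseline and effect terms
#'
#' The penetration is the baseline plus the delayed occupancy effect
#' (optionally floored at zero, the structural calibration variant) plus
#' the delayed tax effect, clipped to `[0, 1]`.
#'
#' @param baseline_hi Baseline penetration fraction.
#' @param effect_occu Delayed occupancy-gap effect (signed fraction).
#' @param effect_tax Delayed tax-incentive effect (fraction).
#' @param clamp_effect_nonneg Apply `max(0, effect_occu)`.
#' @return Penetration fraction in `[0, 1]`.
#' @export
hi_level <- function(baseline_hi, effect_occu, effect_tax = 0,
                     clamp_effect_nonneg = FALSE) {
  if (any(baseline_hi < 0 | baseline_hi > 1)) {
    stop("baseline_hi must lie in [0, 1]", call. = FALSE)
  }
  e <- if (clamp_effect_nonneg) pmax(0, effect_occu) else effect_occu
  pmin(pmax(baseline_hi + e + effect_tax, 0), 1)
}

# per-day exogenous inputs over the horizon
build_daily_inputs <- function(inputs, calendar, start, end,
                               interpolate = FALSE) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  data.frame(
    date = dates,
    inpt_num = daily_admissions(dates, inputs, calendar,
                                interpolate = interpolate),
    pu_los = annual_lookup(dates, inputs, "pu_los", interpolate),
    pu_beds = annual_lookup(dates, inputs, "pu_beds", interpolate),
    pr_beds = annual_lookup(dates, inputs, "pr_beds", interpolate)
  )
}

#' Simulate the insurance-demand feedback model
#'
#' Runs the full stock-flow model with explicit Euler integration: each
#' day's admission demand is split between the sectors by the current
#' penetration, hospital stocks accumulate admissions minus first-order
#' discharges (stock / length of stay), sector occupancies and their gap
#' are computed, the gap in excess of its baseline (scaled by the demand
#' elasticity) passes through a third-order exponential delay, and the
#' penetration is recomputed as baseline plus the delayed effects. The tax
#' effect starts, with an empty delay cascade, at the policy activation
#' date.
#'
#' @param params A [scalar_params()]; `baseline_hi` must not be `NA`.
#' @param inputs An [annual_inputs()] covering `[start, end]`.
#' @param policy A [tax_policy()], or `NULL` for no tax incentive.
#' @param calendar A [surge_calendar()].
#' @param start,end Simulation horizon (dates); defaults 2009-04-01 to
#'   2019-12-31.
#' @param dt Euler step in days; must divide 1 (`1/dt` integer).
#' @param delay_init `"matched"` (occupancy delay starts at the first
#'   day's input, the convention of common system-dynamics engines) or
#'   `"zero"`.
#' @param occupancy_basis `"flow"` (admissions x LoS / beds, default) or
#'   `"stock"` (patients in hospital / beds; equal at equilibrium).
#' @param interpolate Linearly interpolate annual inputs between year
#'   midpoints instead of the piecewise-constant default.
#' @param emit_substeps Record every Euler substep instead of one row per
#'   day (only meaningful for `dt < 1`).
#' @param .daily Precomputed daily-input table (internal; lets batch
#'   callers amortize the input construction across many runs).
#' @return A `hi_trajectory` data frame with one row per day (or substep):
#'   `date`, `t` (days since start), `inpt_num`, `pu_admit`, `pr_admit`,
#'   `pu_discharge`, `pr_discharge`, `using_pu`, `using_pr`, `pu_occu`,
#'   `pr_occu`, `diff_occu`, `effect_occu`, `effect_tax`, `hi`. Stocks and
#'   `hi` are start-of-step values; flows, occupancies and effects are the
#'   values in force during the step.
#' @examples
#' b <- hk_default_bundle(baseline_hi = 0.3)
#' traj <- simulate_insurance(b$scalar, b$annual, b$tax_policy,
#'                            start = "2009-04-01", end = "2010-03-31")
#' tail(traj$hi, 1)
#' @useDynLib hidemand, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @export
simulate_insurance <- function(params, inputs, policy = NULL,
                               calendar = surge_calendar(),
                               start = "2009-04-01", end = "2019-12-31",
                               dt = 1,
                               delay_init = c("matched", "zero"),
                               occupancy_basis = c("flow", "stock"),
                               interpolate = FALSE,
                               emit_substeps = FALSE,
                               .daily = NULL) {
  delay_init <- match.arg(delay_init)
  occupancy_basis <- match.arg(occupancy_basis)
  validate_scalar_params(params)
  if (is.na(params$baseline_hi)) {
    stop("field 'baseline_hi' must be provided before simulating",
         call. = FALSE)
  }
  m <- round(1 / dt)
  if (dt <= 0 || dt > 1 || abs(m * dt - 1) > 1e-9) {
    stop("dt must be a reciprocal of an integer number of substeps per day",
         call. = FALSE)
  }
  daily <- if (is.null(.daily)) {
    build_daily_inputs(inputs, calendar, start, end, interpolate)
  } else .daily
  n_days <- nrow(daily)
  inpt_v <- daily$inpt_num
  los_v <- daily$pu_los
  pub_v <- daily$pu_beds
  prb_v <- daily$pr_beds
  tax_on_v <- if (is.null(policy)) rep(FALSE, n_days) else
    daily$date >= policy$start_date
  tax_input <- if (is.null(policy)) 0 else
    tax_saving_ratio(policy) * params$tax_dmd

  sgn <- if (params$diff_orientation == "public_minus_private") 1 else -1
  rec <- sim_core_cpp(inpt_v, los_v, pub_v, prb_v, tax_on_v, tax_input,
                      params$use_hi, params$selfpay, params$severity_ftr,
                      params$occu_dmd, params$baseline_diff,
                      params$baseline_hi, params$clamp_effect_nonneg,
                      sgn, params$delay_duration / 3, dt, m,
                      delay_init == "matched", occupancy_basis == "flow",
                      emit_substeps)
  rec_date <- if (emit_substeps) rep(daily$date, each = m) else daily$date
  out <- data.frame(date = rec_date, rec)
  names(out) <- c("date", "t", "inpt_num", "pu_admit", "pr_admit",
                  "pu_discharge", "pr_discharge", "using_pu", "using_pr",
                  "pu_occu", "pr_occu", "diff_occu", "effect_occu",
                  "effect_tax", "hi")
  structure(out,
            params = params, policy = policy, calendar = calendar,
            dt = dt, delay_init = delay_init,
            occupancy_basis = occupancy_basis,
            class = c("hi_trajectory", "data.frame"))
}

#' Write / read a simulated trajectory as CSV
#'
#' The CSV carries a commented metadata header (`# key: value` lines) with
#' the parameters, horizon and numerical options, sufficient to reproduce
#' the run, followed by one row per time step with ISO-8601 dates.
#'
#' @param traj A `hi_trajectory` from [simulate_insurance()].
#' @param path Output CSV path.
#' @return `path` invisibly; `read_trajectory()` returns a data frame.
#' @export
write_trajectory <- function(traj, path) {
  p <- attr(traj, "params")
  meta <- c(
    sprintf("# generator: hidemand %s",
            as.character(utils::packageVersion("hidemand"))),
    sprintf("# horizon: %s .. %s", format(min(traj$date)),
            format(max(traj$date))),
    sprintf("# dt: %g", attr(traj, "dt")),
    sprintf("# delay_init: %s", attr(traj, "delay_init")),
    sprintf("# occupancy_basis: %s", attr(traj, "occupancy_basis"))
  )
  if (!is.null(p)) {
    meta <- c(meta, vapply(scalar_param_fields, function(f)
      sprintf("# param %s: %s", f, format(p[[f]])), character(1)))
  }
  pol <- attr(traj, "policy")
  if (!is.null(pol)) {
    meta <- c(meta, sprintf(
      "# tax_policy: %g %g %g %g %s", pol$tax_inct, pol$avg_prm_ratio,
      pol$tax_rate, pol$avg_tax, format(pol$start_date)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- as.data.frame(traj)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
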