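#' Behavioural and structural scalar parameters
#'
#' Bundles every time-constant parameter of the insurance-demand feedback
#' model. Fractions are stored as fractions (0.57, not 57%); rendering as
#' percent happens only at the reporting layer.
#'
#' @param use_hi Fraction of insured patients who use their insurance to
#'   obtain private inpatient care (`UseHI`), in `[0, 1]`.
#' @param selfpay Fraction of uninsured patients willing to pay for private
#'   care out of pocket (`Selfpay`), in `[0, 1]`.
#' @param severity_ftr Severity adjustment ratio converting public average
#'   length of stay into private length of stay (`SeverityFtr`), positive.
#'   Private hospitals treat on average less severe cases, so this is
#'   typically well below 1.
#' @param occu_dmd Elasticity translating the occupancy-rate gap between the
#'   sectors into insurance demand (`OccuDmd`), non-negative.
#' @param tax_dmd Elasticity translating the proportion of tax saved into
#'   insurance demand (`TaxDmd`), non-negative.
#' @param baseline_hi Baseline insurance penetration at the simulation start
#'   (`BaselineHI`), in `[0, 1]`. No default is bundled for Hong Kong: the
#'   value comes from household-survey data and must be supplied by the
#'   user (`NA` is accepted at construction but rejected at simulation).
#' @param baseline_diff Baseline occupancy-rate difference between the
#'   sectors (`BaselineDiff`), a signed fraction; the delayed demand effect
#'   responds to the excess of the current gap over this baseline.
#' @param delay_duration Perception delay of the occupancy and tax effects in
#'   days (`Duration`); default one year.
#' @param surge_peak_ratio Peak winter-surge admissions as a multiple of the
#'   non-surge daily level; must be `>= 1`.
#' @param clamp_effect_nonneg If `TRUE`, the occupancy effect enters the
#'   penetration as `max(0, effect)` (structural calibration variant).
#' @param diff_orientation Sign convention of the occupancy gap:
#'   `"public_minus_private"` (default; a public sector more crowded than
#'   the private one raises insurance demand) or `"private_minus_public"`.
#'
#' @return An object of class `scalar_params` (a validated named list).
#' @examples
#' p <- scalar_params(use_hi = 0.57, selfpay = 0.06, severity_ftr = 0.39,
#'                    occu_dmd = 0.5, tax_dmd = 0.138,
#'                    baseline_hi = 0.3, baseline_diff = 0.055)
#' p$severity_ftr
#' @export
scalar_params <- function(use_hi, selfpay, severity_ftr, occu_dmd, tax_dmd,
                          baseline_hi, baseline_diff,
                          delay_duration = 365,
                          surge_peak_ratio = 1.196,
                          clamp_effect_nonneg = FALSE,
                          diff_orientation = c("public_minus_private",
                                               "private_minus_public")) {
  diff_orientation <- match.arg(diff_orientation)
  p <- structure(list(
    use_hi = as.numeric(use_hi),
    selfpay = as.numeric(selfpay),
    severity_ftr = as.numeric(severity_ftr),
    occu_dmd = as.numeric(occu_dmd),
    tax_dmd = as.numeric(tax_dmd),
    baseline_hi = as.numeric(baseline_hi),
    baseline_diff = as.numeric(baseline_diff),
    delay_duration = as.numeric(delay_duration),
    surge_peak_ratio = as.numeric(surge_peak_ratio),
    clamp_effect_nonneg = isTRUE(clamp_effect_nonneg),
    diff_orientation = diff_orientation
  ), class = "scalar_params")
  validate_scalar_params(p)
  p
}

check_range <- function(value, field, lo = -Inf, hi = Inf, allow_na = FALSE) {
  if (length(value) != 1L) {
    stop(sprintf("field '%s' must be a single value", field), call. = FALSE)
  }
  if (is.na(value)) {
    if (allow_na) return(invisible(TRUE))
    stop(sprintf("field '%s' is missing (NA)", field), call. = FALSE)
  }
  if (value < lo || value > hi) {
    stop(sprintf("field '%s' = %g is outside [%g, %g]", field, value, lo, hi),
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_scalar_params <- function(p) {
  check_range(p$use_hi, "use_hi", 0, 1)
  check_range(p$selfpay, "selfpay", 0, 1)
  check_range(p$baseline_hi, "baseline_hi", 0, 1, allow_na = TRUE)
  check_range(p$baseline_diff, "baseline_diff", -1, 1)
  if (!is.na(p$severity_ftr) && p$severity_ftr <= 0) {
    stop(sprintf("field 'severity_ftr' = %g must be > 0", p$severity_ftr),
         call. = FALSE)
  }
  check_range(p$occu_dmd, "occu_dmd", 0, Inf)
  check_range(p$tax_dmd, "tax_dmd", 0, Inf)
  if (p$delay_duration <= 0) {
    stop(sprintf("field 'delay_duration' = %g must be > 0", p$delay_duration),
         call. = FALSE)
  }
  check_range(p$surge_peak_ratio, "surge_peak_ratio", 1, Inf)
  invisible(p)
}

#' Tax-incentive policy
#'
#' Describes a tax deduction for purchasing certified private health
#' insurance. The per-capita saving is
#' `tax_inct * avg_prm_ratio * tax_rate`, and its ratio to the average tax
#' paid per capita is the "proportion of tax saved" that drives the demand
#' effect after `start_date`.
#'
#' @param tax_inct Maximum tax deduction per person (currency units).
#' @param avg_prm_ratio Average premium actually paid as a fraction of the
#'   deduction cap.
#' @param tax_rate Marginal tax-rate bracket applying to the deduction.
#' @param avg_tax Average tax paid per capita (currency units), positive.
#' @param start_date Calendar date the policy activates (`Date` or ISO
#'   string).
#' @return An object of class `tax_policy`.
#' @examples
#' tp <- tax_policy(8000, 0.85, 0.06, 2876, "2019-04-01")
#' tax_saving(tp)  # 408
#' @export
tax_policy <- function(tax_inct, avg_prm_ratio, tax_rate, avg_tax,
                       start_date) {
  pol <- structure(list(
    tax_inct = as.numeric(tax_inct),
    avg_prm_ratio = as.numeric(avg_prm_ratio),
    tax_rate = as.numeric(tax_rate),
    avg_tax = as.numeric(avg_tax),
    start_date = as.Date(start_date)
  ), class = "tax_policy")
  check_range(pol$tax_inct, "tax_inct", 0, Inf)
  check_range(pol$avg_prm_ratio, "avg_prm_ratio", 0, Inf)
  check_range(pol$tax_rate, "tax_rate", 0, Inf)
  if (pol$avg_tax <= 0) {
    stop(sprintf("field 'avg_tax' = %g must be > 0", pol$avg_tax),
         call. = FALSE)
  }
  if (is.na(pol$start_date)) stop("field 'start_date' is not a valid date",
                                  call. = FALSE)
  pol
}

#' Survey reference series of insurance penetration
#'
#' An ordered set of dated survey observations of the fraction of the
#' population holding voluntary individual private health insurance, used
#' as the calibration reference.
#'
#' @param dates Vector of observation dates (strictly increasing).
#' @param values Observed penetration fractions in `[0, 1]`.
#' @return A `reference_series` data frame with columns `date`, `hi`.
#' @export
reference_series <- function(dates, values) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stop("dates and values must have equal length", call. = FALSE)
  }
  if (length(dates) == 0L) stop("reference series is empty", call. = FALSE)
  if (anyNA(dates) || anyNA(values)) {
    stop("reference series contains missing values", call. = FALSE)
  }
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("reference dates must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    stop("reference values must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(date = dates, hi = values),
            class = c("reference_series", "data.frame"))
}

# ---- derivation helpers for the literature-based parameter priors --------

#' Tax saving implied by a deduction policy
#'
#' The saving per capita is the deduction cap, scaled by the average premium
#' ratio and the applicable tax-rate bracket.
#'
#' @param policy A [tax_policy()].
#' @return Saving in currency units.
#' @examples
#' tax_saving(tax_policy(8000, 0.85, 0.06, 2876, "2019-04-01"))  # 408
#' @export
tax_saving <- function(policy) {
  policy$tax_inct * policy$avg_prm_ratio * policy$tax_rate
}

#' Proportion of tax saved under a deduction policy
#'
#' @param policy A [tax_policy()].
#' @return `tax_saving(policy) / avg_tax`, a fraction.
#' @export
tax_saving_ratio <- function(policy) {
  tax_saving(policy) / policy$avg_tax
}

#' Average tax paid per capita from national accounts
#'
#' Total tax paid is gross national income minus gross national disposable
#' income; dividing by the mid-year population gives the per-capita figure.
#'
#' @param gni Gross national income (currency units).
#' @param gndi Gross national disposable income (currency units).
#' @param population Mid-year population count.
#' @return Average tax per capita.
#' @examples
#' avg_tax_per_capita(2988277e6, 2966685e6, 7507400)  # about 2876
#' @export
avg_tax_per_capita <- function(gni, gndi, population) {
  (gni - gndi) / population
}

#' Literature-derived occupancy-demand elasticity
#'
#' Bridges two published estimates: a waiting-time response of occupancy
#' (elasticity `wait_elasticity`) and a logistic-regression coefficient for
#' the probability of purchasing insurance given a long wait. The
#' coefficient is mapped through the inverse logit, rounded to the
#' precision at which it is tabulated, and multiplied by the waiting-time
#' elasticity.
#'
#' @param logit_p Logistic coefficient for purchasing insurance.
#' @param wait_elasticity Elasticity of waiting time with respect to
#'   occupancy.
#' @param digits Rounding applied to the inverse-logit probability before
#'   the product, matching the tabulated derivation chain.
#' @return The pre-calibration `OccuDmd` value.
#' @examples
#' occu_dmd_literature()  # 2.22 * 0.6014 = 1.3351
#' @export
occu_dmd_literature <- function(logit_p = 0.4115, wait_elasticity = 2.22,
                                digits = 4) {
  p <- round(stats::plogis(logit_p), digits)
  wait_elasticity * p
}

#' Literature-derived tax-demand elasticity
#'
#' A subsidy worth `subsidy_share` of the premium was observed to raise
#' voluntary individual insurance coverage by `uptake_increase` (absolute);
#' the ratio is the demand elasticity per unit proportion of premium saved.
#'
#' @param uptake_increase Absolute increase in coverage fraction.
#' @param subsidy_share Subsidy as a fraction of the premium.
#' @return The `TaxDmd` elasticity.
#' @examples
#' tax_dmd_literature()  # 0.036 / 0.26 = 0.138...
#' @export
tax_dmd_literature <- function(uptake_increase = 0.036, subsidy_share = 0.26) {
  uptake_increase / subsidy_share
}

# ---- config I/O -----------------------------------------------------------

scalar_param_fields <- c("use_hi", "selfpay", "severity_ftr", "occu_dmd",
                         "tax_dmd", "baseline_hi", "baseline_diff",
                         "delay_duration", "surge_peak_ratio",
                         "clamp_effect_nonneg", "diff_orientation")
tax_policy_fields <- c("tax_inct", "avg_prm_ratio", "tax_rate", "avg_tax",
                       "start_date")
scalar_param_optional <- c("delay_duration", "surge_peak_ratio",
                           "clamp_effect_nonneg", "diff_orientation")

# full-precision scalar rendering so that YAML round-trips are lossless
yaml_num <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- ifelse(is.na(x), ".na", formatC(x, format = "g", digits = 17))
  structure(out, class = "verbatim")
}

#' Write model parameters to a YAML config
#'
#' @param params A [scalar_params()] object.
#' @param policy A [tax_policy()] object (optional).
#' @param path File path; `NULL` returns the YAML text instead.
#' @return `path`, invisibly (or the YAML string when `path` is `NULL`).
#' @seealso [load_parameters()]
#' @export
write_parameters <- function(params, policy = NULL, path = NULL) {
  doc <- list(scalar = unclass(params))
  if (!is.null(policy)) {
    pol <- unclass(policy)
    pol$start_date <- format(pol$start_date, "%Y-%m-%d")
    doc$tax_policy <- pol
  }
  txt <- yaml::as.yaml(doc, handlers = list(numeric = yaml_num))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load model parameters from a YAML/JSON config
#'
#' The document must contain a `scalar` mapping with every required
#' parameter field and may contain a `tax_policy` mapping. Unknown keys are
#' rejected by name; missing and out-of-range fields raise errors naming
#' the field.
#'
#' @param path Path to a YAML (or JSON, by extension `.json`) document.
#' @param text Alternatively, the document text itself.
#' @return A list with elements `scalar` ([scalar_params()]) and
#'   `tax_policy` ([tax_policy()] or `NULL`).
#' @export
load_parameters <- function(path = NULL, text = NULL) {
  stopifnot(xor(is.null(path), is.null(text)))
  doc <- if (!is.null(text)) {
    yaml::yaml.load(text)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$scalar)) stop("config has no 'scalar' section", call. = FALSE)
  top_unknown <- setdiff(names(doc), c("scalar", "tax_policy"))
  if (length(top_unknown)) {
    stop(sprintf("unknown config section(s): %s",
                 paste(top_unknown, collapse = ", ")), call. = FALSE)
  }
  sc <- doc$scalar
  unknown <- setdiff(names(sc), scalar_param_fields)
  if (length(unknown)) {
    stop(sprintf("unknown scalar parameter field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(setdiff(scalar_param_fields, scalar_param_optional),
                     names(sc))
  if (length(missing)) {
    stop(sprintf("missing scalar parameter field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- do.call(scalar_params, sc)
  policy <- NULL
  if (!is.null(doc$tax_policy)) {
    tp <- doc$tax_policy
    unknown <- setdiff(names(tp), tax_policy_fields)
    if (length(unknown)) {
      stop(sprintf("unknown tax policy field(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    missing <- setdiff(tax_policy_fields, names(tp))
    if (length(missing)) {
      stop(sprintf("missing tax policy field(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    policy <- do.call(tax_policy, tp)
  }
  list(scalar = params, tax_policy = policy)
}

#' Write / read a reference survey series as CSV
#'
#' @param ref A [reference_series()].
#' @param path CSV path.
#' @return `path` invisibly; `load_reference_series()` returns the series.
#' @export
write_reference_series <- function(ref, path) {
  utils::write.csv(data.frame(date = format(ref$date, "%Y-%m-%d"),
                              hi = ref$hi),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_series
#' @export
load_reference_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "hi") %in% names(df))) {
    stop("reference CSV must have columns 'date' and 'hi'", call. = FALSE)
  }
  reference_series(df$date, df$hi)
}

#' @export
print.scalar_params <- function(x, ...) {
  cat("Scalar model parameters:\n")
  for (f in scalar_param_fields) cat(sprintf("  %-20s %s\n", f,
                                             format(x[[f]])))
  invisible(x)
}

#' @export
print.tax_policy <- function(x, ...) {
  cat(sprintf(paste0("Tax policy: deduction %g, premium ratio %g, rate %g,",
                     " avg tax %g, from %s\n"),
              x$tax_inct, x$avg_prm_ratio, x$tax_rate, x$avg_tax,
              format(x$start_date)))
  cat(sprintf("  per-capita saving %g (%.1f%% of avg tax)\n", tax_saving(x),
              100 * tax_saving_ratio(x)))
  invisible(x)
}
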