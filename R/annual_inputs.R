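#' Annual health-system input series
#'
#' One row per labelled year with the five series the simulator needs:
#' daily admission demand at the winter-surge peak and outside the surge,
#' public average length of stay, and public/private bed counts. Each
#' variable carries a calendar convention: most series are reported for
#' fiscal years (April 1 to March 31 of the next year); private beds are
#' commonly reported for natural years. Series are interpreted as
#' piecewise-constant step functions over their labelled year (an optional
#' linear-interpolation mode is available in the simulator).
#'
#' @param year Integer vector of contiguous year labels.
#' @param inpt_surge,inpt_nonsurge Daily admission demand (admissions/day)
#'   at the surge peak and outside the surge window.
#' @param pu_los Public average length of stay (days).
#' @param pu_beds,pr_beds Public and private bed counts.
#' @param year_convention Named character vector mapping each variable to
#'   `"fiscal_apr_mar"` or `"natural"`.
#' @return An `annual_inputs` data frame.
#' @export
annual_inputs <- function(year, inpt_surge, inpt_nonsurge, pu_los, pu_beds,
                          pr_beds,
                          year_convention = c(inpt_surge = "fiscal_apr_mar",
                                              inpt_nonsurge = "fiscal_apr_mar",
                                              pu_los = "fiscal_apr_mar",
                                              pu_beds = "fiscal_apr_mar",
                                              pr_beds = "natural")) {
  df <- data.frame(year = as.integer(year),
                   inpt_surge = as.numeric(inpt_surge),
                   inpt_nonsurge = as.numeric(inpt_nonsurge),
                   pu_los = as.numeric(pu_los),
                   pu_beds = as.numeric(pu_beds),
                   pr_beds = as.numeric(pr_beds))
  vars <- setdiff(names(df), "year")
  if (!setequal(names(year_convention), vars) ||
      !all(year_convention %in% c("fiscal_apr_mar", "natural"))) {
    stop("year_convention must name every series as fiscal_apr_mar/natural",
         call. = FALSE)
  }
  if (anyNA(df)) stop("annual inputs contain missing values", call. = FALSE)
  for (v in vars) {
    if (any(df[[v]] <= 0)) {
      stop(sprintf("annual input '%s' has a non-positive value", v),
           call. = FALSE)
    }
  }
  if (is.unsorted(df$year, strictly = TRUE)) {
    stop("year labels must be strictly increasing", call. = FALSE)
  }
  if (length(df$year) > 1L && any(diff(df$year) != 1L)) {
    gap <- df$year[which(diff(df$year) != 1L)[1]] + 1L
    stop(sprintf("gap in year coverage: year %d is missing", gap),
         call. = FALSE)
  }
  structure(df, year_convention = year_convention[vars],
            class = c("annual_inputs", "data.frame"))
}

#' Read / write annual inputs as CSV
#'
#' The CSV has columns `year, inpt_surge, inpt_nonsurge, pu_los, pu_beds,
#' pr_beds`, one row per year.
#'
#' @param path CSV path.
#' @param year_convention Passed to [annual_inputs()].
#' @return An `annual_inputs` object.
#' @export
load_annual_inputs <- function(path,
                               year_convention = c(
                                 inpt_surge = "fiscal_apr_mar",
                                 inpt_nonsurge = "fiscal_apr_mar",
                                 pu_los = "fiscal_apr_mar",
                                 pu_beds = "fiscal_apr_mar",
                                 pr_beds = "natural")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "inpt_surge", "inpt_nonsurge", "pu_los", "pu_beds",
            "pr_beds")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("annual-inputs CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  annual_inputs(df$year, df$inpt_surge, df$inpt_nonsurge, df$pu_los,
                df$pu_beds, df$pr_beds, year_convention = year_convention)
}

#' @rdname load_annual_inputs
#' @param inputs An `annual_inputs` object to write.
#' @export
write_annual_inputs <- function(inputs, path) {
  utils::write.csv(as.data.frame(inputs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Bundled Hong Kong 2009-2019 configuration
#'
#' Returns the calibrated Hong Kong parameterization: the behavioural
#' scalars (with the calibrated severity ratio 0.39 and occupancy-demand
#' elasticity 0.5), the 2019 tax-incentive policy (deduction cap 8000,
#' average premium ratio 0.85, 6% bracket, average tax 2876, active from
#' 2019-04-01), the 2009-2019 annual series, and the multivariate
#' sensitivity specification.
#'
#' `baseline_hi` (the 2009 survey penetration) is household-survey data
#' that is not bundled; it must be supplied by the user before simulating.
#' The literature-derived pre-calibration elasticity (see
#' [occu_dmd_literature()], about 1.3351) and severity ratio 0.4 are
#' documented alternatives to the calibrated values shipped here.
#'
#' @param baseline_hi Baseline insurance penetration in 2009 (fraction).
#'   Defaults to `NA`, which must be replaced before simulation.
#' @return A list with elements `scalar`, `tax_policy`, `annual`,
#'   `sensitivity`.
#' @examples
#' b <- hk_default_bundle(baseline_hi = 0.3)
#' tax_saving(b$tax_policy)  # 408
#' @export
hk_default_bundle <- function(baseline_hi = NA_real_) {
  annual <- load_annual_inputs(system.file("extdata",
                                           "hk_annual_inputs.csv",
                                           package = "hidemand",
                                           mustWork = TRUE))
  scalar <- scalar_params(use_hi = 0.57, selfpay = 0.06,
                          severity_ftr = 0.39, occu_dmd = 0.5,
                          tax_dmd = 0.138,
                          baseline_hi = baseline_hi,
                          baseline_diff = 0.055,
                          delay_duration = 365,
                          surge_peak_ratio = 1.196)
  policy <- tax_policy(8000, 0.85, 0.06, 2876, "2019-04-01")
  list(scalar = scalar, tax_policy = policy, annual = annual,
       sensitivity = hk_sensitivity_spec())
}
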