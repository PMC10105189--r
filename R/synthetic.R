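#' Synthetic health-system scenario specification
#'
#' Describes a fully synthetic dual-track health system with the same
#' statistical structure the simulator assumes: piecewise-annual inputs
#' with geometric growth, a winter surge at a fixed peak ratio, and sparse
#' noisy survey observations of the simulated insurance penetration.
#' Scenarios make download-free testing and parameter-recovery studies
#' possible.
#'
#' @param n_years Number of labelled years.
#' @param start_year First year label; the simulation horizon runs from
#'   April 1 of `start_year` to December 31 of the last year.
#' @param base_daily_admissions Non-surge admissions/day in the first year.
#' @param admission_growth Annual growth rate of admission demand.
#' @param beds_pu,beds_pr First-year bed counts.
#' @param beds_pu_growth,beds_pr_growth Annual bed growth rates.
#' @param pu_los Public average length of stay (days, constant).
#' @param true_params [scalar_params()] generating the scenario
#'   (`baseline_hi` must be set).
#' @param policy Optional [tax_policy()] active in the scenario.
#' @param survey_dates Dates of the synthetic survey observations (within
#'   the horizon).
#' @param survey_noise_sd Gaussian observation noise on the penetration
#'   fraction (0 for noiseless).
#' @param seed RNG seed for the observation noise.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(n_years = 8, start_year = 2009,
                          base_daily_admissions = 4000,
                          admission_growth = 0.015,
                          beds_pu = 25000, beds_pr = 5000,
                          beds_pu_growth = 0.005, beds_pr_growth = 0.01,
                          pu_los = 7.4,
                          true_params,
                          policy = NULL,
                          survey_dates = NULL,
                          survey_noise_sd = 0,
                          seed = 1L) {
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (base_daily_admissions <= 0 || beds_pu <= 0 || beds_pr <= 0 ||
      pu_los <= 0) {
    stop("scenario magnitudes must be positive", call. = FALSE)
  }
  validate_scalar_params(true_params)
  if (is.na(true_params$baseline_hi)) {
    stop("true_params$baseline_hi must be set", call. = FALSE)
  }
  years <- seq(start_year, length.out = n_years)
  horizon <- c(as.Date(sprintf("%d-04-01", start_year)),
               as.Date(sprintf("%d-12-31", years[n_years])))
  if (is.null(survey_dates)) {
    survey_dates <- as.Date(sprintf("%d-06-01", years[-1]))
  }
  survey_dates <- as.Date(survey_dates)
  if (any(survey_dates < horizon[1] | survey_dates > horizon[2])) {
    stop("survey_dates must lie within the scenario horizon", call. = FALSE)
  }
  if (survey_noise_sd < 0) stop("survey_noise_sd must be >= 0",
                                call. = FALSE)
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 base_daily_admissions = base_daily_admissions,
                 admission_growth = admission_growth,
                 beds_pu = beds_pu, beds_pr = beds_pr,
                 beds_pu_growth = beds_pu_growth,
                 beds_pr_growth = beds_pr_growth,
                 pu_los = pu_los, true_params = true_params,
                 policy = policy,
                 survey_dates = survey_dates,
                 survey_noise_sd = survey_noise_sd,
                 seed = as.integer(seed),
                 horizon = horizon),
            class = "scenario_spec")
}

#' Generate a synthetic scenario
#'
#' Builds the annual input series (surge level = non-surge level times the
#' peak ratio of `true_params`, exactly), simulates the model under the
#' generating parameters, and emits survey observations equal to the
#' simulated penetration at the survey dates plus Gaussian noise (clipped
#' to `[0, 1]`). Deterministic under the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @return A list with `annual` ([annual_inputs()]), `reference`
#'   ([reference_series()]), `params` (the generating [scalar_params()]),
#'   `policy`, `trajectory` (the noiseless generating run) and `horizon`.
#' @export
generate_scenario <- function(spec) {
  years <- seq(spec$start_year, length.out = spec$n_years)
  k <- seq_len(spec$n_years) - 1
  nonsurge <- spec$base_daily_admissions * (1 + spec$admission_growth)^k
  annual <- annual_inputs(
    year = years,
    inpt_surge = nonsurge * spec$true_params$surge_peak_ratio,
    inpt_nonsurge = nonsurge,
    pu_los = rep(spec$pu_los, spec$n_years),
    pu_beds = spec$beds_pu * (1 + spec$beds_pu_growth)^k,
    pr_beds = spec$beds_pr * (1 + spec$beds_pr_growth)^k)
  calendar <- surge_calendar(peak_ratio = spec$true_params$surge_peak_ratio)
  traj <- simulate_insurance(spec$true_params, annual, policy = spec$policy,
                             calendar = calendar,
                             start = spec$horizon[1], end = spec$horizon[2])
  idx <- match(spec$survey_dates, traj$date)
  stopifnot(!anyNA(idx))
  hi_true <- traj$hi[idx]
  set.seed(spec$seed)
  obs <- hi_true + stats::rnorm(length(idx), 0, spec$survey_noise_sd)
  obs <- pmin(pmax(obs, 0), 1)
  list(annual = annual,
       reference = reference_series(spec$survey_dates, obs),
       params = spec$true_params,
       policy = spec$policy,
       trajectory = traj,
       horizon = spec$horizon,
       calendar = calendar)
}
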