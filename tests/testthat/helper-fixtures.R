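# shared fixtures: a plausible mid-size dual-track system and small
# synthetic scenarios used across the suite

base_test_params <- function(...) {
  args <- list(use_hi = 0.57, selfpay = 0.06, severity_ftr = 0.39,
               occu_dmd = 0.5, tax_dmd = 0.138, baseline_hi = 0.3,
               baseline_diff = 0.055)
  over <- list(...)
  args[names(over)] <- over
  do.call(scalar_params, args)
}

hk_test_bundle <- function(baseline_hi = 0.3) {
  hk_default_bundle(baseline_hi = baseline_hi)
}

# constant-input annual series (no growth) for equilibrium checks
flat_annual <- function(years = 2009:2012, nonsurge = 1000, ratio = 1.196,
                        pu_los = 7, pu_beds = 10000, pr_beds = 2500) {
  n <- length(years)
  annual_inputs(years,
                inpt_surge = rep(nonsurge * ratio, n),
                inpt_nonsurge = rep(nonsurge, n),
                pu_los = rep(pu_los, n),
                pu_beds = rep(pu_beds, n),
                pr_beds = rep(pr_beds, n))
}

# small synthetic scenario for recovery studies: a capacity-expansion
# system (admissions +3%/yr, private beds +5%/yr against flat public
# capacity) observed by bimonthly surveys after a two-year warm-up --
# the differential growth makes the occupancy-gap trajectory informative
# enough to separate the severity ratio from the demand elasticity
recovery_scenario <- function(noise_sd = 0, seed = 1,
                              severity_ftr = 0.39, occu_dmd = 0.5,
                              n_years = 8) {
  p <- base_test_params(severity_ftr = severity_ftr, occu_dmd = occu_dmd)
  years <- seq(2009, length.out = n_years)
  sdates <- seq(as.Date(sprintf("%d-03-01", years[3])),
                as.Date(sprintf("%d-12-01", years[n_years])),
                by = "2 months")
  spec <- scenario_spec(n_years = n_years, true_params = p,
                        admission_growth = 0.03,
                        beds_pu_growth = 0, beds_pr_growth = 0.05,
                        survey_dates = sdates,
                        survey_noise_sd = noise_sd, seed = seed)
  generate_scenario(spec)
}

recovery_grid <- function() {
  calibration_spec(severity_grid = seq(0.35, 0.43, by = 0.02),
                   occu_dmd_grid = seq(0.3, 0.7, by = 0.1),
                   structure_variants = "plain",
                   window = as.Date(c("2011-03-01", "2016-12-01")))
}

# Chebyshev distance in grid cells between recovered and true parameters
recovery_cells_off <- function(result, truth, sev_step = 0.02,
                               od_step = 0.1) {
  max(abs(result$best_params$severity_ftr - truth$severity_ftr) / sev_step,
      abs(result$best_params$occu_dmd - truth$occu_dmd) / od_step)
}
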