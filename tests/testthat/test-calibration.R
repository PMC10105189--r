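fake_traj <- function(dates, hi) {
  data.frame(date = as.Date(dates), hi = hi)
}

test_that("MAPE matches hand arithmetic on survey points", {
  ref <- reference_series(c("2016-06-01", "2018-06-01"), c(0.3243, 0.3677))
  traj <- fake_traj(seq(as.Date("2015-01-01"), as.Date("2019-12-31"),
                        by = "day"), 0.33)
  traj$hi[traj$date == as.Date("2018-06-01")] <- 0.36
  got <- mape(traj, ref)
  expect_equal(got, (0.0057 / 0.3243 + 0.0077 / 0.3677) / 2 * 100,
               tolerance = 1e-10)
  expect_equal(got, 1.926, tolerance = 1e-3)

  # identical series -> 0; single point 3% high -> 3%
  traj$hi <- 0.3243
  expect_equal(mape(traj, reference_series("2016-06-01", 0.3243)), 0)
  traj$hi <- 0.3243 * 1.03
  expect_equal(mape(traj, reference_series("2016-06-01", 0.3243)), 3)
})

test_that("MAPE is scale-invariant and errors on an empty window", {
  ref <- reference_series(c("2016-06-01", "2018-06-01"), c(0.32, 0.37))
  traj <- fake_traj(seq(as.Date("2015-01-01"), as.Date("2019-12-31"),
                        by = "day"), 0.35)
  scaled_ref <- reference_series(ref$date, ref$hi * 0.1)
  scaled_traj <- traj
  scaled_traj$hi <- traj$hi * 0.1
  expect_equal(mape(scaled_traj, scaled_ref), mape(traj, ref))
  expect_error(mape(traj, ref, window = as.Date(c("2009-01-01",
                                                  "2009-12-31"))),
               "window")
})

test_that("fieldwork-year aggregation averages the simulated year", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2019-12-31"), by = "day")
  traj <- fake_traj(dates, seq(0.30, 0.40, length.out = length(dates)))
  ref <- reference_series("2018-06-01", 0.35)
  d <- as.Date("2018-06-01")
  expected <- mean(traj$hi[traj$date > d - 365 & traj$date <= d])
  expect_equal(mape(traj, ref, aggregate = "fieldwork_year"),
               abs(expected - 0.35) / 0.35 * 100)
})

test_that("a single-cell grid returns that cell with its MAPE", {
  sc <- recovery_scenario()
  spec <- calibration_spec(severity_grid = 0.39, occu_dmd_grid = 0.5,
                           structure_variants = "plain",
                           window = as.Date(c("2011-01-01", "2014-12-31")))
  res <- calibrate(spec, sc$params, sc$annual, sc$reference,
                   start = sc$horizon[1], end = sc$horizon[2],
                   calendar = sc$calendar)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$best_params$severity_ftr, 0.39)
  expect_equal(res$best_mape, res$table$mape)
  expect_equal(res$best_mape, 0, tolerance = 1e-10)
})

test_that("calibration recovers the generating parameters without noise", {
  sc <- recovery_scenario(severity_ftr = 0.39, occu_dmd = 0.5)
  res <- calibrate(recovery_grid(), sc$params, sc$annual, sc$reference,
                   start = sc$horizon[1], end = sc$horizon[2],
                   calendar = sc$calendar)
  expect_equal(res$best_params$severity_ftr, 0.39)
  expect_equal(res$best_params$occu_dmd, 0.5)
  expect_equal(res$best_mape, min(res$table$mape))
})

test_that("refining the grid never increases the best MAPE", {
  sc <- recovery_scenario(noise_sd = 0.005, seed = 7)
  win <- as.Date(c("2011-01-01", "2014-12-31"))
  coarse <- calibration_spec(severity_grid = c(0.37, 0.41),
                             occu_dmd_grid = c(0.4, 0.6),
                             structure_variants = "plain", window = win)
  fine <- calibration_spec(severity_grid = c(0.37, 0.39, 0.41),
                           occu_dmd_grid = c(0.4, 0.5, 0.6),
                           structure_variants = "plain", window = win)
  args <- list(base_params = sc$params, inputs = sc$annual,
               reference = sc$reference, start = sc$horizon[1],
               end = sc$horizon[2], calendar = sc$calendar)
  m_coarse <- do.call(calibrate, c(list(coarse), args))$best_mape
  m_fine <- do.call(calibrate, c(list(fine), args))$best_mape
  expect_lte(m_fine, m_coarse)
})

test_that("calibration outputs are written as CSV and YAML", {
  sc <- recovery_scenario()
  spec <- calibration_spec(severity_grid = c(0.38, 0.39),
                           occu_dmd_grid = 0.5,
                           structure_variants = "plain",
                           window = as.Date(c("2011-01-01", "2014-12-31")))
  res <- calibrate(spec, sc$params, sc$annual, sc$reference,
                   start = sc$horizon[1], end = sc$horizon[2],
                   calendar = sc$calendar)
  tpath <- withr::local_tempfile(fileext = ".csv")
  bpath <- withr::local_tempfile(fileext = ".yaml")
  write_calibration_result(res, tpath, bpath)
  tab <- utils::read.csv(tpath)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("severity_ftr", "occu_dmd", "variant", "mape"))
  best <- yaml::read_yaml(bpath)$best
  expect_equal(best$severity_ftr, res$best_params$severity_ftr)
})
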