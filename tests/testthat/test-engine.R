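test_that("admission split matches the closed-form shares and conserves", {
  s <- split_admissions(3945, 0.36, 0.57, 0.06)
  # direct arithmetic: insured staying public + uninsured staying public
  expect_equal(s$pu_admit, 3945 * (0.36 * (1 - 0.57) + 0.64 * (1 - 0.06)))
  expect_equal(s$pu_admit, 2984.0, tolerance = 1e-5)
  expect_equal(s$pr_admit, 961.0, tolerance = 1e-5)
  expect_identical(s$pu_admit + s$pr_admit, 3945)

  expect_equal(split_admissions(100, 0, 0.7, 0)$pu_admit, 100)
  expect_equal(split_admissions(100, 1, 1, 0.5)$pr_admit, 100)
  expect_error(split_admissions(10, 1.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("occupancy rates follow the Little's-law flow form", {
  expect_equal(occupancy_public(2984.0, 7.5, 25661), 0.8722, tolerance = 1e-4)
  expect_equal(occupancy_public(0, 7.5, 25661), 0)
  expect_equal(occupancy_public(2984, 7.5, 2 * 25661),
               occupancy_public(2984, 7.5, 25661) / 2)
  expect_equal(occupancy_private(961.0, 7.5, 0.39, 5056), 0.5560,
               tolerance = 1e-4)
  expect_equal(occupancy_private(961, 7.5, 1, 5056),
               occupancy_public(961, 7.5, 5056))
  expect_error(occupancy_public(10, 7, 0), "pu_beds")

  expect_equal(occupancy_gap(0.8722, 0.5560), 0.3162)
  expect_equal(occupancy_gap(0.5, 0.5), 0)
  expect_equal(occupancy_gap(0.8, 0.6, "private_minus_public"),
               -occupancy_gap(0.8, 0.6, "public_minus_private"))
})

test_that("penetration level adds effects with optional clamping and clips", {
  expect_equal(hi_level(0.30, 0.02, 0), 0.32)
  expect_equal(hi_level(0.30, -0.01, 0, clamp_effect_nonneg = TRUE), 0.30)
  expect_equal(hi_level(0.30, -0.01, 0), 0.29)
  expect_equal(hi_level(0.30, 0.04, 0.0196), 0.3596)
  expect_equal(hi_level(0.9, 0.5, 0.2), 1)
  expect_error(hi_level(1.2, 0), "baseline_hi")
})

test_that("one simulated step reproduces a hand-written recursion exactly", {
  p <- base_test_params(occu_dmd = 0.4, baseline_diff = 0.05)
  a <- flat_annual(2009:2010, nonsurge = 1200, pu_los = 6, pu_beds = 9000,
                   pr_beds = 2000)
  traj <- simulate_insurance(p, a, start = "2009-06-01", end = "2009-06-05")

  # independent spreadsheet-style recursion
  tau <- 365 / 3
  hi <- p$baseline_hi; u_pu <- 0; u_pr <- 0
  o <- NULL
  rows <- list()
  for (i in 1:5) {
    pu_adm <- 1200 * (hi * (1 - p$use_hi) + (1 - hi) * (1 - p$selfpay))
    pr_adm <- 1200 - pu_adm
    pu_oc <- pu_adm * 6 / 9000
    pr_oc <- pr_adm * 6 * p$severity_ftr / 2000
    gap <- pu_oc - pr_oc
    occ_in <- (gap - p$baseline_diff) * p$occu_dmd
    if (i == 1) o <- rep(occ_in * tau, 3)
    rows[[i]] <- c(pu_adm, pr_adm, u_pu, u_pr, pu_oc, pr_oc, gap,
                   o[3] / tau, hi)
    o <- c(o[1] + (occ_in - o[1] / tau),
           o[2] + (o[1] - o[2]) / tau,
           o[3] + (o[2] - o[3]) / tau)
    u_pu <- max(0, u_pu + pu_adm - u_pu / 6)
    u_pr <- max(0, u_pr + pr_adm - u_pr / (6 * p$severity_ftr))
    hi <- min(max(p$baseline_hi + o[3] / tau, 0), 1)
  }
  oracle <- do.call(rbind, rows)
  got <- as.matrix(traj[, c("pu_admit", "pr_admit", "using_pu", "using_pr",
                            "pu_occu", "pr_occu", "diff_occu",
                            "effect_occu", "hi")])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("stocks reach the Little's-law equilibrium and match the flow
           occupancy", {
  p <- base_test_params(occu_dmd = 0)  # freeze the feedback
  a <- flat_annual(2009:2011, nonsurge = 1000, pu_los = 7)
  cal <- surge_calendar(peak_ratio = 1)  # no seasonality
  traj <- simulate_insurance(p, a, calendar = cal, start = "2009-04-01",
                             end = "2009-10-01")
  n <- nrow(traj)
  # after 10x LoS days the stock is admissions x LoS within 0.1%
  at <- traj[traj$t >= 10 * 7, ]
  expect_true(all(abs(at$using_pu - at$pu_admit * 7) / (at$pu_admit * 7)
                  < 0.001))
  # stock-based occupancy equals the flow-based one within 0.1%
  traj2 <- simulate_insurance(p, a, calendar = cal, start = "2009-04-01",
                              end = "2009-10-01", occupancy_basis = "stock")
  at2 <- traj2[traj2$t >= 10 * 7, ]
  expect_true(all(abs(at2$pu_occu - at$pu_occu) / at$pu_occu < 0.001))
  expect_true(all(abs(at2$pr_occu - at$pr_occu) / at$pr_occu < 0.001))
})

test_that("with all effects disabled the penetration stays at baseline", {
  p <- base_test_params(occu_dmd = 0)
  a <- flat_annual(2009:2011)
  traj <- simulate_insurance(p, a, start = "2009-04-01", end = "2011-12-31")
  expect_identical(unique(traj$hi), p$baseline_hi)
  expect_identical(unique(traj$effect_tax), 0)
})

test_that("higher penetration shifts burden toward the private sector", {
  # the balancing loop: raising HI lowers public occupancy, raises private
  # occupancy, and narrows the (public - private) gap at the next step
  s_lo <- split_admissions(4000, 0.30, 0.57, 0.06)
  s_hi <- split_admissions(4000, 0.35, 0.57, 0.06)
  oc <- function(s) {
    pu <- occupancy_public(s$pu_admit, 7.4, 24000)
    pr <- occupancy_private(s$pr_admit, 7.4, 0.39, 4500)
    c(pu = pu, pr = pr, gap = occupancy_gap(pu, pr))
  }
  lo <- oc(s_lo); hi <- oc(s_hi)
  expect_lt(hi[["pu"]], lo[["pu"]])
  expect_gt(hi[["pr"]], lo[["pr"]])
  expect_lt(hi[["gap"]], lo[["gap"]])
})

test_that("more private beds lower private occupancy pointwise", {
  b <- hk_test_bundle()
  t1 <- simulate_insurance(b$scalar, b$annual, b$tax_policy,
                           end = "2012-12-31")
  a2 <- b$annual
  a2$pr_beds <- a2$pr_beds * 2
  t2 <- simulate_insurance(b$scalar, a2, b$tax_policy, end = "2012-12-31")
  warm <- t1$date >= as.Date("2010-04-01")
  expect_true(all(t2$pr_occu[warm] < t1$pr_occu[warm]))
})

test_that("the decade shows an initial transient that later settles", {
  b <- hk_test_bundle(baseline_hi = 0.3)
  traj <- simulate_insurance(b$scalar, b$annual, b$tax_policy)
  yr <- as.integer(format(traj$date, "%Y"))
  early <- max(abs(traj$hi[yr <= 2010] - 0.3))
  yoy <- vapply(2015:2019, function(y)
    abs(mean(traj$hi[yr == y]) - mean(traj$hi[yr == y - 1])), numeric(1))
  expect_gt(early, max(yoy))
})

test_that("tax effect is zero before activation and builds up after", {
  b <- hk_test_bundle(baseline_hi = 0.3)
  traj <- simulate_insurance(b$scalar, b$annual, b$tax_policy)
  pre <- traj$date < as.Date("2019-04-01")
  expect_true(all(traj$effect_tax[pre] == 0))
  post <- traj$effect_tax[!pre]
  expect_true(all(diff(post) >= 0))
  expect_gt(tail(post, 1), 0)
  # the delayed effect approaches (saving / avg tax) x elasticity from below
  expect_lt(tail(post, 1), tax_saving_ratio(b$tax_policy) * 0.138)
})

test_that("substep integration refines without changing the solution much", {
  p <- base_test_params()
  a <- flat_annual(2009:2010)
  t1 <- simulate_insurance(p, a, start = "2009-04-01", end = "2009-12-31")
  t2 <- simulate_insurance(p, a, start = "2009-04-01", end = "2009-12-31",
                           dt = 0.5)
  expect_equal(nrow(t2), nrow(t1))
  expect_equal(tail(t2$hi, 1), tail(t1$hi, 1), tolerance = 0.005)
  t3 <- simulate_insurance(p, a, start = "2009-04-01", end = "2009-12-31",
                           dt = 0.5, emit_substeps = TRUE)
  expect_equal(nrow(t3), 2 * nrow(t1))
  expect_error(simulate_insurance(p, a, dt = 0.3), "dt")
})

test_that("trajectories round-trip through the CSV writer with metadata", {
  b <- hk_test_bundle()
  traj <- simulate_insurance(b$scalar, b$annual, b$tax_policy,
                             start = "2019-01-01", end = "2019-12-31")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  header <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("dt: 1", header)))
  expect_true(any(grepl("param severity_ftr: 0.39", header)))
  back <- read_trajectory(path)
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$hi, traj$hi, tolerance = 1e-12)
  expect_s3_class(back$date, "Date")
})

test_that("a one-day horizon returns the initial state", {
  p <- base_test_params()
  a <- flat_annual(2009:2010)
  traj <- simulate_insurance(p, a, start = "2009-06-01", end = "2009-06-01")
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$using_pu, 0)
  expect_equal(traj$using_pr, 0)
  expect_equal(traj$hi, p$baseline_hi)
})
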