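# Markov cohort engine: accrual conventions, incremental outcomes,
# ICERs, NMB, threshold crossing, baseline-utility calibration.

test_that("cycle-1 accrual follows the stated conventions (hand oracle)", {
  p <- base_calibrated()
  led <- run_arm(p, surgery_arm(p), 1)
  # savings: full cycle-start survival, one year of discounting
  expect_equal(led$savings[1], 157 * 13.2 / 1.03, tolerance = 1e-12)
  expect_equal(round(led$savings[1], 1), 2012.0)
  # utility weighted by end-of-cycle survival
  q1 <- death_prob(make_gompertz_life_table(p$mortality$q0,
                                            p$mortality$gompertz_slope,
                                            p$start_age, p$max_age),
                   p$mortality, p$start_age, 13.2)
  expect_equal(led$utility[1],
               (p$u_base + 0.0042 * 13.2) * (1 - q1) / 1.03,
               tolerance = 1e-12)
  expect_equal(led$alive_start[1], 1)
  expect_equal(led$alive_end[1], 1 - q1)
})

test_that("degenerate horizons and uncalibrated parameters are rejected", {
  p <- base_calibrated()
  expect_error(run_arm(p, surgery_arm(p), 0), "horizon")
  expect_error(run_arm(p, surgery_arm(p), 2.5), "horizon")
  expect_error(run_arm(model_parameters(), surgery_arm(), 5), "u_base")
  expect_error(run_arm(p, surgery_arm(p), 200), "life-table")
})

test_that("ledger survival columns are coherent probabilities", {
  p <- base_calibrated()
  for (arm in list(surgery_arm(p), comparator_arm(p))) {
    led <- run_arm(p, arm, 40)
    expect_true(all(led$alive_end <= led$alive_start + 1e-15))
    expect_true(all(diff(led$alive_end) <= 0))
    expect_true(all(led$alive_start <= 1))
    # discounted quantities never exceed undiscounted counterparts
    expect_true(all(led$life_years_disc <= led$life_years + 1e-15))
  }
})

test_that("zero discount, zero mortality: savings match the closed form", {
  p <- model_parameters(mortality = mortality_model(1e-12, 0, 0),
                        u_base = 1, discount_rate = 0)
  h <- 9
  led <- run_arm(p, surgery_arm(p), h)
  d <- delta_bmi_series(surgery_arm(p), p$regain, h)
  expect_equal(cumsum(led$savings), 157 * cumsum(d), tolerance = 1e-8)
})

test_that("constant hazard, no BMI link: utility follows the geometric form", {
  q <- 0.008
  p <- model_parameters(mortality = mortality_model(q, 0, 0),
                        u_base = 0.9, discount_rate = 0)
  led <- run_arm(p, comparator_arm(p), 10)
  expect_equal(led$utility, 0.9 * (1 - q)^(1:10), tolerance = 1e-12)
})

test_that("identical arms yield null incremental outcomes", {
  p <- base_calibrated()
  led <- run_arm(p, comparator_arm(p), 7)
  inc <- incremental_outcomes(led, led, p, 1:7)
  expect_equal(inc$savings, rep(0, 7))
  expect_equal(inc$added_qalys, rep(0, 7))
  expect_equal(inc$added_life_years, rep(0, 7))
  expect_equal(inc$incremental_cost, rep(25854, 7))
  expect_true(all(inc$icer_status == "undefined"))
  expect_true(all(is.na(inc$icer)))
})

test_that("icer reports ratios and dominance flags correctly", {
  p <- base_calibrated()
  inc <- base_case_results(p, 1:7)
  got <- icer(inc, 7)
  expect_equal(got$status, "well_defined")
  expect_equal(got$icer, inc$incremental_cost[7] / inc$added_qalys[7])
  expect_error(icer(inc, 12), "horizon")
  # hand-built quadrants via the exported helper surface
  expect_equal(bariCEA:::icer_status(-1, 0.1), "dominant")
  expect_equal(bariCEA:::icer_status(1000, -0.1), "dominated")
  expect_equal(bariCEA:::icer_status(1000, 0), "undefined")
})

test_that("NMB is affine in WTP and sign-consistent with the ICER", {
  p <- base_calibrated()
  inc <- base_case_results(p, 1:7)
  w <- c(0, 5e4, 1e5, 1.5e5, 2e5)
  for (h in c(2, 4, 7)) {
    row <- inc[inc$horizon == h, ]
    nmb <- vapply(w, function(x) x * row$added_qalys - row$incremental_cost, 0)
    # affine and increasing (positive QALY gain)
    expect_equal(diff(nmb), rep(5e4 * row$added_qalys, 4), tolerance = 1e-9)
    expect_equal(nmb[3] >= 0, row$icer <= 1e5)
  }
  expect_equal(net_monetary_benefit(inc, 1e5), inc$nmb)
})

test_that("threshold crossing behaves at the WTP extremes", {
  p <- base_calibrated()
  inc <- base_case_results(p, 1:7)
  expect_identical(threshold_crossing_year(inc, Inf), 1L)
  expect_identical(threshold_crossing_year(inc, 0), NA_integer_)
  expect_error(threshold_crossing_year(inc[c(2, 4), ], 1e5), "consecutive")
})

test_that("baseline-utility calibration recovers a known value", {
  p <- base_calibrated()
  p$u_base <- 0.95
  target <- base_case_results(p, 1)$added_qalys[1]
  p$u_base <- NA_real_
  u <- calibrate_baseline_utility(p, target)
  expect_equal(as.numeric(u), 0.95, tolerance = 1e-6)
})

test_that("baseline-utility calibration fails when QALYs cannot respond", {
  p <- base_calibrated()
  p$hrql_gain_per_bmi <- 0
  p$mortality <- mortality_model(p$mortality$q0, p$mortality$gompertz_slope, 0)
  expect_error(calibrate_baseline_utility(p, 0.060), "no root")
  expect_error(calibrate_baseline_utility(p, -0.1), "positive")
})

test_that("cost and savings shifts move every ICER in the expected direction", {
  p <- base_calibrated()
  base <- base_case_results(p, 1:7)
  p2 <- p
  p2$cost_params$intervention_cost <- 2 * p$cost_params$intervention_cost
  doubled <- base_case_results(p2, 1:7)
  expect_true(all(doubled$icer > base$icer))
  p3 <- p
  p3$savings_per_bmi <- p$savings_per_bmi * 1.5
  richer <- base_case_results(p3, 1:7)
  expect_true(all(richer$icer < base$icer))
})
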