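# Moment-matched uncertainty distributions, Monte-Carlo propagation,
# CEAC, percentile intervals, one-way sweeps.

test_that("gamma moment matching is exact in distribution", {
  sh <- gamma_from_moments(25854, 2044 / sqrt(11))
  # independent oracle: sample moments of a large draw
  set.seed(1)
  x <- rgamma(1e6, shape = sh[["shape"]], scale = sh[["scale"]])
  expect_equal(mean(x), 25854, tolerance = 0.005)
  expect_equal(sd(x), 2044 / sqrt(11), tolerance = 0.005)
  # shape formula special case: mean = sd is the exponential shape
  expect_equal(gamma_from_moments(5, 5)[["shape"]], 1)
  expect_equal(gamma_from_moments(157, 47)[["shape"]], (157 / 47)^2)
  expect_error(gamma_from_moments(-1, 2), "positive")
  expect_error(gamma_from_moments(1, 0), "positive")
})

test_that("beta moment matching is exact in distribution and feasibility-checked", {
  ab <- beta_from_moments(0.0042, 0.0011)
  set.seed(2)
  x <- rbeta(1e6, ab[["alpha"]], ab[["beta"]])
  expect_equal(mean(x), 0.0042, tolerance = 0.005)
  expect_equal(sd(x), 0.0011, tolerance = 0.005)
  expect_equal(ab[["alpha"]], 14.5, tolerance = 0.01)
  expect_equal(ab[["beta"]], 3441, tolerance = 0.01)
  # symmetric case
  s <- beta_from_moments(0.5, 0.1)
  expect_equal(s[["alpha"]], s[["beta"]])
  expect_error(beta_from_moments(0.5, 0.51), "[Ii]nfeasible")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("PSA is bit-reproducible under a fixed seed", {
  p <- base_calibrated()
  a <- run_psa(p, n = 50, seed = 99, horizons = c(4, 7))
  b <- run_psa(p, n = 50, seed = 99, horizons = c(4, 7))
  expect_identical(a$draws, b$draws)
  expect_identical(a$outcomes, b$outcomes)
  c2 <- run_psa(p, n = 50, seed = 100, horizons = c(4, 7))
  expect_false(identical(a$draws, c2$draws))
})

test_that("near-degenerate distributions collapse to the base case", {
  p <- base_calibrated()
  d <- parameter_distributions(p)
  for (nm in names(d)) {
    tiny <- d[[nm]]$mean * 1e-6
    if (d[[nm]]$dist == "gamma") {
      sh <- gamma_from_moments(d[[nm]]$mean, tiny)
      d[[nm]]$shape <- sh[["shape"]]; d[[nm]]$scale <- sh[["scale"]]
    } else {
      ab <- beta_from_moments(d[[nm]]$mean, tiny)
      d[[nm]]$alpha <- ab[["alpha"]]; d[[nm]]$beta <- ab[["beta"]]
    }
  }
  res <- run_psa(p, d, n = 20, seed = 3, horizons = 4)
  base <- base_case_results(p, 1:4)
  expect_equal(res$outcomes$icer,
               rep(base$icer[4], 20), tolerance = 1e-5)
  # CE probability is exactly 0 or 1 for a degenerate PSA
  prob <- ceac(res, 4, wtp_grid = 1e5)$probability
  expect_true(prob %in% c(0, 1))
})

test_that("infeasible BMI-reduction draws are rejected and redrawn", {
  p <- base_calibrated()
  d <- parameter_distributions(p)
  # an absurdly dispersed reduction distribution forces rejections
  sh <- gamma_from_moments(40, 30)
  d$bmi_reduction$shape <- sh[["shape"]]; d$bmi_reduction$scale <- sh[["scale"]]
  res <- run_psa(p, d, n = 200, seed = 5, horizons = 1)
  expect_gt(res$n_rejected, 0)
  expect_true(all(res$draws$bmi_reduction < p$bmi_pre))
  expect_equal(nrow(res$draws), 200)
})

test_that("the CEAC is a proper, monotone acceptability curve", {
  p <- base_calibrated()
  res <- run_psa(p, n = 300, seed = 17)
  grid <- seq(0, 2e5, by = 1e4)
  cc <- ceac(res, wtp_grid = grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  for (h in 1:7) {
    expect_true(all(diff(cc$probability[cc$horizon == h]) >= 0))
  }
  # WTP = 0: fraction of replicates that are outright cost-saving
  o4 <- res$outcomes[res$outcomes$horizon == 4, ]
  expect_equal(cc$probability[cc$horizon == 4 & cc$wtp == 0],
               mean(o4$incremental_cost <= 0))
  # very large WTP: fraction with positive QALY gain (~1)
  expect_equal(ceac(res, 7, wtp_grid = 1e9)$probability,
               mean(res$outcomes$added_qalys[res$outcomes$horizon == 7] > 0))
  expect_error(ceac(res, 4, wtp_grid = numeric(0)), "non-empty")
})

test_that("percentile intervals match a hand enumeration and guard small n", {
  # hand-built replicate set: 4 ICERs, all with positive QALY gains
  fake <- structure(list(
    outcomes = data.frame(replicate = 1:4, horizon = 4,
                          incremental_cost = c(100, 200, 300, 400),
                          added_life_years = 0.1,
                          added_qalys = c(0.01, 0.01, 0.01, 0.01),
                          icer = c(10000, 20000, 30000, 40000)),
    horizons = 4, n = 4L, seed = 1L, n_rejected = 0L
  ), class = "psa_result")
  expect_error(percentile_interval(fake, 4), "40 replicates")
  fake40 <- fake
  fake40$outcomes <- fake$outcomes[rep(1:4, 10), ]
  got <- percentile_interval(fake40, 4, level = 0.5)
  # quartiles of ten copies each of {10k, 20k, 30k, 40k}
  expect_equal(unname(got),
               unname(stats::quantile(rep(c(1e4, 2e4, 3e4, 4e4), 10),
                                      c(0.25, 0.75))))
})

test_that("replicates with non-positive QALY gain are excluded from intervals", {
  o <- data.frame(replicate = 1:60, horizon = 1,
                  incremental_cost = 1000,
                  added_life_years = 0.1,
                  added_qalys = c(rep(0.01, 50), rep(-0.01, 10)),
                  icer = c(rep(1e5, 50), rep(NA, 10)))
  fake <- structure(list(outcomes = o, horizons = 1, n = 60L, seed = 1L,
                         n_rejected = 0L), class = "psa_result")
  ci <- percentile_interval(fake, 1)
  expect_equal(unname(ci), c(1e5, 1e5))
})

test_that("one-way sweeps move the ICER in the documented directions", {
  p <- base_calibrated()
  sweep <- function(name, values) one_way(p, name, values, horizon = 4)$icer
  expect_true(all(diff(sweep("discount_rate", c(0, 0.03, 0.06))) > 0))
  expect_true(all(diff(sweep("intervention_cost", c(12927, 25854, 51708))) > 0))
  expect_true(all(diff(sweep("regain_annual_fraction", c(0, 0.05, 0.2))) > 0))
  expect_true(all(diff(sweep("savings_per_bmi", c(0, 157, 314))) < 0))
  expect_true(all(diff(sweep("hrql_gain_per_bmi", c(0, 0.0042, 0.0084))) < 0))
  # zero savings: ICER above base but finite
  s0 <- one_way(p, "savings_per_bmi", 0, horizon = 4)
  base4 <- base_case_results(p, 1:4)$icer[4]
  expect_gt(s0$icer, base4)
  expect_true(is.finite(s0$icer))
  expect_error(one_way(p, "not_a_parameter", 1), "valid names")
  expect_error(one_way(p, "discount_rate", numeric(0)), "non-empty")
})
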