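# File-based commands: validation, determinism, output shapes.

local_outdir <- function(env = parent.frame()) {
  d <- tempfile("bariCEA-out-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

test_that("run_config validates horizons, targets and seeds", {
  expect_error(run_config(horizons = c(3, 2)), "strictly increasing")
  expect_error(run_config(horizons = 0:3), "strictly increasing")
  expect_error(run_config(targets = c(ly_y1 = 1)), "targets")
  cfg <- run_config(output_dir = tempdir())
  expect_error(cmd_psa(cfg), "seed")
  expect_error(cmd_synth(cfg), "seed")
})

test_that("calibration command writes a reusable, byte-stable report", {
  d <- local_outdir()
  cfg <- run_config(output_dir = d)
  p1 <- cmd_calibrate(cfg)
  expect_true(file.exists(file.path(d, "calibration.txt")))
  first <- readLines(file.path(d, "calibration.txt"))
  cmd_calibrate(cfg)
  expect_identical(readLines(file.path(d, "calibration.txt")), first)
  # the report feeds back through the config reader
  p2 <- read_parameter_config(file.path(d, "calibration.txt"))
  expect_equal(p2$u_base, p1$u_base)
  expect_equal(p2$mortality$gompertz_slope, p1$mortality$gompertz_slope,
               tolerance = 1e-12)
  # unattainable targets fail loudly
  bad <- run_config(output_dir = d,
                    targets = c(ly_y1 = 0, ly_y7 = 0, qaly_y1 = 0))
  expect_error(cmd_calibrate(bad))
})

test_that("the base-case table has the published layout and ICER pattern", {
  d <- local_outdir()
  cfg <- run_config(output_dir = d)
  out <- cmd_base_case(cfg)
  expect_equal(nrow(out), 7L)
  expect_equal(names(out),
               c("horizon", "medical_cost_savings", "added_life_years",
                 "added_qalys", "cost_per_qaly", "nmb",
                 "ce_probability_at_wtp"))
  expect_true(all(diff(out$cost_per_qaly) < 0))
  expect_true(file.exists(file.path(d, "base_case.tsv")))
  expect_true(file.exists(file.path(d, "manifest_base_case.txt")))
  # single-horizon config
  one <- cmd_base_case(run_config(horizons = 1L, output_dir = d))
  expect_equal(nrow(one), 1L)
  # zero savings raise every ICER relative to the default run
  p0 <- model_parameters(savings_per_bmi = 0)
  out0 <- cmd_base_case(run_config(params = p0, output_dir = d))
  expect_true(all(out0$cost_per_qaly > out$cost_per_qaly))
})

test_that("PSA command outputs are complete and seed-deterministic", {
  d1 <- local_outdir(); d2 <- local_outdir()
  cfg1 <- run_config(psa_n = 60L, seed = 7L, output_dir = d1)
  cfg2 <- run_config(psa_n = 60L, seed = 7L, output_dir = d2)
  cmd_psa(cfg1)
  cmd_psa(cfg2)
  for (f in c("psa_draws.tsv", "psa_outcomes.tsv", "ceac.tsv",
              "psa_intervals.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  cc <- read.delim(file.path(d1, "ceac.tsv"))
  expect_setequal(unique(cc$horizon), 1:7)
  # small-n path: runs, but interval file is suppressed with a warning
  d3 <- local_outdir()
  expect_warning(cmd_psa(run_config(psa_n = 10L, seed = 1L, output_dir = d3)),
                 "suppressed")
  expect_false(file.exists(file.path(d3, "psa_intervals.tsv")))
  expect_error(cmd_psa(run_config(psa_n = 0L, seed = 1L, output_dir = d3)),
               "positive")
})

test_that("one-way command delegates and writes a monotone sweep table", {
  d <- local_outdir()
  cfg <- run_config(output_dir = d)
  tab <- cmd_one_way(cfg, "discount_rate", c(0, 0.03, 0.06))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$icer) > 0))
  expect_true(file.exists(file.path(d, "one_way_discount_rate.tsv")))
  expect_error(cmd_one_way(cfg, "nope", 1), "valid names")
  expect_error(cmd_one_way(cfg, "discount_rate", numeric(0)), "non-empty")
})

test_that("synthetic-data command writes the three fixture files", {
  d <- local_outdir()
  cfg <- run_config(seed = 5L, output_dir = d)
  paths <- cmd_synth(cfg, cohort_n = 11L, survey_n = 100L)
  for (f in c("cohort.tsv", "survey.tsv", "life_table.tsv",
              "cohort_summary.tsv")) {
    expect_true(file.exists(file.path(d, f)))
  }
  lt <- read_life_table(file.path(d, "life_table.tsv"))
  expect_equal(lt$annual_death_prob[lt$age == 18], 0.008, tolerance = 1e-9)
  # a different seed changes content but not schema
  d2 <- local_outdir()
  cmd_synth(run_config(seed = 6L, output_dir = d2), cohort_n = 11L,
            survey_n = 100L)
  a <- read.delim(file.path(d, "cohort.tsv"))
  b <- read.delim(file.path(d2, "cohort.tsv"))
  expect_identical(names(a), names(b))
  expect_false(identical(a, b))
  # header-only cohort file for n = 0
  d3 <- local_outdir()
  cmd_synth(run_config(seed = 7L, output_dir = d3), cohort_n = 0L,
            survey_n = 10L)
  expect_equal(nrow(read.delim(file.path(d3, "cohort.tsv"))), 0L)
})
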