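# Shared fixtures: the published results-table values the model is held
# against, and a cached calibrated parameter set (calibration is
# deterministic, so one copy serves every test file).

# results-table columns, horizons 1..7
published <- list(
  savings = c(1989, 3857, 5564, 7117, 8523, 9792, 11012),
  added_ly = c(0.00624, 0.01791, 0.03523, 0.05810, 0.08635, 0.11978, 0.15815),
  added_qalys = c(0.060, 0.123, 0.187, 0.252, 0.319, 0.386, 0.457)
)

base_calibrated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_parameters()
    cache
  }
})

surgery_arm <- function(params = base_calibrated()) {
  arm_spec("surgery", params$bmi_pre, params$bmi_reduction)
}

comparator_arm <- function(params = base_calibrated()) {
  arm_spec("no_surgery", params$bmi_pre)
}
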