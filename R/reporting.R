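# Run configuration and file-writing commands: calibration report,
# base-case results table, PSA outputs, one-way sweeps, synthetic-data
# fixtures. Each command validates its inputs, computes everything, and
# only then writes; a manifest (config echo + package version)
# accompanies every output set.

#' Assemble a run configuration
#'
#' @param params A [model_parameters()] set (overrides already applied,
#'   e.g. via [read_parameter_config()]).
#' @param horizons Strictly increasing positive integers (default 1:7).
#' @param wtp_grid WTP grid for CEACs (default $0-$200,000 by $5,000).
#' @param psa_n PSA replicates (default 1,000).
#' @param seed Integer seed; mandatory for any stochastic command.
#' @param output_dir Directory outputs are written to (created if
#'   needed).
#' @param targets Calibration targets: named vector with `ly_y1`,
#'   `ly_y7`, `qaly_y1`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(params = model_parameters(),
                       horizons = 1:7,
                       wtp_grid = seq(0, 2e5, by = 5e3),
                       psa_n = 1000L,
                       seed = NULL,
                       output_dir = ".",
                       targets = c(ly_y1 = 0.00624, ly_y7 = 0.15815,
                                   qaly_y1 = 0.060)) {
  stopifnot(inherits(params, "cea_parameters"))
  horizons <- as.integer(horizons)
  if (any(horizons < 1L) || any(diff(horizons) <= 0L)) {
    stop("horizons must be strictly increasing positive integers")
  }
  if (!all(c("ly_y1", "ly_y7", "qaly_y1") %in% names(targets))) {
    stop("targets must name ly_y1, ly_y7 and qaly_y1")
  }
  structure(list(params = params, horizons = horizons, wtp_grid = wtp_grid,
                 psa_n = as.integer(psa_n), seed = seed,
                 output_dir = output_dir, targets = targets),
            class = "run_config")
}

.require_seed <- function(config) {
  if (is.null(config$seed) || is.na(config$seed)) {
    stop("this command is stochastic; the config must carry a seed")
  }
  as.integer(config$seed)
}

.out_path <- function(config, file) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$output_dir, file)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(config, command) {
  p <- config$params
  lines <- c(
    sprintf("command = %s", command),
    sprintf("package = bariCEA %s",
            as.character(utils::packageVersion("bariCEA"))),
    sprintf("horizons = %s", paste(config$horizons, collapse = ",")),
    sprintf("psa_n = %d", config$psa_n),
    sprintf("seed = %s", ifelse(is.null(config$seed), "NA", config$seed)),
    sprintf("intervention_cost = %.6g", p$cost_params$intervention_cost),
    sprintf("savings_per_bmi = %.6g", p$savings_per_bmi),
    sprintf("hrql_gain_per_bmi = %.6g", p$hrql_gain_per_bmi),
    sprintf("bmi_pre = %.6g", p$bmi_pre),
    sprintf("bmi_reduction = %.6g", p$bmi_reduction),
    sprintf("regain_annual_fraction = %.6g", p$regain$annual_fraction),
    sprintf("regain_plateau_fraction = %.6g", p$regain$plateau_fraction),
    sprintf("discount_rate = %.6g", p$discount_rate),
    sprintf("discount_life_years = %s", p$discount_life_years),
    sprintf("u_base = %s", format(p$u_base)),
    sprintf("gompertz_slope = %s", format(p$mortality$gompertz_slope)),
    sprintf("bmi_log_hazard = %s", format(p$mortality$bmi_log_hazard)),
    sprintf("wtp_threshold = %.6g", p$wtp_threshold)
  )
  writeLines(lines, .out_path(config, paste0("manifest_", command, ".txt")))
}

# calibrate config$params unless already calibrated
.calibrated_params <- function(config) {
  p <- config$params
  if (is.na(p$u_base) || is.na(p$mortality$gompertz_slope) ||
      is.na(p$mortality$bmi_log_hazard)) {
    p <- calibrate_parameters(p,
                              ly_target_y1 = config$targets[["ly_y1"]],
                              ly_target_y7 = config$targets[["ly_y7"]],
                              qaly_target_y1 = config$targets[["qaly_y1"]])
  }
  p
}

#' Calibrate and write the calibration report
#'
#' Runs [calibrate_parameters()] on the configured targets and writes a
#' flat key-value report (`calibration.txt`) that
#' [read_parameter_config()] can consume, so subsequent commands can
#' reuse the calibrated slopes. Deterministic: repeated runs are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return The calibrated `"cea_parameters"`, invisibly; side effect:
#'   `calibration.txt` and a manifest in `config$output_dir`.
#' @export
cmd_calibrate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- calibrate_parameters(config$params,
                            ly_target_y1 = config$targets[["ly_y1"]],
                            ly_target_y7 = config$targets[["ly_y7"]],
                            qaly_target_y1 = config$targets[["qaly_y1"]])
  cal <- attr(p, "calibration")
  lines <- c(
    sprintf("gompertz_slope = %.15g", cal$gompertz_slope),
    sprintf("bmi_log_hazard = %.15g", cal$bmi_log_hazard),
    sprintf("u_base = %.15g", cal$u_base),
    sprintf("# residual_ly_y1 = %.6g", cal$ly_residuals[["y1"]]),
    sprintf("# residual_ly_y7 = %.6g", cal$ly_residuals[["y7"]]),
    sprintf("# residual_qaly_y1 = %.6g", cal$qaly_residual)
  )
  writeLines(lines, .out_path(config, "calibration.txt"))
  .write_manifest(config, "calibrate")
  invisible(p)
}

#' Write the base-case results table
#'
#' One row per horizon, mirroring a published cost-effectiveness results
#' table: cumulative discounted medical cost savings, added life-years,
#' added QALYs, cost per QALY, and NMB at the configured threshold. The
#' `ce_probability_at_wtp` column is `NA` here; [cmd_psa()] fills it.
#'
#' @param config A [run_config()].
#' @param round_dollars Present monetary columns rounded to whole
#'   dollars (default `FALSE`: unrounded).
#' @return The results `data.frame`, invisibly; side effect:
#'   `base_case.tsv` and a manifest.
#' @export
cmd_base_case <- function(config, round_dollars = FALSE) {
  stopifnot(inherits(config, "run_config"))
  p <- .calibrated_params(config)
  inc <- base_case_results(p, config$horizons)
  out <- data.frame(
    horizon = inc$horizon,
    medical_cost_savings = -inc$savings,
    added_life_years = inc$added_life_years,
    added_qalys = inc$added_qalys,
    cost_per_qaly = inc$icer,
    nmb = inc$nmb,
    ce_probability_at_wtp = NA_real_
  )
  if (round_dollars) {
    for (cl in c("medical_cost_savings", "cost_per_qaly", "nmb")) {
      out[[cl]] <- round(out[[cl]])
    }
  }
  .write_tsv(out, .out_path(config, "base_case.tsv"))
  .write_manifest(config, "base_case")
  invisible(out)
}

#' Run the PSA and write its outputs
#'
#' Writes the replicate draws (`psa_draws.tsv`), per-replicate outcomes
#' (`psa_outcomes.tsv`), the CEAC in long format (`ceac.tsv`), and ICER
#' percentile intervals per horizon (`psa_intervals.tsv`). With fewer
#' than 40 replicates the intervals are suppressed with a warning.
#'
#' @param config A [run_config()] with a seed.
#' @return The `"psa_result"`, invisibly.
#' @export
cmd_psa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- .require_seed(config)
  if (config$psa_n < 1L) stop("psa_n must be a positive integer")
  p <- .calibrated_params(config)
  res <- run_psa(p, parameter_distributions(p), n = config$psa_n,
                 seed = seed, horizons = config$horizons)
  cc <- ceac(res, config$horizons, config$wtp_grid)
  ints <- NULL
  if (config$psa_n >= 40L) {
    ints <- do.call(rbind, lapply(config$horizons, function(h) {
      ci <- percentile_interval(res, h)
      data.frame(horizon = h, icer_low = ci[["low"]], icer_high = ci[["high"]])
    }))
  } else {
    warning("fewer than 40 replicates; ICER percentile intervals suppressed")
  }
  .write_tsv(res$draws, .out_path(config, "psa_draws.tsv"))
  .write_tsv(res$outcomes, .out_path(config, "psa_outcomes.tsv"))
  .write_tsv(cc, .out_path(config, "ceac.tsv"))
  if (!is.null(ints)) .write_tsv(ints, .out_path(config, "psa_intervals.tsv"))
  .write_manifest(config, "psa")
  invisible(res)
}

#' Run a one-way sweep and write the table
#'
#' @param config A [run_config()].
#' @param parameter Parameter name (see [one_way()]).
#' @param values Numeric sweep values.
#' @param horizon Evaluation horizon (default 4).
#' @return The sweep `data.frame`, invisibly; side effect:
#'   `one_way_<parameter>.tsv` and a manifest.
#' @export
cmd_one_way <- function(config, parameter, values, horizon = 4L) {
  stopifnot(inherits(config, "run_config"))
  p <- .calibrated_params(config)
  tab <- one_way(p, parameter, values, horizon)
  .write_tsv(tab, .out_path(config, paste0("one_way_", parameter, ".tsv")))
  .write_manifest(config, paste0("one_way_", parameter))
  invisible(tab)
}

#' Generate and write the synthetic data fixtures
#'
#' Writes a synthetic surgical cohort (`cohort.tsv`, with a summary in
#' `cohort_summary.tsv`), an HRQL/expenditure survey (`survey.tsv`), and
#' the parametric life table (`life_table.tsv`). Cohort and survey sizes
#' default to the study's 11 patients and 5,000 respondents.
#'
#' @param config A [run_config()] with a seed.
#' @param cohort_n,survey_n Record counts (`cohort_n = 0` writes a
#'   header-only file).
#' @return Named list of written paths, invisibly.
#' @export
cmd_synth <- function(config, cohort_n = 11L, survey_n = 5000L) {
  stopifnot(inherits(config, "run_config"))
  seed <- .require_seed(config)
  p <- .calibrated_params(config)
  cohort <- gen_cohort(cohort_n, seed)
  survey <- gen_survey(survey_n, seed + 1L,
                       slope_hrql = p$hrql_gain_per_bmi,
                       slope_cost = p$savings_per_bmi)
  lt <- make_gompertz_life_table(p$mortality$q0, p$mortality$gompertz_slope,
                                 p$start_age, p$max_age)
  paths <- list(
    cohort = .write_tsv(cohort, .out_path(config, "cohort.tsv")),
    survey = .write_tsv(survey, .out_path(config, "survey.tsv")),
    life_table = write_life_table(lt, .out_path(config, "life_table.tsv"))
  )
  if (cohort_n > 0L) {
    paths$cohort_summary <- .write_tsv(summarize_cohort(cohort),
                                       .out_path(config, "cohort_summary.tsv"))
  }
  .write_manifest(config, "synth")
  invisible(paths)
}
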