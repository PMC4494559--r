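# Intervention charges, charge-to-cost conversion, and the base-case
# parameter set.

CHARGE_PHASES <- c("preoperative", "perioperative", "postoperative", "foundation")

#' Construct a table of intervention charge lines
#'
#' A charge line is one billing category within a care phase (preoperative,
#' perioperative, postoperative, or the institutional surgical-foundation
#' charge), with the cohort mean and standard deviation of the billed amount
#' in 2013 US$.
#'
#' @param phase Character vector; each element one of
#'   `"preoperative"`, `"perioperative"`, `"postoperative"`, `"foundation"`.
#' @param category Character vector of free-text billing categories
#'   (e.g. `"Clinic"`, `"Pharmacy"`).
#' @param mean_charge,sd_charge Numeric vectors, non-negative, 2013 US$.
#' @return A `data.frame` of class `"charge_lines"` with one row per line.
#' @seealso [base_case_charges()], [aggregate_charges()]
#' @export
charge_lines <- function(phase, category, mean_charge, sd_charge) {
  phase <- as.character(phase)
  bad <- setdiff(unique(phase), CHARGE_PHASES)
  if (length(bad)) {
    stop("unknown charge phase(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(CHARGE_PHASES, collapse = ", "))
  }
  n <- length(phase)
  if (length(category) != n || length(mean_charge) != n || length(sd_charge) != n) {
    stop("phase, category, mean_charge and sd_charge must have equal length")
  }
  mean_charge <- as.numeric(mean_charge)
  sd_charge <- as.numeric(sd_charge)
  if (any(!is.finite(mean_charge)) || any(mean_charge < 0)) {
    stop("mean_charge must be finite and non-negative")
  }
  if (any(!is.finite(sd_charge)) || any(sd_charge < 0)) {
    stop("sd_charge must be finite and non-negative")
  }
  out <- data.frame(
    phase = phase, category = as.character(category),
    mean_charge = mean_charge, sd_charge = sd_charge,
    stringsAsFactors = FALSE
  )
  class(out) <- c("charge_lines", "data.frame")
  out
}

#' Base-case intervention charge lines
#'
#' The thirteen per-phase billing categories of the surgical programme:
#' preoperative (clinic, ancillary, diagnostic), perioperative (ancillary,
#' diagnostic, general nursing, minimally invasive procedures, pharmacy,
#' surgery and procedures), the surgical foundation charge, and
#' postoperative (clinic, ancillary, surgery and procedures). All values in
#' 2013 US$. The components sum to $47,437; the canonical printed total is
#' $47,438 (a $1 discrepancy attributable to per-row rounding, retained as
#' reported rather than reconciled).
#'
#' @return A `"charge_lines"` data frame with 13 rows.
#' @export
base_case_charges <- function() {
  charge_lines(
    phase = c(rep("preoperative", 3), rep("perioperative", 6),
              "foundation", rep("postoperative", 3)),
    category = c(
      "Clinic", "Ancillary", "Diagnostic",
      "Ancillary", "Diagnostic", "Gen nursing",
      "Minimally invasive procedures", "Pharmacy", "Surgery and procedures",
      "Surgical foundation",
      "Clinic", "Ancillary", "Surgery and procedures"
    ),
    mean_charge = c(339, 164, 1578,
                    113, 944, 6498, 13, 3002, 29036,
                    3312,
                    633, 1630, 175),
    sd_charge = c(163, 89, 1061,
                  378, 359, 1444, 41, 520, 2547,
                  552,
                  619, 1134, 584)
  )
}

#' Total mean charge over a set of charge lines
#'
#' @param lines A `"charge_lines"` data frame (may have zero rows).
#' @return Sum of `mean_charge` over all lines (US$); 0 for an empty table.
#' @export
aggregate_charges <- function(lines) {
  if (!inherits(lines, "charge_lines")) {
    lines <- charge_lines(lines$phase, lines$category,
                          lines$mean_charge, lines$sd_charge)
  }
  if (any(lines$mean_charge < 0)) stop("mean_charge must be non-negative")
  sum(lines$mean_charge)
}

#' Convert billed charges to economic costs
#'
#' Applies an institution-level cost-to-charge ratio (base case 0.545,
#' 2013) to convert total billed charges into costs.
#'
#' @param total_charges Non-negative total charges (US$).
#' @param ratio Cost-to-charge ratio in (0, 1].
#' @return `total_charges * ratio` (US$).
#' @examples
#' charges_to_costs(47438, 0.545)  # 25853.71, printed as $25,854
#' @export
charges_to_costs <- function(total_charges, ratio) {
  if (!is.numeric(total_charges) || any(total_charges < 0)) {
    stop("total_charges must be non-negative")
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stop("cost-to-charge ratio must lie in (0, 1]")
  }
  total_charges * ratio
}

#' Intervention cost parameters
#'
#' Bundles the total billed charges, the cost-to-charge ratio, and the
#' resulting one-time intervention cost with its standard deviation (used
#' by the probabilistic sensitivity analysis). By default the printed
#' base-case values are used and checked for internal consistency:
#' `intervention_cost` must equal `total_charges * cost_to_charge_ratio`
#' to within $1 of rounding.
#'
#' @param total_charges Total billed charges, US$ (base 47,438).
#' @param cost_to_charge_ratio Ratio in (0, 1] (base 0.545).
#' @param intervention_cost One-time cost of surgery incl. pre-/post-op
#'   care, US$. Default: derived from charges and rounded to the dollar.
#' @param intervention_cost_sd Standard deviation of the intervention
#'   cost, US$ (base 2,044).
#' @return A list of class `"cost_parameters"`.
#' @export
cost_parameters <- function(total_charges = 47438,
                            cost_to_charge_ratio = 0.545,
                            intervention_cost = NULL,
                            intervention_cost_sd = 2044) {
  derived <- charges_to_costs(total_charges, cost_to_charge_ratio)
  if (is.null(intervention_cost)) intervention_cost <- round(derived)
  if (abs(intervention_cost - derived) > 1) {
    stop(sprintf(paste0("intervention_cost (%.2f) is not total_charges x ",
                        "cost_to_charge_ratio (%.2f) within $1 rounding"),
                 intervention_cost, derived))
  }
  if (intervention_cost_sd < 0) stop("intervention_cost_sd must be non-negative")
  structure(list(
    total_charges = total_charges,
    cost_to_charge_ratio = cost_to_charge_ratio,
    intervention_cost = intervention_cost,
    intervention_cost_sd = intervention_cost_sd
  ), class = "cost_parameters")
}

#' Full base-case model parameter set
#'
#' All inputs of the cost-effectiveness model in one object. Monetary
#' values are 2013 US$ throughout; no inflation adjustment is provided.
#'
#' The mortality link (`gompertz_slope`, `bmi_log_hazard`) and the
#' baseline utility `u_base` are calibrated quantities, `NA` until
#' [calibrate_parameters()] is run (or values are supplied directly).
#'
#' @param cost_params A [cost_parameters()] object.
#' @param savings_per_bmi Annual medical-care savings per unit of BMI
#'   reduction, US$/BMI-unit/year (base 157).
#' @param savings_per_bmi_se Standard error of the above (base 47).
#' @param hrql_gain_per_bmi Utility gain per unit of BMI reduction
#'   (base 0.0042, EQ-5D scale).
#' @param hrql_gain_per_bmi_se Standard error of the above (base 0.0011).
#' @param bmi_pre Pre-surgical BMI, kg/m^2 (base 48.7); also the constant
#'   BMI of the no-surgery comparator.
#' @param bmi_reduction BMI reduction measured 12 months after surgery
#'   (base 13.2).
#' @param weight_loss_kg,weight_loss_sd_kg 12-month weight loss, kg
#'   (base 37.5, SD 13.5); the SD scales the PSA uncertainty on
#'   `bmi_reduction`.
#' @param regain A [regain_schedule()] (base: 5\%/year from cycle 2,
#'   plateau at 25\%).
#' @param mortality A [mortality_model()]; slopes may be `NA` before
#'   calibration.
#' @param u_base Utility of the alive state at the no-surgery reference
#'   BMI; `NA` until calibrated (see [calibrate_baseline_utility()]).
#' @param discount_rate Annual discount rate for costs and QALYs
#'   (base 0.03).
#' @param discount_life_years Logical; whether accumulated life-year
#'   gains are discounted at `discount_rate` like costs and QALYs
#'   (default `TRUE`; the convention under which the published life-year
#'   trajectory calibrates coherently -- see the methods vignette).
#' @param start_age Cohort age at model start, years (base 18).
#' @param max_age Upper end of the life table, years (default 110).
#' @param wtp_threshold Willingness-to-pay per QALY, US$ (base 100,000).
#' @return A list of class `"cea_parameters"`.
#' @export
model_parameters <- function(cost_params = cost_parameters(),
                             savings_per_bmi = 157,
                             savings_per_bmi_se = 47,
                             hrql_gain_per_bmi = 0.0042,
                             hrql_gain_per_bmi_se = 0.0011,
                             bmi_pre = 48.7,
                             bmi_reduction = 13.2,
                             weight_loss_kg = 37.5,
                             weight_loss_sd_kg = 13.5,
                             regain = regain_schedule(),
                             mortality = mortality_model(),
                             u_base = NA_real_,
                             discount_rate = 0.03,
                             discount_life_years = TRUE,
                             start_age = 18,
                             max_age = 110,
                             wtp_threshold = 1e5) {
  stopifnot(inherits(cost_params, "cost_parameters"),
            inherits(regain, "regain_schedule"),
            inherits(mortality, "mortality_model"))
  if (discount_rate < 0) stop("discount_rate must be non-negative")
  if (!is.na(u_base) && (u_base <= 0 || u_base > 1)) {
    stop("u_base must lie in (0, 1]")
  }
  if (bmi_reduction >= bmi_pre) stop("bmi_reduction must be smaller than bmi_pre")
  money <- c(savings_per_bmi = savings_per_bmi,
             savings_per_bmi_se = savings_per_bmi_se,
             wtp_threshold = wtp_threshold)
  if (any(money < 0)) stop("monetary parameters must be non-negative")
  if (max_age <= start_age) stop("max_age must exceed start_age")
  structure(list(
    cost_params = cost_params,
    savings_per_bmi = savings_per_bmi,
    savings_per_bmi_se = savings_per_bmi_se,
    hrql_gain_per_bmi = hrql_gain_per_bmi,
    hrql_gain_per_bmi_se = hrql_gain_per_bmi_se,
    bmi_pre = bmi_pre,
    bmi_reduction = bmi_reduction,
    weight_loss_kg = weight_loss_kg,
    weight_loss_sd_kg = weight_loss_sd_kg,
    regain = regain,
    mortality = mortality,
    u_base = u_base,
    discount_rate = discount_rate,
    discount_life_years = discount_life_years,
    start_age = start_age,
    max_age = max_age,
    wtp_threshold = wtp_threshold
  ), class = "cea_parameters")
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Cost-effectiveness model parameters (2013 US$)\n")
  cat(sprintf("  intervention cost : $%s (SD %s)\n",
              format(x$cost_params$intervention_cost, big.mark = ","),
              format(x$cost_params$intervention_cost_sd, big.mark = ",")))
  cat(sprintf("  savings/BMI-unit  : $%g/yr (SE %g)\n",
              x$savings_per_bmi, x$savings_per_bmi_se))
  cat(sprintf("  HRQL gain/BMI-unit: %g (SE %g)\n",
              x$hrql_gain_per_bmi, x$hrql_gain_per_bmi_se))
  cat(sprintf("  BMI pre / reduction: %g / %g\n", x$bmi_pre, x$bmi_reduction))
  cat(sprintf("  regain: %g%%/yr from cycle %d, plateau %g%%\n",
              100 * x$regain$annual_fraction, x$regain$first_regain_cycle,
              100 * x$regain$plateau_fraction))
  cat(sprintf("  mortality: q0 = %g, g = %s, beta = %s\n",
              x$mortality$q0, format(x$mortality$gompertz_slope),
              format(x$mortality$bmi_log_hazard)))
  cat(sprintf("  u_base = %s, discount = %g%%, start age %g, WTP $%s/QALY\n",
              format(x$u_base), 100 * x$discount_rate, x$start_age,
              format(x$wtp_threshold, big.mark = ",")))
  invisible(x)
}

# ---- flat key-value configuration -----------------------------------------

# parameter keys settable from a config file, with the coercion applied
.config_keys <- c(
  total_charges = "numeric", cost_to_charge_ratio = "numeric",
  intervention_cost = "numeric", intervention_cost_sd = "numeric",
  savings_per_bmi = "numeric", savings_per_bmi_se = "numeric",
  hrql_gain_per_bmi = "numeric", hrql_gain_per_bmi_se = "numeric",
  bmi_pre = "numeric", bmi_reduction = "numeric",
  weight_loss_kg = "numeric", weight_loss_sd_kg = "numeric",
  regain_annual_fraction = "numeric", regain_first_cycle = "numeric",
  regain_plateau_fraction = "numeric",
  q0 = "numeric", gompertz_slope = "numeric", bmi_log_hazard = "numeric",
  u_base = "numeric", discount_rate = "numeric",
  discount_life_years = "logical",
  start_age = "numeric", max_age = "numeric", wtp_threshold = "numeric"
)

#' Read model parameters from a flat key-value config file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Keys are the field names of [model_parameters()] (with regain and
#' mortality fields flattened, e.g. `regain_annual_fraction`,
#' `gompertz_slope`). Unknown keys are hard errors so that typos cannot
#' silently leave a parameter at its default.
#'
#' @param path Path to the config file.
#' @param base Parameter set whose values the file overrides.
#' @return A `"cea_parameters"` object.
#' @export
read_parameter_config <- function(path, base = model_parameters()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  unknown <- setdiff(keys, names(.config_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(names(.config_keys), collapse = ", "))
  }
  if (anyDuplicated(keys)) {
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  ov <- stats::setNames(as.list(vals), keys)
  num <- function(k, default) {
    if (is.null(ov[[k]])) return(default)
    x <- suppressWarnings(as.numeric(ov[[k]]))
    if (is.na(x) && !identical(tolower(ov[[k]]), "na")) {
      stop("config value for ", k, " is not numeric: ", ov[[k]])
    }
    x
  }
  lgl <- function(k, default) {
    if (is.null(ov[[k]])) return(default)
    as.logical(toupper(ov[[k]]))
  }
  model_parameters(
    cost_params = cost_parameters(
      total_charges = num("total_charges", base$cost_params$total_charges),
      cost_to_charge_ratio = num("cost_to_charge_ratio",
                                 base$cost_params$cost_to_charge_ratio),
      intervention_cost = num("intervention_cost",
                              base$cost_params$intervention_cost),
      intervention_cost_sd = num("intervention_cost_sd",
                                 base$cost_params$intervention_cost_sd)
    ),
    savings_per_bmi = num("savings_per_bmi", base$savings_per_bmi),
    savings_per_bmi_se = num("savings_per_bmi_se", base$savings_per_bmi_se),
    hrql_gain_per_bmi = num("hrql_gain_per_bmi", base$hrql_gain_per_bmi),
    hrql_gain_per_bmi_se = num("hrql_gain_per_bmi_se", base$hrql_gain_per_bmi_se),
    bmi_pre = num("bmi_pre", base$bmi_pre),
    bmi_reduction = num("bmi_reduction", base$bmi_reduction),
    weight_loss_kg = num("weight_loss_kg", base$weight_loss_kg),
    weight_loss_sd_kg = num("weight_loss_sd_kg", base$weight_loss_sd_kg),
    regain = regain_schedule(
      annual_fraction = num("regain_annual_fraction", base$regain$annual_fraction),
      first_regain_cycle = num("regain_first_cycle", base$regain$first_regain_cycle),
      plateau_fraction = num("regain_plateau_fraction", base$regain$plateau_fraction)
    ),
    mortality = mortality_model(
      q0 = num("q0", base$mortality$q0),
      gompertz_slope = num("gompertz_slope", base$mortality$gompertz_slope),
      bmi_log_hazard = num("bmi_log_hazard", base$mortality$bmi_log_hazard)
    ),
    u_base = num("u_base", base$u_base),
    discount_rate = num("discount_rate", base$discount_rate),
    discount_life_years = lgl("discount_life_years", base$discount_life_years),
    start_age = num("start_age", base$start_age),
    max_age = num("max_age", base$max_age),
    wtp_threshold = num("wtp_threshold", base$wtp_threshold)
  )
}

#' Read charge lines from a 4-column delimited table
#'
#' Tab-separated with header `phase  category  mean_charge  sd_charge`.
#' A bundled fixture reproducing the base-case billing table is at
#' `system.file("extdata", "charges.tsv", package = "bariCEA")`.
#'
#' @param path File path.
#' @return A `"charge_lines"` data frame.
#' @export
read_charge_lines <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phase", "category", "mean_charge", "sd_charge")
  if (!all(need %in% names(d))) {
    stop("charge table must have columns: ", paste(need, collapse = ", "))
  }
  charge_lines(d$phase, d$category, d$mean_charge, d$sd_charge)
}

#' Write charge lines to a delimited table
#' @param lines A `"charge_lines"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_charge_lines <- function(lines, path) {
  utils::write.table(as.data.frame(lines), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
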