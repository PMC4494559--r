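# Age- and BMI-dependent annual mortality: a parametric (Gompertz) life
# table standing in for an external age-by-BMI life table, a log-linear
# BMI hazard link, and calibration of both to a published added-life-years
# trajectory.

#' BMI-mortality model
#'
#' Annual death probability at age `a` for an individual whose BMI is
#' `delta_bmi` units below the no-surgery reference BMI:
#' `q(a) * exp(-bmi_log_hazard * delta_bmi)`, clipped to \[0, 1\], where
#' `q(a)` comes from the life table. `q0` anchors the table at the start
#' age; the slopes are calibrated (see [calibrate_mortality()]) and may
#' be `NA` until then.
#'
#' @param q0 Annual death probability at the start age for the reference
#'   BMI, in (0, 1) (base 0.008 at age 18).
#' @param gompertz_slope Log-hazard increase per year of age.
#' @param bmi_log_hazard Log-hazard decrease per unit of BMI reduction
#'   (`>= 0`).
#' @return A list of class `"mortality_model"`.
#' @export
mortality_model <- function(q0 = 0.008,
                            gompertz_slope = NA_real_,
                            bmi_log_hazard = NA_real_) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must lie in (0, 1)")
  if (!is.na(bmi_log_hazard) && bmi_log_hazard < 0) {
    stop("bmi_log_hazard must be non-negative")
  }
  structure(list(q0 = q0, gompertz_slope = gompertz_slope,
                 bmi_log_hazard = bmi_log_hazard),
            class = "mortality_model")
}

#' Build a Gompertz life table
#'
#' Parametric stand-in for an external age-indexed life table:
#' `q(a) = min(1, q0 * exp(g * (a - start_age)))` for integer ages
#' `start_age..max_age`. With `g = 0` the table is constant at `q0`.
#'
#' @param q0 Annual death probability at `start_age`, in (0, 1).
#' @param g Gompertz slope (log-hazard per year of age; may be negative).
#' @param start_age,max_age Integer age range, `max_age > start_age`.
#' @return A `data.frame` of class `"life_table"` with columns `age`,
#'   `annual_death_prob`.
#' @export
make_gompertz_life_table <- function(q0, g, start_age = 18, max_age = 110) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must lie in (0, 1)")
  if (max_age <= start_age) stop("max_age must exceed start_age")
  age <- seq.int(start_age, max_age)
  q <- pmin(1, q0 * exp(g * (age - start_age)))
  out <- data.frame(age = age, annual_death_prob = q)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Annual death probability at given ages and BMI reductions
#'
#' Looks up the life-table probability at each age and applies the
#' log-linear BMI hazard multiplier `exp(-beta * delta_bmi)`, clipping to
#' \[0, 1\]. `delta_bmi = 0` (the no-surgery arm) returns the table value
#' exactly.
#'
#' @param table A `"life_table"` data frame.
#' @param model A [mortality_model()] with non-`NA` `bmi_log_hazard`.
#' @param age Integer age(s); must lie within the table's range.
#' @param delta_bmi BMI reduction(s) `>= 0`, recycled against `age`.
#' @return Numeric vector of annual death probabilities.
#' @export
death_prob <- function(table, model, age, delta_bmi) {
  stopifnot(inherits(table, "life_table"), inherits(model, "mortality_model"))
  rng <- range(table$age)
  if (any(age < rng[1] | age > rng[2])) {
    stop(sprintf("age out of life-table range [%d, %d]", rng[1], rng[2]))
  }
  if (any(delta_bmi < 0)) stop("delta_bmi must be non-negative")
  beta <- model$bmi_log_hazard
  if (is.na(beta)) stop("bmi_log_hazard is NA; calibrate the mortality model first")
  q <- table$annual_death_prob[match(age, table$age)]
  pmin(1, pmax(0, q * exp(-beta * delta_bmi)))
}

# internal: cumulative added life-years of surgery vs no surgery at each
# horizon 1..h, for a trial (g, beta); discounting per params
.added_life_years <- function(params, g, beta, horizon) {
  mm <- mortality_model(params$mortality$q0, g, beta)
  lt <- make_gompertz_life_table(mm$q0, g, params$start_age, params$max_age)
  p <- params
  p$mortality <- mm
  surg <- run_arm(p, arm_spec("surgery", params$bmi_pre, params$bmi_reduction),
                  horizon, life_table = lt)
  ns <- run_arm(p, arm_spec("no_surgery", params$bmi_pre), horizon,
                life_table = lt)
  col <- if (isTRUE(params$discount_life_years)) "life_years_disc" else "life_years"
  cumsum(surg[[col]] - ns[[col]])
}

#' Calibrate the mortality link to an added-life-years trajectory
#'
#' Finds the Gompertz age slope `g` and the BMI log-hazard `beta` such
#' that the model's cumulative added life-years (surgery vs no surgery)
#' at horizons 1 and 7 match two published targets to a relative
#' tolerance of 1e-6. The year-1 gap identifies `beta` (at the start age
#' the Gompertz term is 1), the year-7 gap then identifies `g`; the
#' search is implemented as nested root finding and is deterministic for
#' fixed targets.
#'
#' @param params A [model_parameters()] set (its `u_base` is irrelevant
#'   here; life-years do not involve utility).
#' @param ly_target_y1,ly_target_y7 Cumulative added life-years at
#'   horizons 1 and 7 (base targets 0.00624 and 0.15815); must be
#'   positive and increasing.
#' @param beta_box,g_box Search intervals for the two slopes.
#' @return A list with `gompertz_slope`, `bmi_log_hazard`, and
#'   `residuals` (achieved minus target at the two horizons).
#' @export
calibrate_mortality <- function(params,
                                ly_target_y1 = 0.00624,
                                ly_target_y7 = 0.15815,
                                beta_box = c(1e-8, 5),
                                g_box = c(-0.5, 0.5)) {
  stopifnot(inherits(params, "cea_parameters"))
  if (ly_target_y1 <= 0 || ly_target_y7 <= ly_target_y1) {
    stop("life-year targets must be positive and increasing")
  }
  p <- params
  if (is.na(p$u_base)) p$u_base <- 1  # utility plays no role in life-years
  f_beta <- function(beta, g) .added_life_years(p, g, beta, 1L)[1L] - ly_target_y1
  solve_beta <- function(g) {
    lo <- f_beta(beta_box[1], g); hi <- f_beta(beta_box[2], g)
    if (lo * hi > 0) {
      stop(sprintf(paste0("no root for bmi_log_hazard in [%g, %g]: year-1 ",
                          "residuals %.3g and %.3g"),
                   beta_box[1], beta_box[2], lo, hi))
    }
    stats::uniroot(f_beta, beta_box, g = g, tol = 1e-12)$root
  }
  f_g <- function(g) {
    .added_life_years(p, g, solve_beta(g), 7L)[7L] - ly_target_y7
  }
  lo <- f_g(g_box[1]); hi <- f_g(g_box[2])
  if (lo * hi > 0) {
    stop(sprintf(paste0("no root for gompertz_slope in [%g, %g]: year-7 ",
                        "residuals %.3g and %.3g at the box ends"),
                 g_box[1], g_box[2], lo, hi))
  }
  g <- stats::uniroot(f_g, g_box, tol = 1e-12)$root
  beta <- solve_beta(g)
  ly <- .added_life_years(p, g, beta, 7L)
  res <- c(y1 = ly[1L] - ly_target_y1, y7 = ly[7L] - ly_target_y7)
  if (any(abs(res) > 1e-6 * c(ly_target_y1, ly_target_y7))) {
    stop("calibration did not converge to relative tolerance 1e-6: ",
         paste(sprintf("%s = %.3g", names(res), res), collapse = ", "))
  }
  list(gompertz_slope = g, bmi_log_hazard = beta, residuals = res)
}

#' Read / write a life table as a 2-column delimited file
#'
#' Tab-separated with header `age  annual_death_prob`, so an externally
#' published life table can be substituted for the parametric one without
#' code change.
#'
#' @param path File path.
#' @return `read_life_table`: a `"life_table"` data frame.
#' @export
read_life_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("age", "annual_death_prob") %in% names(d))) {
    stop("life table must have columns: age, annual_death_prob")
  }
  if (any(d$annual_death_prob < 0 | d$annual_death_prob > 1)) {
    stop("annual_death_prob must lie in [0, 1]")
  }
  if (!all(diff(d$age) == 1)) stop("life table ages must be consecutive integers")
  out <- data.frame(age = as.integer(d$age),
                    annual_death_prob = as.numeric(d$annual_death_prob))
  class(out) <- c("life_table", "data.frame")
  out
}

#' @rdname read_life_table
#' @param table A `"life_table"` data frame.
#' @return `write_life_table`: `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
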