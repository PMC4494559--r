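# BMI trajectories per model arm, including post-surgical weight regain.

#' Post-surgical weight-regain schedule
#'
#' Regain is expressed as a fraction of the initial BMI reduction (the model
#' operates entirely in BMI units). Under the base case, 5% of the initial
#' reduction is regained per year starting in cycle 2, with cumulative
#' regain plateauing at 25% (reached in cycle 6 and constant thereafter).
#' `annual_fraction = 0` is the "no weight regain" sensitivity case;
#' `annual_fraction = 0.20` gives complete reversal of the regainable
#' fraction (cumulative regain 1 would need plateau 1) -- with
#' `plateau_fraction = 1` it reproduces the "complete regain after five
#' years" sensitivity case.
#'
#' @param annual_fraction Fraction of the initial reduction regained per
#'   year, in \[0, 1\] (base 0.05).
#' @param first_regain_cycle First cycle in which regain applies (base 2;
#'   cycle 1 carries the full 12-month reduction).
#' @param plateau_fraction Maximum cumulative regain, in \[0, 1\] (base 0.25).
#' @return A list of class `"regain_schedule"`.
#' @export
regain_schedule <- function(annual_fraction = 0.05,
                            first_regain_cycle = 2L,
                            plateau_fraction = 0.25) {
  if (annual_fraction < 0 || annual_fraction > 1) {
    stop("annual_fraction must lie in [0, 1]")
  }
  if (plateau_fraction < 0 || plateau_fraction > 1) {
    stop("plateau_fraction must lie in [0, 1]")
  }
  first_regain_cycle <- as.integer(first_regain_cycle)
  if (is.na(first_regain_cycle) || first_regain_cycle < 1L) {
    stop("first_regain_cycle must be a positive integer")
  }
  structure(list(annual_fraction = annual_fraction,
                 first_regain_cycle = first_regain_cycle,
                 plateau_fraction = plateau_fraction),
            class = "regain_schedule")
}

#' Specify a model arm
#'
#' The surgery arm starts from `bmi_pre` and carries a 12-month BMI
#' reduction subject to regain; the no-surgery comparator keeps BMI
#' constant at `bmi_pre` (reduction 0 by construction).
#'
#' @param arm `"surgery"` or `"no_surgery"`.
#' @param bmi_pre Pre-surgical BMI, kg/m^2.
#' @param bmi_reduction BMI reduction at 12 months (ignored, forced to 0,
#'   for the no-surgery arm).
#' @return A list of class `"arm_spec"`.
#' @export
arm_spec <- function(arm = c("surgery", "no_surgery"),
                     bmi_pre = 48.7, bmi_reduction = 13.2) {
  arm <- match.arg(arm)
  if (arm == "no_surgery") bmi_reduction <- 0
  if (bmi_pre <= 0) stop("bmi_pre must be positive")
  if (bmi_reduction < 0 || bmi_reduction >= bmi_pre) {
    stop("bmi_reduction must lie in [0, bmi_pre)")
  }
  structure(list(arm = arm, bmi_pre = bmi_pre, bmi_reduction = bmi_reduction),
            class = "arm_spec")
}

#' BMI reduction (relative to pre-surgical BMI) at given cycles
#'
#' For the surgery arm the reduction at cycle `t` is
#' `bmi_reduction * (1 - min(plateau, annual * max(0, t - first + 1)))`;
#' the no-surgery arm is 0 at every cycle. Vectorised over `cycle`.
#'
#' @param arm An [arm_spec()].
#' @param schedule A [regain_schedule()].
#' @param cycle Integer cycle index(es), `>= 1` (cycle 1 = first
#'   post-surgical year).
#' @return Numeric vector of BMI reductions (BMI units).
#' @examples
#' s <- arm_spec("surgery")
#' delta_bmi_at_cycle(s, regain_schedule(), c(1, 3, 6))  # 13.2 11.88 9.90
#' @export
delta_bmi_at_cycle <- function(arm, schedule, cycle) {
  stopifnot(inherits(arm, "arm_spec"), inherits(schedule, "regain_schedule"))
  cycle <- as.numeric(cycle)
  if (length(cycle) == 0L || any(!is.finite(cycle)) || any(cycle < 1) ||
      any(cycle != floor(cycle))) {
    stop("cycle must be integer(s) >= 1")
  }
  if (arm$arm == "no_surgery") return(rep(0, length(cycle)))
  regained <- pmin(schedule$plateau_fraction,
                   schedule$annual_fraction *
                     pmax(0, cycle - schedule$first_regain_cycle + 1))
  arm$bmi_reduction * (1 - regained)
}

#' BMI-reduction series over a model horizon
#'
#' @param arm An [arm_spec()].
#' @param schedule A [regain_schedule()].
#' @param horizon Number of yearly cycles, `>= 1`.
#' @return Numeric vector of length `horizon`; element `t` is
#'   [delta_bmi_at_cycle()] at cycle `t`. Non-increasing for the surgery
#'   arm.
#' @export
delta_bmi_series <- function(arm, schedule, horizon) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon < 1 ||
      horizon != floor(horizon)) {
    stop("horizon must be a single integer >= 1")
  }
  delta_bmi_at_cycle(arm, schedule, seq_len(horizon))
}
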