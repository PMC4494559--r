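# Probabilistic sensitivity analysis: method-of-moments gamma/beta
# parameterisation, Monte-Carlo propagation through the Markov model,
# cost-effectiveness acceptability curves, ICER percentile intervals,
# and one-way sensitivity sweeps.

#' Gamma shape/scale from a mean and standard deviation
#'
#' Method of moments: `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean,sd Strictly positive moments.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_from_moments(25854, 2044)  # shape ~ 160, scale ~ 161.6
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("mean and sd must be strictly positive")
  }
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Beta shape parameters from a mean and standard deviation
#'
#' Method of moments: with `nu = mean(1-mean)/sd^2 - 1`,
#' `alpha = mean * nu` and `beta = (1-mean) * nu`. The variance must be
#' feasible: `sd^2 < mean(1-mean)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with `sd^2 < mean(1-mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("mean must lie in (0, 1)")
  }
  if (!is.numeric(sd) || sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop("infeasible variance: need sd^2 < mean * (1 - mean)")
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Uncertainty distributions of the sampled parameters
#'
#' The four quantities sampled in the probabilistic sensitivity analysis,
#' with gamma distributions for the monetary/anthropometric ones and a
#' beta distribution for the utility slope. The PSA propagates
#' *parameter* uncertainty -- uncertainty in the estimated means, not
#' patient-to-patient heterogeneity -- so the two quantities whose
#' dispersion is recorded as a cohort SD are assigned the standard error
#' of their mean, `SD / sqrt(cohort_n)` with `cohort_n = 11` patients:
#' \itemize{
#'   \item `intervention_cost` ~ gamma (base mean 25,854; SE
#'     2,044/sqrt(11) ~ 616);
#'   \item `savings_per_bmi` ~ gamma (base mean 157, SE 47, as
#'     published);
#'   \item `bmi_reduction` ~ gamma, uncertainty scaled from the
#'     weight-loss SE since weight loss is the sampled quantity but the
#'     model consumes BMI units:
#'     `sd = bmi_reduction * (weight_loss_sd/sqrt(cohort_n)) /
#'     weight_loss` (base ~ 1.43);
#'   \item `hrql_gain_per_bmi` ~ beta (base mean 0.0042, SE 0.0011, as
#'     published).
#' }
#' Setting `cohort_n = 1` reproduces the population-SD reading (a much
#' more dispersed PSA).
#'
#' @param params A [model_parameters()] set supplying the moments.
#' @param cohort_n Number of patients behind the cohort-SD quantities
#'   (default 11).
#' @return A list of class `"parameter_distributions"`; each element has
#'   `dist` (`"gamma"` or `"beta"`), `mean`, `sd`, and the fitted shape
#'   parameters.
#' @export
parameter_distributions <- function(params = model_parameters(),
                                    cohort_n = 11L) {
  stopifnot(inherits(params, "cea_parameters"))
  if (cohort_n < 1) stop("cohort_n must be a positive integer")
  g <- function(mean, sd) {
    sh <- gamma_from_moments(mean, sd)
    list(dist = "gamma", mean = mean, sd = sd,
         shape = sh[["shape"]], scale = sh[["scale"]])
  }
  bmi_sd <- params$bmi_reduction *
    (params$weight_loss_sd_kg / sqrt(cohort_n)) / params$weight_loss_kg
  bsh <- beta_from_moments(params$hrql_gain_per_bmi, params$hrql_gain_per_bmi_se)
  structure(list(
    intervention_cost = g(params$cost_params$intervention_cost,
                          params$cost_params$intervention_cost_sd / sqrt(cohort_n)),
    savings_per_bmi = g(params$savings_per_bmi, params$savings_per_bmi_se),
    bmi_reduction = g(params$bmi_reduction, bmi_sd),
    hrql_gain_per_bmi = list(dist = "beta",
                             mean = params$hrql_gain_per_bmi,
                             sd = params$hrql_gain_per_bmi_se,
                             alpha = bsh[["alpha"]], beta = bsh[["beta"]])
  ), class = "parameter_distributions")
}

# internal: n draws from one fitted distribution
.draw_dist <- function(d, n) {
  switch(d$dist,
         gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
         beta = stats::rbeta(n, d$alpha, d$beta),
         stop("unknown distribution kind: ", d$dist))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets from `dists` (parameters
#' independent of each other), re-runs the deterministic Markov model for
#' each draw with the calibrated mortality model and baseline utility
#' held fixed, and records the incremental outcomes at every horizon.
#' Draws with `bmi_reduction >= bmi_pre` (an infeasible model) are
#' rejected and redrawn; the count is recorded. Fully reproducible for a
#' fixed `seed`.
#'
#' @param params A calibrated [model_parameters()] set.
#' @param dists A [parameter_distributions()] object.
#' @param n Number of replicates (base 1,000).
#' @param seed Integer RNG seed (mandatory: PSA results are meaningless
#'   without reproducibility).
#' @param horizons Integer vector of horizons (default 1:7).
#' @return A list of class `"psa_result"`: `draws` (one row per
#'   replicate: the four sampled parameters), `outcomes` (long format:
#'   `replicate`, `horizon`, `incremental_cost`, `added_life_years`,
#'   `added_qalys`, `icer`), `n`, `seed`, `n_rejected`.
#' @export
run_psa <- function(params, dists = parameter_distributions(params),
                    n = 1000L, seed, horizons = 1:7) {
  stopifnot(inherits(params, "cea_parameters"),
            inherits(dists, "parameter_distributions"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (missing(seed)) stop("a seed is required for the PSA")
  if (is.na(params$u_base)) stop("calibrate params before running the PSA")
  horizons <- sort(as.integer(horizons))
  hmax <- max(horizons)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  draws <- data.frame(
    replicate = seq_len(n),
    intervention_cost = .draw_dist(dists$intervention_cost, n),
    savings_per_bmi = .draw_dist(dists$savings_per_bmi, n),
    bmi_reduction = .draw_dist(dists$bmi_reduction, n),
    hrql_gain_per_bmi = .draw_dist(dists$hrql_gain_per_bmi, n)
  )
  n_rejected <- 0L
  repeat {
    bad <- which(draws$bmi_reduction >= params$bmi_pre |
                   draws$bmi_reduction <= 0)
    if (!length(bad)) break
    n_rejected <- n_rejected + length(bad)
    draws$bmi_reduction[bad] <- .draw_dist(dists$bmi_reduction, length(bad))
  }

  lt <- make_gompertz_life_table(params$mortality$q0,
                                 params$mortality$gompertz_slope,
                                 params$start_age, params$max_age)
  one <- function(i) {
    p <- params
    p$cost_params$intervention_cost <- draws$intervention_cost[i]
    p$savings_per_bmi <- draws$savings_per_bmi[i]
    p$bmi_reduction <- draws$bmi_reduction[i]
    p$hrql_gain_per_bmi <- draws$hrql_gain_per_bmi[i]
    surg <- run_arm(p, arm_spec("surgery", p$bmi_pre, p$bmi_reduction),
                    hmax, life_table = lt)
    ns <- run_arm(p, arm_spec("no_surgery", p$bmi_pre), hmax, life_table = lt)
    incremental_outcomes(surg, ns, p, horizons)
  }
  res <- lapply(seq_len(n), one)
  outcomes <- do.call(rbind, res)
  outcomes <- data.frame(
    replicate = rep(seq_len(n), each = length(horizons)),
    horizon = outcomes$horizon,
    incremental_cost = outcomes$incremental_cost,
    added_life_years = outcomes$added_life_years,
    added_qalys = outcomes$added_qalys,
    icer = outcomes$icer
  )
  structure(list(draws = draws, outcomes = outcomes, n = n,
                 seed = as.integer(seed), n_rejected = n_rejected,
                 horizons = horizons),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d replicates (seed %d, %d rejected draws), horizons %s\n",
              x$n, x$seed, x$n_rejected,
              paste(range(x$horizons), collapse = "-")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA replicates with
#' non-negative net monetary benefit (`wtp * added_qalys -
#' incremental_cost >= 0`). Non-decreasing in WTP at every horizon.
#'
#' @param result A [run_psa()] result.
#' @param horizons Horizons to tabulate (default: all in `result`).
#' @param wtp_grid Strictly non-empty numeric vector of WTP values
#'   (default $0 to $200,000 in $5,000 steps).
#' @return Long-format `data.frame`: `horizon`, `wtp`, `probability`.
#' @export
ceac <- function(result, horizons = result$horizons,
                 wtp_grid = seq(0, 2e5, by = 5e3)) {
  stopifnot(inherits(result, "psa_result"))
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  if (!all(horizons %in% result$horizons)) {
    stop("result does not cover all requested horizons")
  }
  rows <- lapply(horizons, function(h) {
    o <- result$outcomes[result$outcomes$horizon == h, ]
    prob <- vapply(wtp_grid, function(w) {
      mean(w * o$added_qalys - o$incremental_cost >= 0)
    }, 0)
    data.frame(horizon = h, wtp = wtp_grid, probability = prob)
  })
  do.call(rbind, rows)
}

#' Percentile interval of the ICER distribution at one horizon
#'
#' Empirical 2.5th/97.5th (for `level = 0.95`) percentiles of the
#' per-replicate ICERs. Replicates with non-positive QALY gains have no
#' meaningful ICER and are excluded (they still contribute to the CEAC
#' via net monetary benefit); fewer than 40 valid replicates make the
#' tail percentiles unstable and raise an error.
#'
#' @param result A [run_psa()] result.
#' @param horizon One horizon covered by `result`.
#' @param level Interval coverage (default 0.95).
#' @return Named numeric vector `c(low, high)` (US$/QALY).
#' @export
percentile_interval <- function(result, horizon, level = 0.95) {
  stopifnot(inherits(result, "psa_result"))
  if (!horizon %in% result$horizons) stop("no results for horizon ", horizon)
  o <- result$outcomes[result$outcomes$horizon == horizon, ]
  valid <- o$icer[o$added_qalys > 0 & is.finite(o$icer)]
  if (length(valid) < 40L) {
    stop("fewer than 40 replicates with positive QALY gain; ",
         "percentiles unstable (have ", length(valid), ")")
  }
  a <- (1 - level) / 2
  q <- stats::quantile(valid, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# parameters that one_way() knows how to sweep
.one_way_names <- c("hrql_gain_per_bmi", "intervention_cost",
                    "savings_per_bmi", "discount_rate",
                    "regain_annual_fraction")

#' One-way sensitivity sweep
#'
#' Re-runs the deterministic model over a grid of values for a single
#' parameter, everything else (including the calibrated mortality model
#' and baseline utility) held at the base case, and reports the ICER at
#' the given horizon.
#'
#' @param params A calibrated [model_parameters()] set.
#' @param name One of `"hrql_gain_per_bmi"`, `"intervention_cost"`,
#'   `"savings_per_bmi"`, `"discount_rate"`,
#'   `"regain_annual_fraction"`.
#' @param values Numeric vector of parameter values to sweep.
#' @param horizon Evaluation horizon (default 4).
#' @return `data.frame` with columns `parameter`, `value`,
#'   `incremental_cost`, `added_qalys`, `icer`, `icer_status`.
#' @export
one_way <- function(params, name, values, horizon = 4L) {
  stopifnot(inherits(params, "cea_parameters"))
  if (!is.character(name) || length(name) != 1L ||
      !name %in% .one_way_names) {
    stop("unknown parameter '", paste(name, collapse = ","),
         "'; valid names: ", paste(.one_way_names, collapse = ", "))
  }
  if (!length(values)) stop("values must be non-empty")
  rows <- lapply(values, function(v) {
    p <- params
    switch(name,
           hrql_gain_per_bmi = { p$hrql_gain_per_bmi <- v },
           intervention_cost = { p$cost_params$intervention_cost <- v },
           savings_per_bmi = { p$savings_per_bmi <- v },
           discount_rate = { p$discount_rate <- v },
           regain_annual_fraction = {
             p$regain <- regain_schedule(v, p$regain$first_regain_cycle,
                                         p$regain$plateau_fraction)
           })
    inc <- .base_incrementals(p, horizon)
    i <- horizon
    data.frame(parameter = name, value = v,
               incremental_cost = inc$incremental_cost[i],
               added_qalys = inc$added_qalys[i],
               icer = inc$icer[i], icer_status = inc$icer_status[i])
  })
  do.call(rbind, rows)
}
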