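# Download-free synthetic stand-ins for the study's data sources: a small
# surgical cohort with per-category billing lines, an HRQL/expenditure-
# vs-BMI survey, and (via make_gompertz_life_table) a life table.

# truncated-normal draws by redraw; bounds may be +/-Inf
.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  repeat {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
}

#' Generate a synthetic surgical cohort
#'
#' Each patient record carries sex (female with probability 10/11), age
#' at surgery (mean 17.3, SD 1.7, truncated to 14-20 years), height
#' (mean 169.3 cm, SD 8.8), pre-surgical weight (mean 138.2 kg, SD 16.9,
#' truncated positive), 12-month weight loss (mean 37.5 kg, SD 13.5,
#' truncated to (0, 90% of weight)), and one billed amount per charge
#' line (normal with that line's mean/SD, truncated at 0). BMI is
#' derived from weight and height rather than drawn independently, so
#' the weight-height-BMI triangle is internally consistent (marginal BMI
#' dispersion is then implied, not matched exactly).
#'
#' @param n Number of patients (`>= 0`; the study cohort had 11).
#' @param seed Integer RNG seed.
#' @param charges A `"charge_lines"` table (default [base_case_charges()]);
#'   one column per line is generated, named `charge_<phase>_<category>`.
#' @return A `data.frame`, one row per patient: `id`, `sex`
#'   (`"F"`/`"M"`), `age_at_surgery`, `height_cm`, `weight_kg`,
#'   `bmi_pre`, `weight_loss_12m_kg`, `bmi_post`, then the charge
#'   columns and `total_charges`.
#' @export
gen_cohort <- function(n, seed, charges = base_case_charges()) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  sex <- ifelse(stats::runif(n) < 10 / 11, "F", "M")
  age <- .rnorm_trunc(n, 17.3, 1.7, 14, 20)
  height <- .rnorm_trunc(n, 169.3, 8.8, 100, Inf)
  weight <- .rnorm_trunc(n, 138.2, 16.9, 40, Inf)
  loss <- numeric(n)
  if (n > 0L) {
    loss <- .rnorm_trunc(n, 37.5, 13.5, 1e-6, Inf)
    over <- which(loss >= 0.9 * weight)
    while (length(over)) {
      loss[over] <- .rnorm_trunc(length(over), 37.5, 13.5, 1e-6, Inf)
      over <- over[loss[over] >= 0.9 * weight[over]]
    }
  }
  h2 <- (height / 100)^2
  out <- data.frame(
    id = seq_len(n),
    sex = sex,
    age_at_surgery = age,
    height_cm = height,
    weight_kg = weight,
    bmi_pre = weight / h2,
    weight_loss_12m_kg = loss,
    bmi_post = (weight - loss) / h2,
    stringsAsFactors = FALSE
  )
  cname <- paste0("charge_", gsub("[^A-Za-z0-9]+", "_",
                                  paste(charges$phase, charges$category)))
  for (j in seq_len(nrow(charges))) {
    out[[cname[j]]] <- .rnorm_trunc(n, charges$mean_charge[j],
                                    charges$sd_charge[j], 0, Inf)
  }
  out$total_charges <- rowSums(out[, cname, drop = FALSE])
  out
}

#' Summary statistics of a synthetic cohort
#'
#' Tabulates, per clinical variable, the count, mean, SD, median and
#' range -- both statistic families, since published cohort descriptions
#' mix them.
#'
#' @param records A non-empty cohort from [gen_cohort()].
#' @return A `data.frame` with columns `variable`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`; plus a leading row for the female count and
#'   fraction.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty cohort data frame")
  }
  vars <- c("age_at_surgery", "height_cm", "weight_kg", "bmi_pre",
            "weight_loss_12m_kg", "bmi_post", "total_charges")
  vars <- intersect(vars, names(records))
  stat <- function(v) {
    x <- records[[v]]
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = stats::sd(x), median = stats::median(x),
               min = min(x), max = max(x))
  }
  female <- data.frame(variable = "female_fraction",
                       n = nrow(records),
                       mean = mean(records$sex == "F"),
                       sd = NA_real_,
                       median = NA_real_,
                       min = NA_real_, max = NA_real_)
  rbind(female, do.call(rbind, lapply(vars, stat)))
}

#' Generate a synthetic HRQL/expenditure-vs-BMI survey
#'
#' Emulates a household health survey restricted to severely obese
#' respondents (BMI >= 34): BMI is drawn right-skewed above 34
#' (34 + gamma), utility falls linearly in BMI and annual medical
#' expenditure rises linearly in BMI, each with additive Gaussian noise
#' and modest age/sex terms (the published slope estimates were age- and
#' gender-adjusted). Utility is clipped to \[0, 1\] and expenditure at
#' 0; the intercepts and noise scales default to values at which
#' clipping is rare, so the generating slopes remain identifiable (see
#' the methods vignette). Real survey-cost skew, sampling weights and
#' panel structure are deliberately not emulated.
#'
#' @param n Number of respondents (`>= 1`).
#' @param seed Integer RNG seed.
#' @param slope_hrql Utility decrease per BMI unit above 34 (base
#'   0.0042).
#' @param slope_cost Expenditure increase per BMI unit above 34, US$/yr
#'   (base 157).
#' @param noise_sds Named numeric vector `c(hrql = ..., cost = ...)` of
#'   residual SDs (defaults 0.08 utility, $1,200).
#' @param hrql_at_34 Mean utility at BMI 34 for a reference respondent
#'   (default 0.78).
#' @param cost_at_34 Mean expenditure at BMI 34, US$ (default 3,500).
#' @return A `data.frame`: `id`, `age`, `sex`, `bmi`, `hrql`,
#'   `annual_expenditure`.
#' @export
gen_survey <- function(n, seed, slope_hrql = 0.0042, slope_cost = 157,
                       noise_sds = c(hrql = 0.08, cost = 1200),
                       hrql_at_34 = 0.78, cost_at_34 = 3500) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  age <- .rnorm_trunc(n, 45, 14, 18, 85)
  sex <- ifelse(stats::runif(n) < 0.55, "F", "M")
  bmi <- 34 + stats::rgamma(n, shape = 2, scale = 3)
  # small covariate effects so 'age- and gender-adjusted' recovery is
  # exercised; centred so they do not shift the BMI slope
  age_eff_h <- -0.001 * (age - 45)
  sex_eff_h <- ifelse(sex == "F", 0.01, -0.01)
  hrql <- hrql_at_34 - slope_hrql * (bmi - 34) + age_eff_h + sex_eff_h +
    stats::rnorm(n, 0, noise_sds[["hrql"]])
  hrql <- pmin(1, pmax(0, hrql))
  age_eff_c <- 40 * (age - 45)
  sex_eff_c <- ifelse(sex == "F", 150, -150)
  expend <- cost_at_34 + slope_cost * (bmi - 34) + age_eff_c + sex_eff_c +
    stats::rnorm(n, 0, noise_sds[["cost"]])
  expend <- pmax(0, expend)
  data.frame(id = seq_len(n), age = age, sex = sex, bmi = bmi,
             hrql = hrql, annual_expenditure = expend,
             stringsAsFactors = FALSE)
}

#' Recover the HRQL and expenditure slopes from a survey
#'
#' Ordinary least squares of utility and of annual expenditure on BMI,
#' adjusted for age and sex, with conventional standard errors. Sign
#' convention: both slopes are reported as the gain per unit of BMI
#' *reduction*, i.e. positive numbers under the generating model
#' (utility rises and spending falls as BMI falls).
#'
#' @param survey A [gen_survey()] data frame (or any data frame with
#'   columns `bmi`, `hrql`, `annual_expenditure`, and optionally `age`,
#'   `sex`) with at least 3 rows and positive BMI variance.
#' @return A list: `hrql_per_bmi`, `hrql_se`, `cost_per_bmi`, `cost_se`.
#' @export
recover_slopes <- function(survey) {
  stopifnot(is.data.frame(survey))
  if (nrow(survey) < 3L) stop("need at least 3 survey records")
  if (stats::var(survey$bmi) <= 0) {
    stop("BMI has zero variance; slope not identifiable")
  }
  rhs <- "bmi"
  if ("age" %in% names(survey)) rhs <- c(rhs, "age")
  if ("sex" %in% names(survey) && length(unique(survey$sex)) > 1L) {
    rhs <- c(rhs, "sex")
  }
  fml <- function(y) stats::as.formula(paste(y, "~", paste(rhs, collapse = "+")))
  fit_h <- stats::lm(fml("hrql"), data = survey)
  fit_c <- stats::lm(fml("annual_expenditure"), data = survey)
  co_h <- summary(fit_h)$coefficients["bmi", ]
  co_c <- summary(fit_c)$coefficients["bmi", ]
  list(hrql_per_bmi = -unname(co_h["Estimate"]),
       hrql_se = unname(co_h["Std. Error"]),
       cost_per_bmi = unname(co_c["Estimate"]),
       cost_se = unname(co_c["Std. Error"]))
}
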