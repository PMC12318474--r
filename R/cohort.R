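#' Faller-type categories
#'
#' The mutually exclusive nonfatal faller types a surviving person-cycle can
#' take: no fall; a single fall not requiring medical attention (non-MA); a
#' single medically attended (MA) fall; recurrent non-MA falls; and recurrent
#' falls including one or more MA falls.
#'
#' @return character vector of the five type labels, `"no_fall"` first.
#' @export
faller_types <- function() {
  c("no_fall", "single_non_ma", "single_ma", "recurrent_non_ma", "recurrent_ma")
}

# shared column layout for cohorts
cohort_columns <- function() {
  c("id", "age", "sex", "ses_quartile", "falls_history", "frailty",
    "physical_activity", "cognitive_impairment", "fear_of_falling",
    "abnormal_gait_balance", "alive", "in_ltc", "entry_year")
}

#' Generate a baseline cohort of community-dwelling adults aged 60+
#'
#' Ages follow a truncated exponential mass above 60; SES quartiles are
#' assigned in equal shares (within one person when `n` is not divisible by
#' four); baseline frailty is drawn from a lognormal-noise age trend scaled
#' by the quartile frailty gradient; falls history, physical activity,
#' cognitive impairment, fear of falling and gait/balance impairment are
#' drawn from logistic prevalence models in age and frailty. Everyone starts
#' alive and outside long-term care.
#'
#' @param n number of individuals (>= 1 for a baseline cohort; 0 allowed for
#'   entry cohorts).
#' @param params an `fp_parameters` object.
#' @param seed integer seed; the cohort is a pure function of
#'   `(n, params, seed)`.
#' @param age optional fixed entry age (used for annual entry cohorts).
#' @param entry_year model cycle at which the cohort enters (0 = baseline).
#' @return a data.frame of class `fp_cohort`, one row per individual, with
#'   columns `r paste(cohort_columns(), collapse = ", ")`.
#' @export
#' @examples
#' cohort <- generate_baseline_cohort(100, build_default_parameters(), seed = 1)
#' summary(cohort$frailty)
generate_baseline_cohort <- function(n, params, seed, age = NULL, entry_year = 0L) {
  if (entry_year == 0L && n < 1) stop("baseline cohort requires n >= 1", call. = FALSE)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  cp <- params$cohort_params
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ses <- rep_len(1:4, n)
  ages <- if (is.null(age)) {
    60 + pmin(stats::rexp(n, rate = 1 / cp$age_mean_excess), cp$age_max - 60)
  } else rep(as.numeric(age), n)
  female <- stats::runif(n) < cp$female_prob

  sdlog <- cp$baseline_frailty_sdlog
  trend <- cp$baseline_frailty_mean_60 + cp$baseline_frailty_age_slope * (ages - 60)
  noise <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) # mean-one lognormal noise
  frailty <- pmin(100, pmax(0,
    trend * params$ses_gradients$frailty[ses] * cp$baseline_frailty_multiplier * noise))

  prev <- function(base, age_slope = 0, frailty_slope = 0) {
    stats::plogis(stats::qlogis(base) + age_slope * (ages - 60) + frailty_slope * frailty)
  }
  falls_history <- as.integer(stats::runif(n) < prev(cp$falls_history_base,
    cp$falls_history_age_slope, cp$falls_history_frailty_slope))
  low_act <- stats::runif(n) < prev(cp$low_activity_base, 0, cp$low_activity_frailty_slope)
  cog <- as.integer(stats::runif(n) < prev(cp$cognitive_base, cp$cognitive_age_slope))
  fear <- as.integer(stats::runif(n) < prev(cp$fear_base, 0, cp$fear_frailty_slope))
  gait <- as.integer(stats::runif(n) < prev(cp$gait_base, cp$gait_age_slope,
                                            cp$gait_frailty_slope))

  cohort <- data.frame(
    id = seq_len(n),
    age = ages,
    sex = ifelse(female, "female", "male"),
    ses_quartile = ses,
    falls_history = falls_history,
    frailty = frailty,
    physical_activity = ifelse(low_act, "low", "high"),
    cognitive_impairment = cog,
    fear_of_falling = fear,
    abnormal_gait_balance = gait,
    alive = rep(TRUE, n),
    in_ltc = rep(FALSE, n),
    entry_year = rep(as.integer(entry_year), n),
    stringsAsFactors = FALSE
  )
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "creation_cycle") <- as.integer(entry_year)
  class(cohort) <- c("fp_cohort", "data.frame")
  cohort
}

#' Generate an annual entry cohort aged exactly 60
#'
#' New individuals enter the open population each cycle at age 60, with the
#' other characteristics drawn as at baseline for a 60-year-old.
#'
#' @param cycle model cycle index (>= 1) at which the cohort enters.
#' @param n cohort size (0 allowed).
#' @inheritParams generate_baseline_cohort
#' @return an `fp_cohort` data.frame with `age == 60` and
#'   `entry_year == cycle` throughout.
#' @export
generate_entry_cohort <- function(cycle, n, params, seed) {
  if (cycle < 1) stop("entry cohorts require cycle >= 1", call. = FALSE)
  generate_baseline_cohort(n, params, seed, age = 60, entry_year = as.integer(cycle))
}

#' Write a cohort to CSV
#'
#' @param cohort an `fp_cohort` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path, row.names = FALSE)
  invisible(path)
}
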