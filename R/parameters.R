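#' Default synthetic model parameterisation
#'
#' Builds the complete set of numeric inputs of the falls-prevention model:
#' falls-risk regression coefficients, faller-type mixture, mortality and
#' long-term-care (LTC) admission risks, frailty progression, utilities,
#' costs (GBP, 2023 prices), intervention pathway characteristics, access
#' (supply/demand) rates by care level, socioeconomic-status (SES) gradients
#' and the economic evaluation settings.
#'
#' The values are a synthetic parameterisation designed to reproduce the
#' qualitative structure of a UK urban 60+ community: roughly 30% of the
#' cohort with falls history, annual fall risk rising with age and frailty,
#' 28% hospitalisation probability per medically attended (MA) fall, 3.5%
#' annual discounting over a 40-cycle horizon, and SES gradients that make
#' the most deprived quartile (quartile 4) strictly worse off on baseline
#' frailty, fall risk, utility, mortality and GP access than the least
#' deprived (quartile 1). Every value can be overridden via a YAML/JSON
#' configuration file, see [read_parameters()].
#'
#' @return an object of class `fp_parameters`: a named, nested list.
#' @export
#' @examples
#' p <- build_default_parameters()
#' p$hospitalisation_prob_per_ma_fall  # 0.28
#' p$economics$discount_rate           # 0.035
build_default_parameters <- function() {
  params <- list(
    # log-odds scale; frailty enters as frailty/100, age as (age - 60) years
    fall_risk_coefficients = c(
      intercept = -2.2, age = 0.03, female = 0.15, falls_history = 0.9,
      frailty = 1.6, low_activity = 0.3, cognitive_impairment = 0.4,
      fear_of_falling = 0.3, abnormal_gait_balance = 0.6
    ),
    # conditional on >=1 nonfatal fall in the cycle
    faller_type_split = c(
      single_non_ma = 0.45, single_ma = 0.20,
      recurrent_non_ma = 0.20, recurrent_ma = 0.15
    ),
    # P(recurrent-with-MA type carries 2 rather than 1 MA fall)
    recurrent_ma_two_prob = 0.3,
    hospitalisation_prob_per_ma_fall = 0.28,
    fatal_fall_params = c(base_prob = 3e-04, age_slope = 0.06, frailty_slope = 1.2),
    other_cause_mortality_params = c(
      base_prob_male = 0.006, base_prob_female = 0.004,
      age_log_slope = 0.085, frailty_multiplier = 1.0
    ),
    frailty_progression = list(
      # frailty-index points per year by attained age band
      base_by_age = c(age_60_69 = 0.6, age_70_79 = 0.9, age_80_plus = 1.3),
      faller_increment = c(
        no_fall = 0, single_non_ma = 0.2, single_ma = 0.6,
        recurrent_non_ma = 0.5, recurrent_ma = 1.2
      )
    ),
    # annual probabilities; logistic in (age - 60) and frailty/100;
    # 'multiplier' is the scenario knob applied to the resulting probability
    cognitive_impairment_incidence = c(
      base_prob = 0.01, age_slope = 0.05, frailty_slope = 0.8, multiplier = 1.0
    ),
    fear_of_falling_onset = c(base_prob = 0.05, fall_addition = 0.15),
    gait_balance_onset = c(base_prob = 0.04, frailty_slope = 1.2),
    activity_transition = c(
      to_low_prob = 0.06, to_low_frailty_slope = 0.8, to_high_prob = 0.03
    ),
    ltc_admission_params = c(intercept = -7.5, age_slope = 0.07, frailty_slope = 3.5),
    utility_params = list(
      baseline_60 = 0.92, age_decrement = 0.003, female_decrement = 0.01,
      frailty_decrement = 0.004,
      acute_loss = c(
        no_fall = 0, single_non_ma = 0.005, single_ma = 0.03,
        recurrent_non_ma = 0.015, recurrent_ma = 0.05
      ),
      hospitalised_loss = 0.06,
      floor = 0
    ),
    cost_params = list(
      allcause_base = 1800, allcause_age_slope = 40, allcause_frailty_slope = 55,
      fall_cost = c(no_fall = 0, single_non_ma = 40, recurrent_non_ma = 120),
      ma_fall_cost = 750,                # per non-hospitalised MA fall
      hospitalised_ma_fall_cost = 13000, # hip-fracture admission per hospitalised MA fall
      oop_base = 250, oop_frailty_slope = 18,
      productivity_paid_base = 9000, productivity_paid_age_decline = 600,
      productivity_unpaid_base = 3000, productivity_frailty_decline = 0.008,
      informal_care_frailty_slope = 30
    ),
    intervention_params = list(
      R = list(public_cost = 600, copayment = 20, participant_time_cost = 150,
               caregiver_time_cost = 80, relative_risk = 0.76, effect_duration = 2),
      P = list(public_cost = 450, copayment = 15, participant_time_cost = 120,
               caregiver_time_cost = 60, relative_risk = 0.80, effect_duration = 2),
      SR = list(public_cost = 250, copayment = 40, participant_time_cost = 100,
                caregiver_time_cost = 20, relative_risk = 0.85, effect_duration = 1)
    ),
    access_params = list(
      gp_access_rate = 0.75,
      supply = list(
        usual = c(R = 0.5, P = 0.35, SR = 0.4),
        recommended = c(R = 1, P = 1, SR = 1) # no supply constraint when scaled up
      ),
      demand = list(
        usual = c(R = 0.5, P = 0.45, SR = 0.3),
        recommended = c(R = 0.7, P = 0.6, SR = 0.45)
      )
    ),
    # quartile 1 = least deprived ... quartile 4 = most deprived
    ses_gradients = list(
      frailty = c(0.85, 0.95, 1.05, 1.25),   # multiplies baseline frailty draw
      fall_odds = c(0.9, 1.0, 1.1, 1.3),     # multiplies fall odds
      utility = c(1.02, 1.00, 0.98, 0.94),   # multiplies baseline utility
      mortality = c(0.9, 1.0, 1.1, 1.25),    # multiplies other-cause death prob
      gp_access = c(1.1, 1.0, 0.95, 0.85)    # multiplies GP access rate (capped at 1)
    ),
    cohort_params = list(
      age_mean_excess = 8, age_max = 95,
      baseline_frailty_mean_60 = 8, baseline_frailty_age_slope = 0.45,
      baseline_frailty_sdlog = 0.5, baseline_frailty_multiplier = 1.0,
      female_prob = 0.55,
      falls_history_base = 0.22, falls_history_age_slope = 0.02,
      falls_history_frailty_slope = 0.015,
      low_activity_base = 0.30, low_activity_frailty_slope = 0.02,
      cognitive_base = 0.06, cognitive_age_slope = 0.05,
      fear_base = 0.20, fear_frailty_slope = 0.02,
      gait_base = 0.15, gait_age_slope = 0.03, gait_frailty_slope = 0.02
    ),
    # proactive screening: falls history AND abnormal gait/balance ("and"),
    # switchable to "or"
    proactive_screen_rule = "and",
    economics = list(
      discount_rate = 0.035, horizon = 40,
      public_thresholds = c(20000, 30000), societal_threshold = 60000
    )
  )
  class(params) <- c("fp_parameters", "list")
  validate_parameters(params)
  params
}

#' Validate a model parameter set
#'
#' Checks the structural invariants every parameter set must satisfy:
#' probabilities in \[0, 1\], the faller-type mixture summing to one,
#' relative risks in (0, 1\], non-negative costs, supply equal to one at the
#' recommended level, a non-negative discount rate, horizon of at least one
#' cycle and positive thresholds.
#'
#' @param params an `fp_parameters` object (or plain list with the same shape).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, why) {
    stop(sprintf("invalid parameter '%s': %s", field, why), call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!all(is.finite(x)) || any(x < 0) || any(x > 1))
      fail(field, "must be a probability in [0, 1]")
  }
  for (f in c("hospitalisation_prob_per_ma_fall", "recurrent_ma_two_prob"))
    chk_prob(params[[f]], f)
  split <- params$faller_type_split
  chk_prob(split, "faller_type_split")
  if (abs(sum(split) - 1) > 1e-12)
    fail("faller_type_split", "must sum to 1")
  if (!setequal(names(split), faller_types()[-1]))
    fail("faller_type_split", "must name the four nonfatal faller types")
  chk_prob(params$fatal_fall_params[["base_prob"]], "fatal_fall_params$base_prob")
  chk_prob(params$cognitive_impairment_incidence[["base_prob"]],
           "cognitive_impairment_incidence$base_prob")
  chk_prob(params$access_params$gp_access_rate, "access_params$gp_access_rate")
  for (lvl in c("usual", "recommended")) {
    chk_prob(params$access_params$supply[[lvl]],
             paste0("access_params$supply$", lvl))
    chk_prob(params$access_params$demand[[lvl]],
             paste0("access_params$demand$", lvl))
  }
  if (any(params$access_params$supply$recommended != 1))
    fail("access_params$supply$recommended", "supply must equal 1 at recommended level")
  for (pw in c("R", "P", "SR")) {
    ip <- params$intervention_params[[pw]]
    rr <- ip$relative_risk
    if (!is.finite(rr) || rr <= 0 || rr > 1)
      fail(paste0("intervention_params$", pw, "$relative_risk"),
           "relative risk must lie in (0, 1]")
    costs <- unlist(ip[c("public_cost", "copayment", "participant_time_cost",
                         "caregiver_time_cost")])
    if (any(!is.finite(costs)) || any(costs < 0))
      fail(paste0("intervention_params$", pw), "costs must be finite and >= 0")
    if (ip$effect_duration < 1)
      fail(paste0("intervention_params$", pw, "$effect_duration"), "must be >= 1")
  }
  cp <- params$cost_params
  costs <- c(cp$allcause_base, cp$fall_cost, cp$ma_fall_cost,
             cp$hospitalised_ma_fall_cost, cp$oop_base,
             cp$productivity_paid_base, cp$productivity_unpaid_base)
  if (any(!is.finite(costs)) || any(costs < 0))
    fail("cost_params", "cost levels must be finite and >= 0")
  fr <- unlist(params$frailty_progression)
  if (any(!is.finite(fr))) fail("frailty_progression", "increments must be finite")
  for (g in names(params$ses_gradients)) {
    v <- params$ses_gradients[[g]]
    if (length(v) != 4 || any(!is.finite(v)) || any(v <= 0))
      fail(paste0("ses_gradients$", g), "must be 4 positive quartile multipliers")
  }
  ec <- params$economics
  if (!is.finite(ec$discount_rate) || ec$discount_rate < 0)
    fail("economics$discount_rate", "must be >= 0")
  if (ec$horizon < 1) fail("economics$horizon", "must be >= 1")
  if (any(c(ec$public_thresholds, ec$societal_threshold) <= 0))
    fail("economics thresholds", "must be > 0")
  if (!params$proactive_screen_rule %in% c("and", "or"))
    fail("proactive_screen_rule", "must be 'and' or 'or'")
  invisible(params)
}

#' Read a parameter configuration file (YAML or JSON)
#'
#' The document mirrors the field names of the default parameter set; any
#' subset of fields may be given and is merged over the defaults. Unknown
#' keys are rejected with an error naming the key.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `fp_parameters` object.
#' @seealso [write_parameters()], [build_default_parameters()]
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported configuration format: .", ext, call. = FALSE)
  )
  params <- merge_into_template(unclass(build_default_parameters()), doc, "")
  class(params) <- c("fp_parameters", "list")
  validate_parameters(params)
  params
}

#' Write a parameter set to a configuration file
#'
#' @param params an `fp_parameters` object.
#' @param path output path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  x <- rapply(unclass(params), function(v) if (!is.null(names(v))) as.list(v) else v,
              classes = c("numeric", "integer", "character"), how = "replace")
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    stop("unsupported configuration format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# Merge a user document over the default template, rejecting unknown keys and
# coercing leaves to the template's shape (yaml returns named lists where the
# template holds named numeric vectors).
merge_into_template <- function(template, doc, prefix) {
  if (is.null(doc)) return(template)
  if (!is.list(template)) {
    leaf <- unlist(doc)
    if (!is.null(names(template))) {
      if (is.null(names(leaf)) && length(leaf) == length(template)) {
        names(leaf) <- names(template)
      } else {
        bad <- setdiff(names(leaf), names(template))
        if (length(bad))
          stop("unknown key in configuration: ", prefix, "$", bad[1], call. = FALSE)
        out <- template
        out[names(leaf)] <- leaf
        return(out)
      }
    }
    storage.mode(leaf) <- storage.mode(template)
    return(leaf)
  }
  if (!is.list(doc)) stop("configuration field ", prefix, " must be a mapping", call. = FALSE)
  bad <- setdiff(names(doc), names(template))
  if (length(bad))
    stop("unknown key in configuration: ",
         if (nzchar(prefix)) paste0(prefix, "$", bad[1]) else bad[1], call. = FALSE)
  for (k in names(doc)) {
    template[[k]] <- merge_into_template(
      template[[k]], doc[[k]],
      if (nzchar(prefix)) paste0(prefix, "$", k) else k
    )
  }
  template
}

#' @export
print.fp_parameters <- function(x, ...) {
  cat("<fp_parameters> falls-prevention model inputs\n")
  cat("  discount rate:", x$economics$discount_rate,
      " horizon:", x$economics$horizon, "cycles\n")
  cat("  hospitalisation prob per MA fall:", x$hospitalisation_prob_per_ma_fall, "\n")
  cat("  thresholds (public):", paste(x$economics$public_thresholds, collapse = ", "),
      " societal:", x$economics$societal_threshold, "GBP/QALY\n")
  invisible(x)
}
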