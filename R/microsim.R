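#' Annual discount factor
#'
#' Costs and QALYs accrue at cycle start and are discounted to model start:
#' cycle 0 is undiscounted.
#'
#' @param cycle cycle index (>= 0), vectorised.
#' @param rate annual discount rate (default 0.035).
#' @return `(1 + rate)^(-cycle)`.
#' @export
#' @examples
#' discount_factor(0:3, 0.035)
discount_factor <- function(cycle, rate = 0.035) {
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle)
}

# indicator helpers over a cohort data.frame (or plain list of columns, which
# the simulation engine uses internally for speed)
ind_female <- function(cohort) as.numeric(cohort$sex == "female")
ind_low_activity <- function(cohort) as.numeric(cohort$physical_activity == "low")
n_persons <- function(cohort) length(cohort[["id"]])

#' Annual fall probability from the logistic risk model
#'
#' The linear predictor combines the risk coefficients with the person's
#' characteristics (age above 60, sex, falls history, frailty/100, low
#' physical activity, cognitive impairment, fear of falling, abnormal
#' gait/balance) plus the SES quartile log-odds shift. Any active
#' intervention effect multiplies the fall odds.
#'
#' @param cohort an `fp_cohort` data.frame (or any data.frame with the same
#'   columns).
#' @param params an `fp_parameters` object.
#' @param active_effect relative risk applied on the odds scale, in (0, 1];
#'   scalar or one value per row.
#' @return vector of probabilities in (0, 1).
#' @export
fall_probability <- function(cohort, params, active_effect = 1) {
  if (any(active_effect <= 0) || any(active_effect > 1))
    stop("active_effect must lie in (0, 1]", call. = FALSE)
  b <- params$fall_risk_coefficients
  lp <- b[["intercept"]] +
    b[["age"]] * (cohort$age - 60) +
    b[["female"]] * ind_female(cohort) +
    b[["falls_history"]] * cohort$falls_history +
    b[["frailty"]] * cohort$frailty / 100 +
    b[["low_activity"]] * ind_low_activity(cohort) +
    b[["cognitive_impairment"]] * cohort$cognitive_impairment +
    b[["fear_of_falling"]] * cohort$fear_of_falling +
    b[["abnormal_gait_balance"]] * cohort$abnormal_gait_balance +
    log(params$ses_gradients$fall_odds[cohort$ses_quartile])
  p <- stats::plogis(lp)
  # odds multiplication; the effect == 1 branch is exact so that a null
  # intervention leaves probabilities bit-identical
  if (all(active_effect == 1)) return(p)
  e <- rep_len(active_effect, length(p))
  treated <- e != 1
  p[treated] <- p[treated] * e[treated] / (1 - p[treated] + p[treated] * e[treated])
  p
}

#' Classify a cycle's faller type and count hospitalised MA falls
#'
#' Non-fallers are `no_fall`. Fallers draw one of the four nonfatal faller
#' types from the conditional mixture; recurrent-with-MA types carry 1 or 2
#' MA falls; every MA fall is independently hospitalised with the configured
#' probability (default 0.28, keyed to hip-fracture admission).
#'
#' @param fell logical vector: did the person fall this cycle?
#' @param params an `fp_parameters` object.
#' @param u optional list of uniform variates (`type`, `count`, `hosp`), one
#'   per person, for common-random-number control; drawn internally when
#'   `NULL`.
#' @return list with `type` (character, see [faller_types()]), `ma_count`
#'   and `hospitalised` (integer counts).
#' @export
classify_faller <- function(fell, params, u = NULL) {
  split <- params$faller_type_split
  if (abs(sum(split) - 1) > 1e-12)
    stop("faller_type_split must sum to 1", call. = FALSE)
  n <- length(fell)
  if (is.null(u))
    u <- list(type = stats::runif(n), count = stats::runif(n), hosp = stats::runif(n))
  types <- faller_types()
  idx <- findInterval(u$type, cumsum(split), left.open = TRUE) + 2L # 2..5
  type <- rep("no_fall", n)
  type[fell] <- types[idx[fell]]
  ma_count <- integer(n)
  ma_count[type == "single_ma"] <- 1L
  rma <- type == "recurrent_ma"
  ma_count[rma] <- 1L + as.integer(u$count[rma] < params$recurrent_ma_two_prob)
  hospitalised <- integer(n)
  has_ma <- ma_count > 0L
  hospitalised[has_ma] <- as.integer(stats::qbinom(
    u$hosp[has_ma], ma_count[has_ma], params$hospitalisation_prob_per_ma_fall))
  list(type = type, ma_count = ma_count, hospitalised = hospitalised)
}

#' Mortality step: fatal fall, then other-cause death
#'
#' A fatal-fall draw at the logistic of the fatal-fall parameters (age and
#' frailty slopes on the log-odds scale) is followed, for survivors, by
#' other-cause death at the age/sex baseline schedule multiplied by the
#' frailty multiplier and the SES mortality gradient.
#'
#' @inheritParams classify_faller
#' @param cohort an `fp_cohort` data.frame.
#' @param u optional list of uniforms (`fatal`, `other`).
#' @return list with logical `died` and character `cause`
#'   (`"fatal_fall"`, `"other"` or `NA`).
#' @export
mortality_step <- function(cohort, params, u = NULL) {
  n <- n_persons(cohort)
  if (is.null(u)) u <- list(fatal = stats::runif(n), other = stats::runif(n))
  fp <- params$fatal_fall_params
  p_fatal <- stats::plogis(stats::qlogis(fp[["base_prob"]]) +
    fp[["age_slope"]] * (cohort$age - 60) + fp[["frailty_slope"]] * cohort$frailty / 100)
  oc <- params$other_cause_mortality_params
  base <- rep(oc[["base_prob_male"]], n)
  base[cohort$sex == "female"] <- oc[["base_prob_female"]]
  q <- pmin(0.99, base * exp(oc[["age_log_slope"]] * (cohort$age - 60)) *
              (1 + oc[["frailty_multiplier"]] * cohort$frailty / 100) *
              params$ses_gradients$mortality[cohort$ses_quartile])
  fatal <- u$fatal < p_fatal
  other <- !fatal & u$other < q
  cause <- rep(NA_character_, n)
  cause[other] <- "other"
  cause[fatal] <- "fatal_fall"
  list(died = fatal | other, cause = cause)
}

#' Annual frailty progression
#'
#' Frailty increases by an age-band base increment plus a faller-type
#' add-on, optionally scaled by a scenario multiplier, clamped to \[0, 100\].
#'
#' @param cohort an `fp_cohort` data.frame.
#' @param faller_type character vector of this cycle's faller types.
#' @param params an `fp_parameters` object.
#' @param scenario_multiplier scales the total increment (default 1).
#' @return numeric vector of updated frailty values.
#' @export
update_frailty <- function(cohort, faller_type, params, scenario_multiplier = 1) {
  fp <- params$frailty_progression
  base <- unname(fp$base_by_age)[findInterval(cohort$age, c(70, 80)) + 1L]
  inc <- (base + fp$faller_increment[faller_type]) * scenario_multiplier
  pmin(100, pmax(0, cohort$frailty + unname(inc)))
}

#' Update time-varying characteristics at cycle end
#'
#' Sets next-cycle falls history from this cycle's faller type; applies
#' cognitive-impairment incidence (absorbing, scaled by the scenario
#' multiplier and capped at 1), fear-of-falling onset (raised in fallers),
#' gait/balance impairment onset (absorbing) and physical-activity
#' transitions; then ages everyone by one year. Frailty is updated
#' separately by [update_frailty()].
#'
#' @inheritParams update_frailty
#' @param u optional list of uniforms (`cognitive`, `fear`, `gait`,
#'   `activity`).
#' @return the updated cohort data.frame.
#' @export
update_time_varying <- function(cohort, faller_type, params, u = NULL) {
  n <- n_persons(cohort)
  if (is.null(u))
    u <- list(cognitive = stats::runif(n), fear = stats::runif(n),
              gait = stats::runif(n), activity = stats::runif(n))
  fell <- faller_type != "no_fall"
  cohort$falls_history <- as.integer(fell)

  ci <- params$cognitive_impairment_incidence
  p_cog <- pmin(1, stats::plogis(stats::qlogis(ci[["base_prob"]]) +
    ci[["age_slope"]] * (cohort$age - 60) +
    ci[["frailty_slope"]] * cohort$frailty / 100) * ci[["multiplier"]])
  cohort$cognitive_impairment <- as.integer(
    cohort$cognitive_impairment == 1L | u$cognitive < p_cog)

  fo <- params$fear_of_falling_onset
  p_fear <- pmin(1, fo[["base_prob"]] + fo[["fall_addition"]] * fell)
  cohort$fear_of_falling <- as.integer(cohort$fear_of_falling == 1L | u$fear < p_fear)

  gb <- params$gait_balance_onset
  p_gait <- stats::plogis(stats::qlogis(gb[["base_prob"]]) +
                          gb[["frailty_slope"]] * cohort$frailty / 100)
  cohort$abnormal_gait_balance <- as.integer(
    cohort$abnormal_gait_balance == 1L | u$gait < p_gait)

  at <- params$activity_transition
  low <- cohort$physical_activity == "low"
  p_to_low <- stats::plogis(stats::qlogis(at[["to_low_prob"]]) +
                            at[["to_low_frailty_slope"]] * cohort$frailty / 100)
  new_low <- (low & u$activity >= at[["to_high_prob"]]) |
             (!low & u$activity < p_to_low)
  activity <- rep("high", n)
  activity[new_low] <- "low"
  cohort$physical_activity <- activity

  cohort$age <- cohort$age + 1
  cohort
}

#' Long-term care admission
#'
#' Admission probability is logistic in age and frailty; admission is an
#' absorbing model exit at the end of the cycle.
#'
#' @inheritParams update_frailty
#' @param u optional uniform variates, one per row.
#' @return logical vector: admitted this cycle.
#' @export
ltc_admission <- function(cohort, params, u = NULL) {
  if (is.null(u)) u <- stats::runif(n_persons(cohort))
  lp <- params$ltc_admission_params
  p <- stats::plogis(lp[["intercept"]] + lp[["age_slope"]] * (cohort$age - 60) +
                     lp[["frailty_slope"]] * cohort$frailty / 100)
  u < p
}

#' Eligibility for the reactive pathway
#'
#' A person is referred reactively if the immediately preceding cycle
#' recorded at least one medically attended fall.
#'
#' @param prev_ma_count integer vector: MA falls recorded in the previous
#'   cycle.
#' @return logical vector.
#' @export
eligible_reactive <- function(prev_ma_count) {
  prev_ma_count > 0
}

#' Eligibility for the proactive pathway
#'
#' Requires a successful GP-contact draw at the SES-adjusted access rate and
#' a positive risk screen. The screen combines falls history and abnormal
#' gait/balance with the rule in `params$proactive_screen_rule`
#' (conjunction by default).
#'
#' @inheritParams update_frailty
#' @param u_gp optional uniform variates for the GP-contact draw.
#' @return logical vector.
#' @export
eligible_proactive <- function(cohort, params, u_gp = NULL) {
  if (is.null(u_gp)) u_gp <- stats::runif(n_persons(cohort))
  rate <- pmin(1, params$access_params$gp_access_rate *
                 params$ses_gradients$gp_access[cohort$ses_quartile])
  seen <- u_gp < rate
  screen <- if (identical(params$proactive_screen_rule, "or")) {
    cohort$falls_history == 1L | cohort$abnormal_gait_balance == 1L
  } else {
    cohort$falls_history == 1L & cohort$abnormal_gait_balance == 1L
  }
  seen & screen
}

#' Eligibility for the self-referred pathway
#'
#' Every community-dwelling (alive, not in LTC) person may self-refer;
#' uptake is then governed by the demand probability.
#'
#' @param cohort an `fp_cohort` data.frame.
#' @return logical vector, `TRUE` throughout.
#' @export
eligible_self_referred <- function(cohort) {
  rep(TRUE, n_persons(cohort))
}

#' Assign at most one intervention pathway per cycle
#'
#' A pathway is received if the person is eligible for it and both its
#' supply and demand draws succeed. When several pathways qualify,
#' precedence is reactive > proactive > self-referred.
#'
#' @inheritParams update_frailty
#' @param config an `fp_strategy_config`.
#' @param prev_ma_count MA falls in the previous cycle (reactive
#'   eligibility).
#' @param u optional list of uniforms: `gp`, and `supply_R/P/SR`,
#'   `demand_R/P/SR`.
#' @return character vector in `c("none", "R", "P", "SR")`.
#' @export
assign_intervention <- function(cohort, config, params, prev_ma_count, u = NULL) {
  n <- n_persons(cohort)
  if (is.null(u)) {
    u <- list(gp = stats::runif(n))
    for (pw in c("R", "P", "SR")) {
      u[[paste0("supply_", pw)]] <- stats::runif(n)
      u[[paste0("demand_", pw)]] <- stats::runif(n)
    }
  }
  eligible <- list(
    R = eligible_reactive(prev_ma_count),
    P = eligible_proactive(cohort, params, u$gp),
    SR = eligible_self_referred(cohort)
  )
  received <- rep("none", n)
  for (pw in c("R", "P", "SR")) { # precedence order
    take <- received == "none" & eligible[[pw]] &
      u[[paste0("supply_", pw)]] < config$supply[[pw]] &
      u[[paste0("demand_", pw)]] < config$demand[[pw]]
    received[take] <- pw
  }
  received
}

#' Per-cycle utility and costs by category
#'
#' Cycle utility is the age/sex baseline scaled by the SES utility gradient,
#' minus the frailty decrement and the acute loss of the cycle's faller type
#' (plus a further loss per hospitalised MA fall), floored at the configured
#' minimum. Public sector cost combines the all-cause base (age, frailty),
#' the directly fall-related cost (recorded separately inside the all-cause
#' total) and the public intervention cost if a pathway was received.
#' Nonpublic components — out-of-pocket expenditure, paid and unpaid
#' productivity value, informal care cost, copayment and time costs — are
#' returned in separate columns. All values are undiscounted.
#'
#' @inheritParams update_frailty
#' @param ma_count integer vector of MA falls this cycle.
#' @param ma_hospitalised integer vector of hospitalised MA falls
#'   (`<= ma_count`).
#' @param intervention character vector in `c("none", "R", "P", "SR")`.
#' @return data.frame with columns `utility`, `cost_public_allcause`,
#'   `cost_public_fall`, `oop_expenditure`, `productivity_paid`,
#'   `productivity_unpaid`, `informal_care`, `intervention_public`,
#'   `intervention_copay`, `intervention_participant_time`,
#'   `intervention_caregiver_time`.
#' @export
cycle_outcomes <- function(cohort, faller_type, ma_count, ma_hospitalised, params,
                           intervention = "none") {
  n <- n_persons(cohort)
  up <- params$utility_params
  base_u <- (up$baseline_60 - up$age_decrement * (cohort$age - 60) -
             up$female_decrement * ind_female(cohort)) *
    params$ses_gradients$utility[cohort$ses_quartile]
  utility <- pmax(up$floor,
    base_u - up$frailty_decrement * cohort$frailty -
      unname(up$acute_loss[faller_type]) - up$hospitalised_loss * ma_hospitalised)

  cp <- params$cost_params
  allcause_base <- cp$allcause_base + cp$allcause_age_slope * (cohort$age - 60) +
    cp$allcause_frailty_slope * cohort$frailty

  # per-type base cost; MA-fall costs are added per fall below
  type_cost <- c(cp$fall_cost, single_ma = 0, recurrent_ma = 0)
  fall_cost <- unname(type_cost[faller_type]) +
    (ma_count - ma_hospitalised) * cp$ma_fall_cost +
    ma_hospitalised * cp$hospitalised_ma_fall_cost

  ip <- params$intervention_params
  pw_idx <- list(R = intervention == "R", P = intervention == "P",
                 SR = intervention == "SR")
  int_cost <- function(field) {
    v <- numeric(n)
    for (pw in c("R", "P", "SR")) v[pw_idx[[pw]]] <- ip[[pw]][[field]]
    v
  }
  int_public <- int_cost("public_cost")
  prod_scale <- pmax(0, 1 - cp$productivity_frailty_decline * cohort$frailty)
  out <- list(
    utility = utility,
    cost_public_allcause = allcause_base + fall_cost + int_public,
    cost_public_fall = fall_cost,
    oop_expenditure = cp$oop_base + cp$oop_frailty_slope * cohort$frailty,
    productivity_paid = pmax(0, cp$productivity_paid_base -
      cp$productivity_paid_age_decline * (cohort$age - 60)) * prod_scale,
    productivity_unpaid = cp$productivity_unpaid_base * prod_scale,
    informal_care = cp$informal_care_frailty_slope * cohort$frailty,
    intervention_public = int_public,
    intervention_copay = int_cost("copayment"),
    intervention_participant_time = int_cost("participant_time_cost"),
    intervention_caregiver_time = int_cost("caregiver_time_cost")
  )
  structure(out, class = "data.frame", row.names = c(NA_integer_, -n))
}

# outcome accumulator column names shared by summaries and writers
outcome_columns <- function() {
  c("qalys", "cost_public_allcause", "cost_public_fall", "oop_expenditure",
    "productivity_paid", "productivity_unpaid", "informal_care",
    "intervention_public", "intervention_copay",
    "intervention_participant_time", "intervention_caregiver_time")
}

#' Run one strategy through the annual-cycle microsimulation
#'
#' Simulates a baseline cohort of community-dwelling adults aged 60+ plus
#' one entry cohort of 60-year-olds per cycle over the horizon. Within each
#' cycle the event order is: intervention assignment, mortality (fatal fall
#' then other-cause), nonfatal fall classification for survivors, outcome
#' accrual discounted to the cycle index, frailty and time-varying updates,
#' and LTC admission. Death and LTC admission are absorbing exits. All event
#' draws are keyed by `(master_seed, cycle, event)` and person id, so runs
#' of different strategies under the same master seed use common random
#' numbers: a null intervention (relative risk 1, zero costs) yields
#' bit-identical summaries across all strategies.
#'
#' @param params an `fp_parameters` object.
#' @param config an `fp_strategy_config`, or a strategy name.
#' @param population_spec list with `n_baseline` (default 20000) and
#'   `n_entry` (per-cycle entry cohort size, default 3% of `n_baseline`).
#' @param master_seed integer master seed.
#' @param horizon number of annual cycles (default from `params`).
#' @return an object of class `fp_strategy_summary`: a data.frame with one
#'   row per SES quartile (`Q1`–`Q4`) plus a `total` row, columns `strategy`,
#'   `group`, `persons` and the discounted outcome totals
#'   `r paste(outcome_columns(), collapse = ", ")`.
#' @export
#' @examples
#' p <- build_default_parameters()
#' s <- run_strategy(p, "UC", list(n_baseline = 500, n_entry = 15), master_seed = 1)
#' s[s$group == "total", c("persons", "qalys")]
run_strategy <- function(params, config, population_spec = NULL,
                         master_seed = 1L, horizon = NULL) {
  validate_parameters(params)
  if (is.character(config)) config <- strategy_config(config, params)
  stopifnot(inherits(config, "fp_strategy_config"))
  if (is.null(horizon)) horizon <- params$economics$horizon
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (is.null(population_spec)) population_spec <- list()
  nb <- population_spec$n_baseline %||% 20000
  ne <- population_spec$n_entry %||% round(0.03 * nb)

  cohorts <- vector("list", horizon)
  cohorts[[1]] <- generate_baseline_cohort(nb, params, stream_seed(master_seed, "baseline"))
  if (horizon > 1 && ne > 0) {
    for (cyc in seq_len(horizon - 1)) {
      cohorts[[cyc + 1]] <- generate_entry_cohort(
        cyc, ne, params, stream_seed(master_seed, "entry", cyc))
    }
  }
  ind <- do.call(rbind, lapply(cohorts[!vapply(cohorts, is.null, logical(1))],
                               as.data.frame))
  n <- nrow(ind)
  ind$id <- seq_len(n)
  ses <- ind$ses_quartile
  # plain list of columns: cheap single-column updates inside the cycle loop
  ind <- as.list(ind)

  acc <- matrix(0, nrow = n, ncol = length(outcome_columns()),
                dimnames = list(NULL, outcome_columns()))
  prev_ma <- integer(n)
  effect_rr <- rep(1, n)
  effect_left <- integer(n)
  rate <- params$economics$discount_rate
  state_cols <- c("id", "age", "sex", "ses_quartile", "falls_history", "frailty",
                  "physical_activity", "cognitive_impairment", "fear_of_falling",
                  "abnormal_gait_balance")

  for (t in 0:(horizon - 1)) {
    # persons present by cycle t occupy the contiguous id window 1..k
    # (baseline cohort first, then entry cohorts in cycle order), so event
    # draws of length k stay id-aligned across strategies
    k <- min(n, nb + t * ne)
    aw <- which(ind$alive[1:k] & !ind$in_ltc[1:k])
    if (!length(aw)) break
    # one block of uniforms per cycle; each event owns a fixed slot of k
    # values, so draws remain keyed by (master seed, cycle, event, person id)
    events <- c("gp", "supply_R", "demand_R", "supply_P", "demand_P",
                "supply_SR", "demand_SR", "fatal_fall", "other_mortality",
                "fall", "faller_type", "ma_count", "hosp", "cognitive",
                "fear", "gait", "activity", "ltc")
    ublock <- stream_runif(length(events) * k, master_seed, "cycle", t)
    udraw <- function(event) {
      off <- (match(event, events) - 1L) * k
      ublock[off + aw]
    }
    df <- (1 + rate)^(-t)
    act <- lapply(ind[state_cols], function(v) v[aw])

    # 1. intervention assignment
    u_int <- list(gp = udraw("gp"))
    for (pw in c("R", "P", "SR")) {
      u_int[[paste0("supply_", pw)]] <- udraw(paste0("supply_", pw))
      u_int[[paste0("demand_", pw)]] <- udraw(paste0("demand_", pw))
    }
    received <- assign_intervention(act, config, params, prev_ma[aw], u_int)
    for (pw in c("R", "P", "SR")) {
      sel <- aw[received == pw]
      if (!length(sel)) next
      effect_rr[sel] <- params$intervention_params[[pw]]$relative_risk
      effect_left[sel] <- params$intervention_params[[pw]]$effect_duration
    }

    # 2. mortality
    mort <- mortality_step(act, params, list(fatal = udraw("fatal_fall"),
                                             other = udraw("other_mortality")))
    ind$alive[aw[mort$died]] <- FALSE
    sl <- !mort$died          # survivors, local index within act
    sv <- aw[sl]              # survivors, global index

    # 3. nonfatal fall classification for survivors
    eff <- rep(1, length(aw))
    on_effect <- effect_left[aw] > 0L
    eff[on_effect] <- effect_rr[aw][on_effect]
    p_fall <- fall_probability(act, params, eff)
    fell <- sl & udraw("fall") < p_fall
    fallcls <- classify_faller(fell, params, list(
      type = udraw("faller_type"), count = udraw("ma_count"), hosp = udraw("hosp")))
    ftype <- fallcls$type
    hosp <- fallcls$hospitalised
    ma_n <- fallcls$ma_count

    # 4. outcome accrual (survivors only; the dead accrue nothing this cycle)
    out <- cycle_outcomes(act, ftype, ma_n, hosp, params, received)
    acc[sv, "qalys"] <- acc[sv, "qalys"] + df * out$utility[sl]
    for (col in outcome_columns()[-1])
      acc[sv, col] <- acc[sv, col] + df * out[[col]][sl]

    # 5. frailty and time-varying updates
    new_frailty <- update_frailty(act, ftype, params)
    ind$frailty[sv] <- new_frailty[sl]
    act$frailty <- new_frailty
    upd <- update_time_varying(act, ftype, params, list(
      cognitive = udraw("cognitive"), fear = udraw("fear"),
      gait = udraw("gait"), activity = udraw("activity")))
    for (col in c("falls_history", "cognitive_impairment", "fear_of_falling",
                  "abnormal_gait_balance", "physical_activity", "age"))
      ind[[col]][sv] <- upd[[col]][sl]

    # 6. LTC admission (absorbing exit at end of cycle)
    admitted <- sl & ltc_admission(upd, params, udraw("ltc"))
    ind$in_ltc[aw[admitted]] <- TRUE

    prev_ma <- integer(n)
    prev_ma[sv] <- ma_n[sl]
    effect_left <- pmax(0L, effect_left - 1L)
  }

  groups <- paste0("Q", 1:4)
  per_q <- t(vapply(1:4, function(g) colSums(acc[ses == g, , drop = FALSE]),
                    numeric(ncol(acc))))
  persons <- tabulate(ses, nbins = 4)
  summary <- data.frame(
    strategy = config$name,
    group = c(groups, "total"),
    persons = c(persons, sum(persons)),
    rbind(per_q, colSums(per_q)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  attr(summary, "master_seed") <- as.integer(master_seed)
  attr(summary, "horizon") <- as.integer(horizon)
  class(summary) <- c("fp_strategy_summary", "data.frame")
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run several strategies under common random numbers
#'
#' @inheritParams run_strategy
#' @param strategy_names character vector of strategy names (default all
#'   eight).
#' @return a single `fp_strategy_summary` data.frame with all strategies
#'   stacked.
#' @export
run_strategies <- function(params, strategy_names = strategies(),
                           population_spec = NULL, master_seed = 1L,
                           horizon = NULL) {
  out <- lapply(strategy_names, function(s)
    run_strategy(params, strategy_config(s, params), population_spec,
                 master_seed, horizon))
  res <- do.call(rbind, lapply(out, as.data.frame))
  class(res) <- c("fp_strategy_summary", "data.frame")
  res
}
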