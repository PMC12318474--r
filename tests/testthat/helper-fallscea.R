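# Shared fixtures, built in code.

# Parameters with every intervention neutral: relative risk 1, zero costs.
null_intervention_params <- function(params = build_default_parameters()) {
  for (pw in c("R", "P", "SR")) {
    params$intervention_params[[pw]]$relative_risk <- 1
    for (f in c("public_cost", "copayment", "participant_time_cost",
                "caregiver_time_cost"))
      params$intervention_params[[pw]][[f]] <- 0
  }
  params
}

# Parameters with all stochastic events switched off and utility pinned at 1:
# survivors accrue exactly one QALY per cycle, so person-years are exact.
zero_event_params <- function(params = build_default_parameters(),
                              discount_rate = 0) {
  params$fall_risk_coefficients[] <- 0
  params$fall_risk_coefficients[["intercept"]] <- -50
  params$fatal_fall_params[["base_prob"]] <- 1e-12
  params$fatal_fall_params[["age_slope"]] <- 0
  params$fatal_fall_params[["frailty_slope"]] <- 0
  params$other_cause_mortality_params[["base_prob_male"]] <- 0
  params$other_cause_mortality_params[["base_prob_female"]] <- 0
  params$ltc_admission_params[["intercept"]] <- -50
  params$ltc_admission_params[["age_slope"]] <- 0
  params$ltc_admission_params[["frailty_slope"]] <- 0
  params$utility_params$baseline_60 <- 1
  params$utility_params$age_decrement <- 0
  params$utility_params$female_decrement <- 0
  params$utility_params$frailty_decrement <- 0
  params$utility_params$acute_loss[] <- 0
  params$utility_params$hospitalised_loss <- 0
  params$ses_gradients$utility <- rep(1, 4)
  params$cost_params$allcause_base <- 0
  params$cost_params$allcause_age_slope <- 0
  params$cost_params$allcause_frailty_slope <- 0
  params$cost_params$fall_cost[] <- 0
  params$cost_params$ma_fall_cost <- 0
  params$cost_params$hospitalised_ma_fall_cost <- 0
  params$cost_params$oop_base <- 0
  params$cost_params$oop_frailty_slope <- 0
  params$cost_params$productivity_paid_base <- 0
  params$cost_params$productivity_unpaid_base <- 0
  params$cost_params$informal_care_frailty_slope <- 0
  params$economics$discount_rate <- discount_rate
  null_intervention_params(params)
}

# A tiny hand-built cohort with controllable characteristics.
make_cohort <- function(n = 1, age = 70, sex = "female", ses = 1,
                        falls_history = 0L, frailty = 20,
                        physical_activity = "high", cognitive = 0L,
                        fear = 0L, gait = 0L, entry_year = 0L) {
  data.frame(
    id = seq_len(n), age = rep_len(age, n), sex = rep_len(sex, n),
    ses_quartile = rep_len(ses, n), falls_history = rep_len(falls_history, n),
    frailty = rep_len(frailty, n),
    physical_activity = rep_len(physical_activity, n),
    cognitive_impairment = rep_len(cognitive, n),
    fear_of_falling = rep_len(fear, n),
    abnormal_gait_balance = rep_len(gait, n),
    alive = TRUE, in_ltc = FALSE, entry_year = rep_len(entry_year, n),
    stringsAsFactors = FALSE
  )
}

# Exhaustive pair/mixture dominance oracle, independent of the frontier
# algorithm: strong dominance by pairwise comparison, extended dominance by
# testing every two-strategy mixture at the candidate's cost.
oracle_frontier <- function(pts) {
  n <- nrow(pts)
  strong <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (pts$public_cost[j] <= pts$public_cost[i] &&
          pts$societal_qalys[j] >= pts$societal_qalys[i] &&
          (pts$public_cost[j] < pts$public_cost[i] ||
           pts$societal_qalys[j] > pts$societal_qalys[i])) {
        strong[i] <- TRUE
        break
      }
    }
  }
  extended <- logical(n)
  for (i in which(!strong)) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == i || b == i || a == b) next
        ca <- pts$public_cost[a]; cb <- pts$public_cost[b]
        if (!(ca <= pts$public_cost[i] && pts$public_cost[i] <= cb && cb > ca)) next
        lam <- (pts$public_cost[i] - ca) / (cb - ca)
        qmix <- (1 - lam) * pts$societal_qalys[a] + lam * pts$societal_qalys[b]
        if (qmix > pts$societal_qalys[i] + 1e-9) { extended[i] <- TRUE; break }
      }
      if (extended[i]) break
    }
  }
  cls <- rep("on-frontier", n)
  cls[extended] <- "extendedly dominated"
  cls[strong] <- "strongly dominated"
  data.frame(strategy = pts$strategy, classification = cls,
             stringsAsFactors = FALSE)
}

table1_points <- function() {
  tab <- read_table1()
  data.frame(strategy = tab$strategy,
             public_cost = tab$incremental_public_cost,
             societal_qalys = tab$incremental_societal_qaly,
             stringsAsFactors = FALSE)
}
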