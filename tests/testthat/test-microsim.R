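test_that("discount factors follow (1 + r)^(-t) with cycle 0 undiscounted", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(7, 0), 1)
  expect_equal(discount_factor(2, 0.035), 1 / 1.035^2)
  expect_error(discount_factor(-1, 0.035), "cycle")
})

test_that("fall probability evaluates the logistic risk model", {
  p <- build_default_parameters()
  p$fall_risk_coefficients[] <- 0
  p$ses_gradients$fall_odds <- rep(1, 4)
  person <- make_cohort(1)
  expect_equal(fall_probability(person, p), 0.5)
  # direct evaluation: logistic(-1 + 0.8 * 50/100)
  p$fall_risk_coefficients[["intercept"]] <- -1
  p$fall_risk_coefficients[["frailty"]] <- 0.8
  person$frailty <- 50
  expect_equal(fall_probability(person, p), stats::plogis(-0.6), tolerance = 1e-12)
  # a protective effect strictly lowers the probability, monotonically
  p_full <- fall_probability(person, p, active_effect = 1)
  p_half <- fall_probability(person, p, active_effect = 0.5)
  expect_lt(p_half, p_full)
  expect_equal(p_half / (1 - p_half), 0.5 * p_full / (1 - p_full), tolerance = 1e-12)
  expect_error(fall_probability(person, p, active_effect = 1.2), "0, 1")
})

test_that("faller classification respects the mixture and the hospitalisation rate", {
  p <- build_default_parameters()
  out <- classify_faller(c(FALSE, FALSE), p)
  expect_identical(out$type, c("no_fall", "no_fall"))
  expect_identical(out$ma_count, c(0L, 0L))
  # degenerate split
  p1 <- p
  p1$faller_type_split[] <- 0
  p1$faller_type_split[["single_non_ma"]] <- 1
  out1 <- classify_faller(rep(TRUE, 200), p1)
  expect_true(all(out1$type == "single_non_ma"))
  expect_true(all(out1$hospitalised == 0L))
  # invalid split is a configuration error
  p2 <- p
  p2$faller_type_split[["single_ma"]] <- 0.5
  expect_error(classify_faller(TRUE, p2), "sum to 1")
  # hospitalisation frequency of single MA falls: 28% within 3 standard errors
  p3 <- p
  p3$faller_type_split[] <- 0
  p3$faller_type_split[["single_ma"]] <- 1
  n <- 100000
  out3 <- classify_faller(rep(TRUE, n), p3,
                          u = list(type = rep(0.5, n),
                                   count = stream_runif(n, 1, "count") ,
                                   hosp = stream_runif(n, 1, "hosp")))
  freq <- mean(out3$hospitalised)
  se <- sqrt(0.28 * 0.72 / n)
  expect_lt(abs(freq - 0.28), 3 * se)
})

test_that("mortality combines fatal falls and the other-cause schedule", {
  p <- zero_event_params()
  person <- make_cohort(3)
  out <- mortality_step(person, p)
  expect_false(any(out$died))
  # forced other-cause death via explicit uniforms below the schedule value
  p2 <- build_default_parameters()
  p2$other_cause_mortality_params[["base_prob_female"]] <- 0.99
  p2$other_cause_mortality_params[["age_log_slope"]] <- 0
  out2 <- mortality_step(make_cohort(1, age = 60, frailty = 0), p2,
                         u = list(fatal = 0.999, other = 0.5))
  expect_true(out2$died)
  expect_identical(out2$cause, "other")
  # closed-form combination 1 - (1 - p_fatal)(1 - q) at n = 100000
  p3 <- build_default_parameters()
  p3$ses_gradients$mortality <- rep(1, 4)
  cohort <- make_cohort(100000, age = 70, sex = "male", frailty = 20)
  fp <- p3$fatal_fall_params
  p_fatal <- stats::plogis(stats::qlogis(fp[["base_prob"]]) +
    fp[["age_slope"]] * 10 + fp[["frailty_slope"]] * 0.2)
  oc <- p3$other_cause_mortality_params
  q <- oc[["base_prob_male"]] * exp(oc[["age_log_slope"]] * 10) * 1.2
  expected <- 1 - (1 - p_fatal) * (1 - q)
  out3 <- mortality_step(cohort, p3,
                         u = list(fatal = stream_runif(100000, 2, "f"),
                                  other = stream_runif(100000, 2, "o")))
  se <- sqrt(expected * (1 - expected) / 100000)
  expect_lt(abs(mean(out3$died) - expected), 3 * se)
})

test_that("frailty progression adds age-band and faller increments, clamped", {
  p <- build_default_parameters()
  p$frailty_progression$base_by_age[] <- 0
  p$frailty_progression$faller_increment[] <- 0
  person <- make_cohort(1, frailty = 37.5)
  expect_equal(update_frailty(person, "no_fall", p), 37.5)
  # arithmetic: (0.8 + 1.2) * 1.2 = +2.4
  p$frailty_progression$base_by_age[] <- 0.8
  p$frailty_progression$faller_increment[["recurrent_ma"]] <- 1.2
  expect_equal(update_frailty(person, "recurrent_ma", p, scenario_multiplier = 1.2),
               37.5 + 2.4)
  # clamped at 100
  person$frailty <- 99.5
  expect_equal(update_frailty(person, "recurrent_ma", p), 100)
})

test_that("time-varying updates set falls history, age, and absorbing states", {
  p <- build_default_parameters()
  p$cognitive_impairment_incidence[c("base_prob", "age_slope", "frailty_slope")] <-
    c(1e-12, 0, 0)
  p$fear_of_falling_onset[] <- 0
  p$gait_balance_onset[c("base_prob", "frailty_slope")] <- c(1e-12, 0)
  p$activity_transition[] <- c(1e-12, 0, 0)
  person <- make_cohort(1, age = 70)
  upd <- update_time_varying(person, "single_ma", p)
  expect_identical(upd$falls_history, 1L)
  expect_equal(upd$age, 71)
  expect_identical(upd$cognitive_impairment, 0L)
  upd2 <- update_time_varying(person, "no_fall", p)
  expect_identical(upd2$falls_history, 0L)
  # cognitive incidence scales with the scenario multiplier: 0.05 * 1.2
  p2 <- build_default_parameters()
  p2$cognitive_impairment_incidence[] <- c(0.05, 0, 0, 1.2)
  n <- 100000
  cohort <- make_cohort(n, cognitive = 0L)
  upd3 <- update_time_varying(cohort, rep("no_fall", n), p2,
    u = list(cognitive = stream_runif(n, 3, "c"), fear = stream_runif(n, 3, "f"),
             gait = stream_runif(n, 3, "g"), activity = stream_runif(n, 3, "a")))
  se <- sqrt(0.06 * 0.94 / n)
  expect_lt(abs(mean(upd3$cognitive_impairment) - 0.06), 3 * se)
})

test_that("LTC admission is logistic and monotone in frailty", {
  p <- build_default_parameters()
  p$ltc_admission_params[["intercept"]] <- -50
  expect_false(any(ltc_admission(make_cohort(100), p)))
  p$ltc_admission_params[["intercept"]] <- 50
  expect_true(all(ltc_admission(make_cohort(100), p)))
  # with a positive frailty slope the same uniform admits the frailer person
  # but not the fitter one
  p2 <- build_default_parameters()
  frail <- make_cohort(1, frailty = 80)
  fit <- make_cohort(1, frailty = 10)
  u_mid <- 0.005 # between the two admission probabilities
  expect_true(ltc_admission(frail, p2, u = u_mid))
  expect_false(ltc_admission(fit, p2, u = u_mid))
})

test_that("pathway eligibility rules match their definitions", {
  p <- build_default_parameters()
  # reactive: an MA fall in the immediately preceding cycle
  expect_true(eligible_reactive(1L))
  expect_true(eligible_reactive(2L))
  expect_false(eligible_reactive(0L))
  # proactive: GP contact and positive screen (conjunction by default)
  pos <- make_cohort(1, falls_history = 1L, gait = 1L)
  neg_gait <- make_cohort(1, falls_history = 1L, gait = 0L)
  p_open <- p
  p_open$access_params$gp_access_rate <- 1
  p_open$ses_gradients$gp_access <- rep(1, 4)
  expect_true(eligible_proactive(pos, p_open, u_gp = 0.99))
  expect_false(eligible_proactive(neg_gait, p_open, u_gp = 0.99))
  p_closed <- p
  p_closed$access_params$gp_access_rate <- 0
  expect_false(eligible_proactive(pos, p_closed, u_gp = 0.001))
  # disjunctive screening is a configuration switch
  p_or <- p_open
  p_or$proactive_screen_rule <- "or"
  expect_true(eligible_proactive(neg_gait, p_or, u_gp = 0.99))
  # self-referral is open to every community-dwelling person
  expect_true(all(eligible_self_referred(make_cohort(5))))
})

test_that("intervention assignment enforces precedence and access draws", {
  p <- build_default_parameters()
  cfg <- strategy_config("RC", p)
  person <- make_cohort(1, falls_history = 1L, gait = 1L)
  u_yes <- list(gp = 0, supply_R = 0, demand_R = 0, supply_P = 0, demand_P = 0,
                supply_SR = 0, demand_SR = 0)
  # eligible for R (previous MA fall), P and SR with certain access: R wins
  expect_identical(assign_intervention(person, cfg, p, prev_ma_count = 1L, u_yes), "R")
  # not reactive-eligible: P beats SR
  expect_identical(assign_intervention(person, cfg, p, prev_ma_count = 0L, u_yes), "P")
  # zero demand everywhere yields no receipt
  cfg0 <- cfg
  cfg0$demand[] <- 0
  expect_identical(assign_intervention(person, cfg0, p, prev_ma_count = 1L), "none")
  # long-run receipt frequency under usual care: eligibility x supply x demand
  p_sr <- p
  p_sr$access_params$gp_access_rate <- 0 # closes the proactive pathway
  cfg_uc <- strategy_config("UC", p_sr)
  n <- 50000
  cohort <- make_cohort(n, falls_history = 0L, gait = 0L)
  set.seed(42)
  received <- assign_intervention(cohort, cfg_uc, p_sr, prev_ma_count = integer(n))
  target <- p$access_params$supply$usual[["SR"]] * p$access_params$demand$usual[["SR"]]
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(received == "SR") - target), 3 * se)
  expect_true(all(received %in% c("none", "SR")))
})

test_that("cycle outcomes compose utility and cost components", {
  p <- zero_event_params(discount_rate = 0.035)
  person <- make_cohort(1, age = 70, frailty = 25, ses = 2)
  # utility arithmetic: 0.8 base - 0.1 frailty decrement - 0.05 acute loss
  p$utility_params$baseline_60 <- 0.8
  p$utility_params$frailty_decrement <- 0.004 # x 25 = 0.1
  p$utility_params$acute_loss[["single_ma"]] <- 0.05
  out <- cycle_outcomes(person, "single_ma", 1L, 0L, p)
  expect_equal(out$utility, 0.65)
  # no fall, no intervention, zero base cost: zero public cost
  out0 <- cycle_outcomes(person, "no_fall", 0L, 0L, p)
  expect_equal(out0$cost_public_allcause, 0)
  expect_equal(out0$cost_public_fall, 0)
  # a hospitalised MA fall carries the configured hip-fracture cost
  p$cost_params$hospitalised_ma_fall_cost <- 13000
  out1 <- cycle_outcomes(person, "single_ma", 1L, 1L, p)
  expect_equal(out1$cost_public_fall, 13000)
  expect_equal(out1$cost_public_allcause, 13000)
  # intervention costs land in their payer columns
  p$intervention_params$R$public_cost <- 600
  p$intervention_params$R$copayment <- 20
  out2 <- cycle_outcomes(person, "no_fall", 0L, 0L, p, intervention = "R")
  expect_equal(out2$intervention_public, 600)
  expect_equal(out2$intervention_copay, 20)
  expect_equal(out2$cost_public_allcause, 600)
})

test_that("a riskless closed cohort accrues exact person-years", {
  p <- zero_event_params()
  pop <- list(n_baseline = 100, n_entry = 0)
  s <- run_strategy(p, "UC", pop, master_seed = 1, horizon = 3)
  tot <- s[s$group == "total", ]
  expect_equal(tot$qalys, 300)
  expect_equal(tot$cost_public_allcause, 0)
  # discounting turns each person-year stream into an annuity
  p2 <- zero_event_params(discount_rate = 0.035)
  s2 <- run_strategy(p2, "UC", pop, master_seed = 1, horizon = 3)
  expect_equal(s2$qalys[s2$group == "total"],
               100 * (1 + 1.035^-1 + 1.035^-2), tolerance = 1e-9)
})

test_that("exits are absorbing: nothing accrues after LTC admission", {
  p <- zero_event_params()
  p$ltc_admission_params[["intercept"]] <- 50 # certain admission at cycle end
  s <- run_strategy(p, "UC", list(n_baseline = 80, n_entry = 0),
                    master_seed = 1, horizon = 5)
  # everyone exits after the first cycle: exactly one QALY each
  expect_equal(s$qalys[s$group == "total"], 80)
})

test_that("summaries are deterministic and conserve quartile accounting", {
  p <- build_default_parameters()
  pop <- list(n_baseline = 600, n_entry = 20)
  a <- run_strategy(p, "R", pop, master_seed = 7, horizon = 12)
  b <- run_strategy(p, "R", pop, master_seed = 7, horizon = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_strategy(p, "R", pop, master_seed = 8, horizon = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  tot <- a[a$group == "total", ]
  qs <- a[a$group != "total", ]
  for (col in c("persons", fallscea:::outcome_columns())) {
    expect_equal(sum(qs[[col]]), tot[[col]], tolerance = 1e-6 * max(1, abs(tot[[col]])),
                 label = paste("column", col))
  }
  # fall-related public cost is contained in the all-cause total
  expect_true(all(a$cost_public_fall <= a$cost_public_allcause))
})

test_that("strategy configurations validate their shape", {
  p <- build_default_parameters()
  rc <- strategy_config("RC", p)
  expect_true(all(rc$levels == "recommended"))
  expect_true(all(rc$supply == 1))
  uc <- strategy_config("UC", p)
  expect_true(all(uc$levels == "usual"))
  rsr <- strategy_config("R+SR", p)
  expect_identical(unname(rsr$levels), c("recommended", "usual", "recommended"))
  expect_error(strategy_config("XX", p))
})
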