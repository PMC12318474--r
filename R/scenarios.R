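#' Names of the alternative scenarios
#'
#' The main (base) scenario plus plus/minus 20% variations of baseline
#' frailty, frailty progression rate, cognitive impairment incidence,
#' intervention demand at the recommended level (usual-care rates are never
#' altered), and the GP access rate.
#'
#' @return character vector of valid scenario names.
#' @export
scenario_names <- function() {
  c("main",
    "frailty_baseline_up20", "frailty_baseline_down20",
    "frailty_progression_up20", "frailty_progression_down20",
    "cognitive_incidence_up20", "cognitive_incidence_down20",
    "demand_up20", "demand_down20",
    "gp_access_up20", "gp_access_down20")
}

#' Apply a named scenario to a parameter set
#'
#' Returns a modified copy; the input is never mutated. `frailty_baseline`
#' scales each individual's baseline frailty draw (clamped to \[0, 100\] at
#' draw time); `frailty_progression` scales the annual increments;
#' `cognitive_incidence` scales the annual incidence probability (capped at
#' 1); `demand` scales recommended-level demand only; `gp_access` scales
#' the GP access rate (capped at 1); `main` is the identity.
#'
#' @param params an `fp_parameters` object.
#' @param scenario one of [scenario_names()].
#' @return a modified `fp_parameters` object.
#' @export
#' @examples
#' p <- apply_scenario(build_default_parameters(), "demand_up20")
#' p$access_params$demand$usual # unchanged
apply_scenario <- function(params, scenario) {
  if (!scenario %in% scenario_names())
    stop("unknown scenario '", scenario, "'; valid names: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  if (scenario == "main") return(params)
  mult <- if (grepl("up20$", scenario)) 1.2 else 0.8
  out <- unclass(params)
  if (grepl("^frailty_baseline", scenario)) {
    out$cohort_params$baseline_frailty_multiplier <-
      out$cohort_params$baseline_frailty_multiplier * mult
  } else if (grepl("^frailty_progression", scenario)) {
    out$frailty_progression$base_by_age <- out$frailty_progression$base_by_age * mult
    out$frailty_progression$faller_increment <-
      out$frailty_progression$faller_increment * mult
  } else if (grepl("^cognitive_incidence", scenario)) {
    out$cognitive_impairment_incidence[["multiplier"]] <-
      out$cognitive_impairment_incidence[["multiplier"]] * mult
  } else if (grepl("^demand", scenario)) {
    d <- out$access_params$demand$recommended
    d[] <- pmin(1, d * mult)
    out$access_params$demand$recommended <- d
  } else if (grepl("^gp_access", scenario)) {
    out$access_params$gp_access_rate <-
      min(1, out$access_params$gp_access_rate * mult)
  }
  class(out) <- c("fp_parameters", "list")
  validate_parameters(out)
  out
}

#' Deterministic multi-seed scenario run
#'
#' Runs every strategy at point-estimate parameters (after applying the
#' scenario) under each of `n_seeds` seeds — common random numbers within a
#' seed — and averages the summaries across seeds to integrate out
#' first-order (individual-level) variability. CEA and DCEA outputs are
#' produced from the averaged summaries.
#'
#' @param params an `fp_parameters` object (point estimates).
#' @param scenario one of [scenario_names()].
#' @param strategy_names strategies to run (default all eight).
#' @param n_seeds number of seeds to average over (default 10).
#' @param population_spec passed to [run_strategy()].
#' @param master_seed master seed from which the per-seed streams are
#'   derived; scenario runs reuse the same seed list as the main scenario.
#' @param horizon cycles per run (default from `params`).
#' @param dcea_args optional list of overrides passed to [dcea_table()].
#' @return list with `scenario`, `summaries` (seed-averaged
#'   `fp_strategy_summary`), `points`, `cea` (dominance frontier) and
#'   `dcea` (an `fp_dcea_table`).
#' @export
deterministic_scenario_run <- function(params, scenario = "main",
                                       strategy_names = strategies(),
                                       n_seeds = 10, population_spec = NULL,
                                       master_seed = 1L, horizon = NULL,
                                       dcea_args = list()) {
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  sp <- apply_scenario(params, scenario)
  seeds <- vapply(seq_len(n_seeds), function(i) stream_seed(master_seed, "seed", i),
                  integer(1))
  all_runs <- do.call(rbind, lapply(seeds, function(s)
    as.data.frame(run_strategies(sp, strategy_names, population_spec, s, horizon))))
  cols <- c("persons", outcome_columns())
  avg <- stats::aggregate(all_runs[cols], by = all_runs[c("strategy", "group")],
                          FUN = mean)
  avg <- avg[order(match(avg$strategy, strategy_names),
                   match(avg$group, c(paste0("Q", 1:4), "total"))), ]
  rownames(avg) <- NULL
  class(avg) <- c("fp_strategy_summary", "data.frame")

  lambda_soc <- sp$economics$societal_threshold
  pts <- strategy_points(avg, lambda_soc)
  cea <- dominance_frontier(pts[c("strategy", "public_cost", "societal_qalys")])
  dcea <- do.call(dcea_table, c(
    list(summaries = avg),
    utils::modifyList(list(lambda_pub = sp$economics$public_thresholds,
                           lambda_soc = lambda_soc), dcea_args)))
  list(scenario = scenario, seeds = seeds, summaries = avg, points = pts,
       cea = cea, dcea = dcea)
}
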