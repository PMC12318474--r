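#' Run the probabilistic sensitivity analysis
#'
#' For each run, one parameter set is drawn from the PSA distributions and
#' every strategy is simulated under common random numbers within the run
#' (the simulation master seed is shared across strategies of a run, so
#' incremental comparisons are paired). The whole analysis is a pure
#' function of `master_seed`.
#'
#' @param base_params point-estimate parameter set.
#' @param spec an `fp_psa_spec`; see [default_psa_spec()].
#' @param strategy_names strategies to simulate (default all eight).
#' @param n_runs number of PSA runs (the source analysis used 800; smaller
#'   values are appropriate for scaled-down runs).
#' @param master_seed integer master seed.
#' @param population_spec passed to [run_strategy()]; PSA runs are usually
#'   scaled down relative to deterministic runs.
#' @param horizon cycles per run (default from `base_params`).
#' @return an object of class `fp_psa_result`: list with `runs` (data.frame
#'   stacking every run x strategy x group summary row, with `run` and
#'   `seed` columns), `lambda_soc`, and `n_runs`.
#' @export
run_psa <- function(base_params, spec = default_psa_spec(base_params),
                    strategy_names = strategies(), n_runs = 800,
                    master_seed = 1L, population_spec = NULL, horizon = NULL) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  runs <- vector("list", n_runs)
  # individual-level (first-order) noise is held fixed across runs and
  # strategies, so run-to-run variation reflects parameter uncertainty only
  sim_seed <- stream_seed(master_seed, "psa_sim")
  for (r in seq_len(n_runs)) {
    param_seed <- stream_seed(master_seed, "psa_param", r)
    params_r <- sample_psa_parameters(spec, base_params, param_seed)
    summ <- run_strategies(params_r, strategy_names, population_spec,
                           sim_seed, horizon)
    summ$run <- r
    summ$seed <- param_seed
    runs[[r]] <- as.data.frame(summ)
  }
  out <- list(
    runs = do.call(rbind, runs),
    lambda_soc = base_params$economics$societal_threshold,
    n_runs = n_runs,
    strategies = strategy_names
  )
  class(out) <- "fp_psa_result"
  out
}

#' @export
print.fp_psa_result <- function(x, ...) {
  cat("<fp_psa_result>", x$n_runs, "runs x", length(x$strategies), "strategies\n")
  invisible(x)
}

#' Expected (mean) outcomes across PSA runs
#'
#' Arithmetic mean of every outcome field across runs, per strategy and
#' group; the probabilistic point estimates reported by the analysis.
#'
#' @param psa an `fp_psa_result`.
#' @return an `fp_strategy_summary` data.frame of means (persons included).
#' @export
expected_outcomes <- function(psa) {
  runs <- psa$runs
  cols <- c("persons", outcome_columns())
  agg <- stats::aggregate(runs[cols], by = runs[c("strategy", "group")], FUN = mean)
  agg <- agg[order(match(agg$strategy, psa$strategies),
                   match(agg$group, c(paste0("Q", 1:4), "total"))), ]
  rownames(agg) <- NULL
  class(agg) <- c("fp_strategy_summary", "data.frame")
  agg
}

# per-run strategy points (totals only)
psa_points <- function(psa) {
  runs <- psa$runs
  out <- do.call(rbind, lapply(split(runs, runs$run), function(d) {
    p <- strategy_points(d, psa$lambda_soc)
    p$run <- d$run[1]
    p
  }))
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness acceptability curve and frontier
#'
#' For each run and threshold, the net monetary benefit of strategy *s* is
#' `lambda * societal QALYs_s - public cost_s`. The CEAC gives the fraction
#' of runs in which each strategy attains the maximal NMB (exact ties split
#' equally, so rows sum to one); the CEAF marks, at each threshold, the
#' strategy with the highest expected NMB across runs.
#'
#' @param psa an `fp_psa_result`.
#' @param lambda_grid public thresholds to evaluate, GBP/QALY (default 0 to
#'   50000 in steps of 500).
#' @param lambda_soc societal threshold used for the QALY conversion
#'   (default from the PSA object).
#' @return an object of class `fp_ceac`: data.frame with `lambda`, one
#'   probability column per strategy, and `ceaf` naming the
#'   highest-expected-NMB strategy.
#' @export
ceac_ceaf <- function(psa, lambda_grid = seq(0, 50000, by = 500),
                      lambda_soc = psa$lambda_soc) {
  if (!length(lambda_grid) || any(lambda_grid < 0) || is.unsorted(lambda_grid))
    stop("lambda_grid must be nonempty, non-negative and sorted", call. = FALSE)
  pts <- psa_points(psa)
  strat <- psa$strategies
  qal <- matrix(NA_real_, nrow = psa$n_runs, ncol = length(strat),
                dimnames = list(NULL, strat))
  cost <- qal
  for (s in strat) {
    d <- pts[pts$strategy == s, ]
    qal[d$run, s] <- societal_qalys(d$health_qalys, d$net_nonpublic_cost, lambda_soc)
    cost[d$run, s] <- d$public_cost
  }
  prob <- matrix(0, nrow = length(lambda_grid), ncol = length(strat),
                 dimnames = list(NULL, strat))
  ceaf <- character(length(lambda_grid))
  for (k in seq_along(lambda_grid)) {
    nmb <- lambda_grid[k] * qal - cost
    best <- apply(nmb, 1, max)
    winners <- nmb == best
    prob[k, ] <- colMeans(winners / rowSums(winners))
    ceaf[k] <- strat[which.max(colMeans(nmb))]
  }
  out <- data.frame(lambda = lambda_grid, prob, ceaf,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("fp_ceac", "data.frame")
  out
}

#' Per-run incremental (QALY, cost) scatter against a comparator
#'
#' One pair per run per non-comparator strategy, suitable for the
#' incremental cost-effectiveness plane.
#'
#' @param psa an `fp_psa_result`.
#' @param comparator comparator strategy name (default `"UC"`).
#' @param lambda_soc societal threshold for the QALY conversion.
#' @return data.frame with `run`, `strategy`, `delta_societal_qalys`,
#'   `delta_cost_public`.
#' @export
incremental_scatter <- function(psa, comparator = "UC", lambda_soc = psa$lambda_soc) {
  if (!comparator %in% psa$strategies)
    stop("comparator not found in PSA runs: ", comparator, call. = FALSE)
  pts <- psa_points(psa)
  pts$societal_qalys <- societal_qalys(pts$health_qalys, pts$net_nonpublic_cost,
                                       lambda_soc)
  ref <- pts[pts$strategy == comparator, c("run", "societal_qalys", "public_cost")]
  names(ref) <- c("run", "ref_qalys", "ref_cost")
  oth <- pts[pts$strategy != comparator, ]
  m <- merge(oth, ref, by = "run")
  out <- data.frame(
    run = m$run, strategy = m$strategy,
    delta_societal_qalys = m$societal_qalys - m$ref_qalys,
    delta_cost_public = m$public_cost - m$ref_cost
  )
  out[order(out$run, match(out$strategy, psa$strategies)), ]
}
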