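#' Per-capita societal net health benefit by SES quartile
#'
#' For each quartile g, `NHB_g = (health QALYs_g - net nonpublic cost_g /
#' lambda_soc - public cost_g / lambda_pub) / persons_g`: the quartile's
#' societal QALYs net of the health opportunity cost of its public sector
#' spending, per person.
#'
#' @param summary an `fp_strategy_summary` for one strategy (quartile rows
#'   plus total).
#' @param lambda_pub public threshold, GBP/QALY.
#' @param lambda_soc societal threshold, GBP/QALY.
#' @return data.frame with `strategy`, `ses_quartile`, `persons`,
#'   `nhb_per_capita`.
#' @export
per_capita_nhb_by_quartile <- function(summary, lambda_pub, lambda_soc = 60000) {
  q <- summary[summary$group != "total", ]
  if (any(q$persons <= 0))
    stop("every SES quartile must contain at least one person", call. = FALSE)
  nonpub <- q$oop_expenditure + q$informal_care + q$intervention_copay +
    q$intervention_participant_time + q$intervention_caregiver_time -
    q$productivity_paid - q$productivity_unpaid
  nhb <- (q$qalys - nonpub / lambda_soc - q$cost_public_allcause / lambda_pub) /
    q$persons
  data.frame(
    strategy = q$strategy,
    ses_quartile = as.integer(sub("^Q", "", q$group)),
    persons = q$persons,
    nhb_per_capita = nhb,
    stringsAsFactors = FALSE
  )
}

#' Atkinson equally-distributed-equivalent level
#'
#' The uniform outcome level a social planner with relative inequality
#' aversion `epsilon` deems equivalent to the distribution: the weighted
#' mean at `epsilon = 0`, the weighted geometric mean at `epsilon = 1`, and
#' `(sum w_g x_g^(1 - epsilon))^(1/(1 - epsilon))` otherwise. Requires
#' strictly positive values when `epsilon > 0` (use the Kolm index for
#' distributions with non-positive outcomes).
#'
#' @param values outcome level per group (e.g. per-capita NHB per quartile).
#' @param weights positive group weights summing to 1 (default equal).
#' @param epsilon relative inequality-aversion parameter, `>= 0`.
#' @return the EDE level, a single number.
#' @export
#' @examples
#' atkinson_ede(c(2, 3, 4, 5), epsilon = 0)  # 3.5, the mean
#' atkinson_ede(c(2, 3, 4, 5), epsilon = 2)  # harmonic mean
atkinson_ede <- function(values, weights = rep(1 / length(values), length(values)),
                         epsilon) {
  check_weights(weights, length(values))
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (epsilon == 0) return(sum(weights * values))
  if (any(values <= 0))
    stop("Atkinson EDE requires strictly positive values when epsilon > 0; ",
         "use kolm_ede() for distributions with non-positive outcomes",
         call. = FALSE)
  if (epsilon == 1) return(exp(sum(weights * log(values))))
  # factor out the maximum for numerical stability at large epsilon
  m <- max(values)
  m * sum(weights * (values / m)^(1 - epsilon))^(1 / (1 - epsilon))
}

#' Kolm equally-distributed-equivalent level
#'
#' The uniform level equivalent under absolute inequality aversion `alpha`:
#' `-(1/alpha) * log(sum w_g exp(-alpha x_g))`. Defined for any real
#' values; translation-invariant (adding a constant to all values adds that
#' constant to the EDE).
#'
#' @param values outcome level per group.
#' @param weights positive group weights summing to 1 (default equal).
#' @param alpha absolute inequality-aversion parameter, `> 0`.
#' @return the EDE level, a single number.
#' @export
#' @examples
#' kolm_ede(c(2, 3, 4, 5), alpha = 0.15)
kolm_ede <- function(values, weights = rep(1 / length(values), length(values)),
                     alpha) {
  check_weights(weights, length(values))
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  # shift by the minimum so the exponentials cannot overflow
  m <- min(values)
  m - log(sum(weights * exp(-alpha * (values - m)))) / alpha
}

check_weights <- function(weights, n) {
  if (length(weights) != n || any(weights <= 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be positive, match the number of values and sum to 1",
         call. = FALSE)
  invisible(weights)
}

#' Distributional cost-effectiveness table
#'
#' For every strategy, threshold and inequality-index value, computes the
#' EDE level of per-capita societal NHB across SES quartiles, the
#' incremental EDE NHB against the comparator, and flags the optimal
#' (highest-EDE) strategy per (index, threshold) row.
#'
#' @param summaries stacked `fp_strategy_summary` rows for all strategies.
#' @param lambda_pub public thresholds to evaluate (default 20000 and
#'   30000).
#' @param lambda_soc societal threshold (default 60000).
#' @param epsilon Atkinson index values (default 0, 5, 11, 15, 20, 30; 11
#'   is the relative aversion elicited from the English general public).
#' @param alpha Kolm index values (default 0.15, the elicited absolute
#'   aversion).
#' @param weights quartile weights (default equal quarters).
#' @param comparator comparator strategy (default `"UC"`).
#' @return an object of class `fp_dcea_table`: data.frame with `strategy`,
#'   `lambda_pub`, `index_family` (`"atkinson"`/`"kolm"`), `index_value`,
#'   `ede_nhb`, `ede_inhb`, `optimal`.
#' @export
dcea_table <- function(summaries, lambda_pub = c(20000, 30000),
                       lambda_soc = 60000, epsilon = c(0, 5, 11, 15, 20, 30),
                       alpha = 0.15, weights = rep(0.25, 4), comparator = "UC") {
  strat <- unique(summaries$strategy)
  if (!comparator %in% strat)
    stop("comparator not found: ", comparator, call. = FALSE)
  rows <- list()
  for (lp in lambda_pub) {
    nhb <- lapply(strat, function(s)
      per_capita_nhb_by_quartile(summaries[summaries$strategy == s, ], lp,
                                 lambda_soc)$nhb_per_capita)
    names(nhb) <- strat
    for (family in c("atkinson", "kolm")) {
      idx_values <- if (family == "atkinson") epsilon else alpha
      for (iv in idx_values) {
        ede <- vapply(strat, function(s) {
          if (family == "atkinson") atkinson_ede(nhb[[s]], weights, iv)
          else kolm_ede(nhb[[s]], weights, iv)
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          strategy = strat, lambda_pub = lp, index_family = family,
          index_value = iv, ede_nhb = unname(ede),
          ede_inhb = unname(ede - ede[[comparator]]),
          optimal = seq_along(strat) == which.max(ede),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fp_dcea_table", "data.frame")
  out
}

#' Incremental EDE NHB against a comparator
#'
#' @param ede_by_strategy named numeric vector of EDE NHB levels.
#' @param comparator name of the comparator strategy.
#' @return named vector of `EDE(strategy) - EDE(comparator)`.
#' @export
ede_inhb <- function(ede_by_strategy, comparator) {
  if (!comparator %in% names(ede_by_strategy))
    stop("comparator not found: ", comparator, call. = FALSE)
  ede_by_strategy - ede_by_strategy[[comparator]]
}

#' Optimal strategy per (index value, threshold) row
#'
#' The strategy with the highest EDE level of societal NHB is optimal on
#' both efficiency and equity grounds. Exact ties are broken
#' lexicographically with a warning.
#'
#' @param table an `fp_dcea_table`.
#' @return data.frame with `lambda_pub`, `index_family`, `index_value`,
#'   `optimal_strategy`.
#' @export
optimal_strategy <- function(table) {
  keys <- unique(table[c("lambda_pub", "index_family", "index_value")])
  keys$optimal_strategy <- NA_character_
  for (i in seq_len(nrow(keys))) {
    d <- table[table$lambda_pub == keys$lambda_pub[i] &
               table$index_family == keys$index_family[i] &
               table$index_value == keys$index_value[i], ]
    best <- d$strategy[d$ede_nhb == max(d$ede_nhb)]
    if (length(best) > 1) {
      warning("EDE tie at lambda ", keys$lambda_pub[i], ", ",
              keys$index_family[i], " ", keys$index_value[i],
              "; broken lexicographically", call. = FALSE)
      best <- sort(best)
    }
    keys$optimal_strategy[i] <- best[1]
  }
  rownames(keys) <- NULL
  keys
}

#' Progressivity classification of quartile-level incremental NHB
#'
#' A strategy is unambiguously progressive if its incremental NHB strictly
#' increases from the least to the most deprived quartile, unambiguously
#' regressive if it strictly decreases, and mixed otherwise.
#'
#' @param inhb_by_quartile four values ordered least to most deprived.
#' @return one of `"unambiguously progressive"`,
#'   `"unambiguously regressive"`, `"mixed"`.
#' @export
#' @examples
#' progressivity(c(0.01, 0.02, 0.03, 0.04))
progressivity <- function(inhb_by_quartile) {
  if (length(inhb_by_quartile) != 4)
    stop("expected four quartile values", call. = FALSE)
  d <- diff(inhb_by_quartile)
  if (all(d > 0)) "unambiguously progressive"
  else if (all(d < 0)) "unambiguously regressive"
  else "mixed"
}
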