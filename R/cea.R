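#' Convert health QALYs and nonpublic costs to societal QALYs
#'
#' Net nonpublic cost (out-of-pocket + informal care + copayment + time
#' costs minus productivity value) is converted to its QALY equivalent at
#' the societal threshold and netted off the health QALYs: a nonpublic
#' saving (negative cost) adds QALY equivalents.
#'
#' @param health_qalys health QALYs.
#' @param net_nonpublic_cost net nonpublic cost in GBP (may be negative).
#' @param lambda_soc societal cost-effectiveness threshold, GBP/QALY
#'   (default 60000).
#' @return societal QALYs: `health_qalys - net_nonpublic_cost / lambda_soc`.
#' @export
#' @examples
#' societal_qalys(100, -600000, 60000) # a saving adds 10 QALY equivalents
societal_qalys <- function(health_qalys, net_nonpublic_cost, lambda_soc = 60000) {
  if (any(lambda_soc <= 0)) stop("lambda_soc must be > 0", call. = FALSE)
  health_qalys - net_nonpublic_cost / lambda_soc
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental public sector cost per societal QALY gained, reported to the
#' nearest pound. Callers must screen dominance first: a non-positive QALY
#' gain is an error, not a ratio.
#'
#' @param delta_cost_public incremental public sector cost, GBP.
#' @param delta_societal_qalys incremental societal QALYs (> 0).
#' @return the ICER rounded to the nearest pound.
#' @export
#' @examples
#' icer(5609678, 2371.6) # 2365
icer <- function(delta_cost_public, delta_societal_qalys) {
  if (any(delta_societal_qalys <= 0))
    stop("incremental societal QALYs must be > 0; screen for dominance first",
         call. = FALSE)
  round(delta_cost_public / delta_societal_qalys)
}

#' Incremental net monetary benefit
#'
#' Societal QALY gain valued at the public threshold, minus the incremental
#' public sector cost. Positive values indicate an efficiency gain over the
#' comparator.
#'
#' @param delta_societal_qalys incremental societal QALYs.
#' @param delta_cost_public incremental public sector cost, GBP.
#' @param lambda_pub public cost-effectiveness threshold, GBP/QALY.
#' @return INMB in GBP.
#' @export
inmb <- function(delta_societal_qalys, delta_cost_public, lambda_pub) {
  if (any(lambda_pub <= 0)) stop("lambda_pub must be > 0", call. = FALSE)
  lambda_pub * delta_societal_qalys - delta_cost_public
}

#' Incremental net health benefit
#'
#' The incremental public sector cost converted to its QALY equivalent at
#' the public threshold and netted off the societal QALY gain; equals
#' `inmb() / lambda_pub`.
#'
#' @inheritParams inmb
#' @return INHB in QALYs.
#' @export
inhb <- function(delta_societal_qalys, delta_cost_public, lambda_pub) {
  if (any(lambda_pub <= 0)) stop("lambda_pub must be > 0", call. = FALSE)
  delta_societal_qalys - delta_cost_public / lambda_pub
}

#' Strong and extended dominance frontier
#'
#' Sorts strategies by public sector cost, marks strongly dominated
#' strategies (another strategy with no higher cost and no fewer QALYs, at
#' least one strictly better; exact ties keep the lexicographically first
#' name), then iteratively removes extendedly dominated strategies (those
#' whose ICER against the preceding frontier strategy is at least the ICER
#' of the next frontier strategy against them) until sequential ICERs
#' strictly increase. ICERs are reported to the nearest pound; full
#' precision is kept in `icer_exact`.
#'
#' @param points data.frame with columns `strategy`, `public_cost` and
#'   `societal_qalys` (absolute or incremental against a common comparator —
#'   the frontier is invariant to a common offset). At least two rows;
#'   strategy names unique.
#' @return an object of class `fp_cea_result`: the input sorted by cost
#'   with columns `classification` (`"on-frontier"`, `"strongly dominated"`,
#'   `"extendedly dominated"`), `comparator` (next-cheapest frontier
#'   strategy), `icer` and `icer_exact`.
#' @export
#' @examples
#' tab <- read_table1()
#' dominance_frontier(data.frame(strategy = tab$strategy,
#'   public_cost = tab$incremental_public_cost,
#'   societal_qalys = tab$incremental_societal_qaly))
dominance_frontier <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("strategy", "public_cost", "societal_qalys") %in% names(points)))
  if (nrow(points) < 2) stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(points$strategy))
    stop("duplicate strategy names", call. = FALSE)
  pts <- points[order(points$public_cost, -points$societal_qalys, points$strategy), ]
  n <- nrow(pts)
  classification <- rep("on-frontier", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cheaper <- pts$public_cost[j] <= pts$public_cost[i]
      better <- pts$societal_qalys[j] >= pts$societal_qalys[i]
      strict <- pts$public_cost[j] < pts$public_cost[i] ||
        pts$societal_qalys[j] > pts$societal_qalys[i]
      tie_break <- !strict && pts$strategy[j] < pts$strategy[i]
      if (cheaper && better && (strict || tie_break)) {
        classification[i] <- "strongly dominated"
        break
      }
    }
  }

  repeat {
    keep <- which(classification == "on-frontier")
    if (length(keep) < 3) break
    dc <- diff(pts$public_cost[keep])
    dq <- diff(pts$societal_qalys[keep])
    ratio <- dc / dq
    drop <- which(ratio[-length(ratio)] >= ratio[-1])
    if (!length(drop)) break
    classification[keep[drop[1] + 1]] <- "extendedly dominated"
  }

  frontier <- which(classification == "on-frontier")
  comparator <- rep(NA_character_, n)
  icer_exact <- rep(NA_real_, n)
  if (length(frontier) > 1) {
    for (k in 2:length(frontier)) {
      i <- frontier[k]; j <- frontier[k - 1]
      comparator[i] <- pts$strategy[j]
      icer_exact[i] <- (pts$public_cost[i] - pts$public_cost[j]) /
        (pts$societal_qalys[i] - pts$societal_qalys[j])
    }
  }
  pts$classification <- classification
  pts$comparator <- comparator
  pts$icer_exact <- icer_exact
  pts$icer <- ifelse(is.na(icer_exact), NA_real_, round(icer_exact))
  rownames(pts) <- NULL
  class(pts) <- c("fp_cea_result", "data.frame")
  pts
}

#' Net-benefit measures for every strategy against a named comparator
#'
#' @param points data.frame with `strategy`, `public_cost`, `societal_qalys`.
#' @param comparator comparator strategy name (default `"UC"`).
#' @param lambda_pub public threshold, GBP/QALY.
#' @return data.frame with incremental cost, incremental societal QALYs,
#'   `inmb` and `inhb` per strategy.
#' @export
net_benefit_table <- function(points, comparator = "UC", lambda_pub = 30000) {
  if (!comparator %in% points$strategy)
    stop("comparator not found: ", comparator, call. = FALSE)
  ref <- points[points$strategy == comparator, ]
  dq <- points$societal_qalys - ref$societal_qalys
  dc <- points$public_cost - ref$public_cost
  data.frame(
    strategy = points$strategy, comparator = comparator, lambda_pub = lambda_pub,
    delta_cost_public = dc, delta_societal_qalys = dq,
    inmb = inmb(dq, dc, lambda_pub), inhb = inhb(dq, dc, lambda_pub)
  )
}

#' Derive strategy-level (cost, QALY) points from simulation summaries
#'
#' Collapses the `total` rows of strategy summaries into the points the CEA
#' layers consume. Public cost is the discounted all-cause public sector
#' cost (which includes public intervention spending); with
#' `basis = "fall-related"` only the directly fall-related component plus
#' public intervention cost is used. Net nonpublic cost is out-of-pocket
#' expenditure + informal care + copayment + participant and caregiver time
#' costs, minus paid and unpaid productivity value (productivity enters the
#' societal ledger as a negative cost).
#'
#' @param summaries an `fp_strategy_summary` data.frame (stacked strategies).
#' @param lambda_soc societal threshold for the QALY conversion.
#' @param basis `"all-cause"` (default) or `"fall-related"`.
#' @return data.frame with `strategy`, `public_cost`, `health_qalys`,
#'   `net_nonpublic_cost`, `societal_qalys`.
#' @export
strategy_points <- function(summaries, lambda_soc = 60000, basis = "all-cause") {
  basis <- match.arg(basis, c("all-cause", "fall-related"))
  tot <- summaries[summaries$group == "total", ]
  public <- if (basis == "all-cause") tot$cost_public_allcause
            else tot$cost_public_fall + tot$intervention_public
  nonpub <- tot$oop_expenditure + tot$informal_care + tot$intervention_copay +
    tot$intervention_participant_time + tot$intervention_caregiver_time -
    tot$productivity_paid - tot$productivity_unpaid
  data.frame(
    strategy = tot$strategy,
    public_cost = public,
    health_qalys = tot$qalys,
    net_nonpublic_cost = nonpub,
    societal_qalys = societal_qalys(tot$qalys, nonpub, lambda_soc),
    stringsAsFactors = FALSE
  )
}

#' Read the bundled published worked example of strategy incrementals
#'
#' Eight strategies' incremental public sector costs (all-cause, GBP) and
#' incremental societal QALYs against usual care, as printed in the source
#' analysis. Feeding these into [dominance_frontier()] reproduces the
#' published classification and frontier ICERs.
#'
#' @param path optional CSV path; defaults to the bundled fixture.
#' @return data.frame with `strategy`, `incremental_public_cost`,
#'   `incremental_societal_qaly`.
#' @export
read_table1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1.csv", package = "fallscea", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
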