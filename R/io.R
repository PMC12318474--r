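#' Write strategy summaries to CSV
#'
#' One row per strategy and group (SES quartiles plus total), with every
#' discounted outcome accumulator as a column.
#'
#' @param summaries an `fp_strategy_summary` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_strategy_summaries <- function(summaries, path) {
  cols <- c("strategy", "group", "persons", outcome_columns())
  utils::write.csv(as.data.frame(summaries)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a CEA frontier table to CSV
#'
#' Mirrors the layout of the published worked example: strategies in cost
#' order with incremental cost, incremental societal QALY, ICER (to the
#' nearest pound) and classification/comparator. QALYs are written to four
#' decimals, costs to the pound.
#'
#' @param cea an `fp_cea_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cea_table <- function(cea, path) {
  d <- as.data.frame(cea)
  base <- d[1, ]
  out <- data.frame(
    strategy = d$strategy,
    incremental_public_cost = round(d$public_cost - base$public_cost),
    incremental_societal_qaly = round(d$societal_qalys - base$societal_qalys, 4),
    icer = ifelse(d$classification == "on-frontier",
                  ifelse(is.na(d$icer), "", as.character(d$icer)),
                  d$classification),
    comparator = ifelse(is.na(d$comparator), "N/A", d$comparator)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a CEAC/CEAF table to CSV
#'
#' @param ceac an `fp_ceac` data.frame from [ceac_ceaf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(ceac, path) {
  utils::write.csv(as.data.frame(ceac), path, row.names = FALSE)
  invisible(path)
}

#' Write the PSA incremental scatter to CSV
#'
#' @param scatter data.frame from [incremental_scatter()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scatter <- function(scatter, path) {
  utils::write.csv(scatter, path, row.names = FALSE)
  invisible(path)
}

#' Write a DCEA table to CSV
#'
#' EDE NHB values are written to four decimals.
#'
#' @param dcea an `fp_dcea_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcea <- function(dcea, path) {
  d <- as.data.frame(dcea)
  d$ede_nhb <- round(d$ede_nhb, 4)
  d$ede_inhb <- round(d$ede_inhb, 4)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: configuration
#' source, scenario, strategies, seeds, package version and output paths.
#' The timestamp is informational and excluded from reproducibility
#' comparisons.
#'
#' @param path output JSON file.
#' @param config_path configuration file used (`NA` for package defaults).
#' @param scenario scenario name.
#' @param strategy_names strategies run.
#' @param seeds seeds used.
#' @param outputs named list/vector of result file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path = NA, scenario = "main",
                           strategy_names = strategies(), seeds = integer(),
                           outputs = character()) {
  manifest <- list(
    package = "fallscea",
    version = as.character(utils::packageVersion("fallscea")),
    config = config_path,
    scenario = scenario,
    strategies = strategy_names,
    seeds = seeds,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
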