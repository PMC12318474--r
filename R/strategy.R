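#' The eight evaluated falls-prevention strategies
#'
#' Every permutation of scaling the reactive (R), proactive (P) and
#' self-referred (SR) pathways from their usual-care level to the
#' guideline-recommended level: usual care (UC, none scaled up), single
#' pathways, pairs, and recommended care (RC, all three scaled up).
#'
#' @return character vector of strategy names.
#' @export
strategies <- function() {
  c("UC", "R", "P", "SR", "R+P", "R+SR", "P+SR", "RC")
}

#' Build a strategy configuration
#'
#' Resolves a strategy name into per-pathway service levels and the
#' associated supply and demand probabilities from the parameter set. At the
#' recommended level the supply probability is 1 (no supply-side
#' constraint); at the usual level both supply and demand reflect current
#' practice.
#'
#' @param name one of `strategies()`.
#' @param params an `fp_parameters` object providing the access rates.
#' @return an object of class `fp_strategy_config`: list with elements
#'   `name`, `levels` (named character, `"usual"`/`"recommended"` per
#'   pathway), `supply` and `demand` (named numeric per pathway).
#' @export
#' @examples
#' strategy_config("R+SR")$levels
strategy_config <- function(name, params = build_default_parameters()) {
  name <- match.arg(name, strategies())
  scaled <- switch(name,
    UC = character(0),
    RC = c("R", "P", "SR"),
    strsplit(name, "+", fixed = TRUE)[[1]]
  )
  pathways <- c("R", "P", "SR")
  levels <- ifelse(pathways %in% scaled, "recommended", "usual")
  names(levels) <- pathways
  supply <- vapply(pathways, function(pw)
    params$access_params$supply[[levels[[pw]]]][[pw]], numeric(1))
  demand <- vapply(pathways, function(pw)
    params$access_params$demand[[levels[[pw]]]][[pw]], numeric(1))
  if (any(supply[levels == "recommended"] != 1))
    stop("supply must be 1 for every recommended-level pathway", call. = FALSE)
  structure(list(name = name, levels = levels, supply = supply, demand = demand),
            class = "fp_strategy_config")
}

#' @export
print.fp_strategy_config <- function(x, ...) {
  cat("<fp_strategy_config>", x$name, "\n")
  for (pw in names(x$levels))
    cat(sprintf("  %-2s %-11s supply %.2f demand %.2f\n",
                pw, x$levels[[pw]], x$supply[[pw]], x$demand[[pw]]))
  invisible(x)
}
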