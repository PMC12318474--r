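#' Build the default PSA distribution specification
#'
#' Assigns a second-order uncertainty distribution to each distributed model
#' input, following standard health-economics practice: beta for
#' probabilities and utilities, gamma for costs, lognormal for positive
#' rate-like quantities (frailty increments), and normal for log-odds
#' regression coefficients. Hyperparameters are derived from the point
#' estimate and a coefficient of variation so that the distribution mean
#' equals the point estimate.
#'
#' @param params the base parameter set (used only to check the fields exist).
#' @param cv coefficient of variation applied to every entry (default 0.2).
#' @return a data.frame with columns `field` (a `$`-separated path into the
#'   parameter list), `family` (`"beta"`, `"gamma"`, `"lognormal"` or
#'   `"normal"`) and `cv`; class `fp_psa_spec`.
#' @export
default_psa_spec <- function(params = build_default_parameters(), cv = 0.2) {
  entries <- rbind(
    data.frame(field = "hospitalisation_prob_per_ma_fall", family = "beta"),
    data.frame(field = "recurrent_ma_two_prob", family = "beta"),
    data.frame(field = "fall_risk_coefficients", family = "normal"),
    data.frame(field = "fatal_fall_params", family = "normal"),
    data.frame(field = "ltc_admission_params", family = "normal"),
    data.frame(field = "other_cause_mortality_params$base_prob_male", family = "beta"),
    data.frame(field = "other_cause_mortality_params$base_prob_female", family = "beta"),
    data.frame(field = "frailty_progression$base_by_age", family = "lognormal"),
    data.frame(field = "frailty_progression$faller_increment", family = "lognormal"),
    data.frame(field = "cognitive_impairment_incidence$base_prob", family = "beta"),
    data.frame(field = "fear_of_falling_onset$base_prob", family = "beta"),
    data.frame(field = "gait_balance_onset$base_prob", family = "beta"),
    data.frame(field = "activity_transition$to_low_prob", family = "beta"),
    data.frame(field = "utility_params$frailty_decrement", family = "beta"),
    data.frame(field = "utility_params$acute_loss", family = "beta"),
    data.frame(field = "utility_params$hospitalised_loss", family = "beta"),
    data.frame(field = "cost_params$allcause_base", family = "gamma"),
    data.frame(field = "cost_params$ma_fall_cost", family = "gamma"),
    data.frame(field = "cost_params$hospitalised_ma_fall_cost", family = "gamma"),
    data.frame(field = "cost_params$oop_base", family = "gamma"),
    data.frame(field = "cost_params$informal_care_frailty_slope", family = "gamma"),
    data.frame(field = "intervention_params$R$relative_risk", family = "beta"),
    data.frame(field = "intervention_params$P$relative_risk", family = "beta"),
    data.frame(field = "intervention_params$SR$relative_risk", family = "beta"),
    data.frame(field = "intervention_params$R$public_cost", family = "gamma"),
    data.frame(field = "intervention_params$P$public_cost", family = "gamma"),
    data.frame(field = "intervention_params$SR$public_cost", family = "gamma"),
    data.frame(field = "access_params$gp_access_rate", family = "beta"),
    data.frame(field = "access_params$demand$usual", family = "beta"),
    data.frame(field = "access_params$demand$recommended", family = "beta")
  )
  entries$cv <- cv
  for (f in entries$field) get_param_path(params, f) # existence check
  class(entries) <- c("fp_psa_spec", "data.frame")
  entries
}

# Resolve a "$"-separated path into the nested parameter list.
get_param_path <- function(params, field) {
  keys <- strsplit(field, "$", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    if (is.null(x[[k]]))
      stop("PSA specification names unknown parameter field: ", field, call. = FALSE)
    x <- x[[k]]
  }
  x
}

set_param_path <- function(params, field, value) {
  keys <- strsplit(field, "$", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(params))
  eval(call("<-", expr, value))
  params
}

# One draw per element of `mean`, from a family parameterised so that the
# distribution mean equals `mean` with coefficient of variation `cv`.
# cv = 0 (or a degenerate mean such as 0 or 1 for the beta) returns the point
# estimate unchanged.
draw_psa_value <- function(mean, family, cv) {
  out <- mean
  for (i in seq_along(mean)) {
    m <- mean[[i]]
    if (cv == 0 || m == 0) next
    out[[i]] <- switch(family,
      beta = {
        v <- (cv * m)^2
        if (m >= 1 || v >= m * (1 - m)) m
        else {
          k <- m * (1 - m) / v - 1
          stats::rbeta(1, m * k, (1 - m) * k)
        }
      },
      gamma = {
        shape <- 1 / cv^2
        stats::rgamma(1, shape = shape, rate = shape / m)
      },
      lognormal = {
        if (m < 0) stop("lognormal PSA family requires a positive point estimate",
                        call. = FALSE)
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      },
      normal = stats::rnorm(1, mean = m, sd = cv * abs(m)),
      stop("unknown PSA distribution family: ", family, call. = FALSE)
    )
  }
  out
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Each field named in the specification is drawn independently from its
#' distribution family, with hyperparameters derived from the base value
#' (as distribution mean) and the entry's coefficient of variation. Fields
#' not named in the specification are copied unchanged. Draws are a pure
#' function of `(spec, base, seed)`.
#'
#' @param spec an `fp_psa_spec` data.frame, see [default_psa_spec()].
#' @param base the point-estimate parameter set.
#' @param seed single non-negative integer.
#' @return a new `fp_parameters` object.
#' @export
#' @examples
#' base <- build_default_parameters()
#' spec <- default_psa_spec(base)
#' draw <- sample_psa_parameters(spec, base, seed = 7)
sample_psa_parameters <- function(spec, base, seed) {
  stopifnot(seed >= 0)
  for (f in spec$field) get_param_path(base, f) # fail before consuming RNG
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  out <- unclass(base)
  for (i in seq_len(nrow(spec))) {
    f <- spec$field[i]
    value <- draw_psa_value(get_param_path(out, f), spec$family[i], spec$cv[i])
    out <- set_param_path(out, f, value)
  }
  # renormalise probabilities that must stay coherent after perturbation
  out$faller_type_split <- out$faller_type_split / sum(out$faller_type_split)
  out$access_params$gp_access_rate <- min(1, out$access_params$gp_access_rate)
  class(out) <- c("fp_parameters", "list")
  out
}
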