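#' Scenario configuration
#'
#' Bundles a transplant sequence with every assumption the analysis varies:
#' live-donor availability at the time of first graft failure, preemptive
#' retransplant probabilities, candidacy scaling, rate substitutions, the
#' third-transplant toggle, and the modelled age window.
#'
#' @param sequence One of `"LD-DD"`, `"DD-LD"`, `"DD-DD"`, `"LD-LD"`: the
#'   planned donor sources of the first and second transplants (the third,
#'   when enabled, is always deceased-donor).
#' @param start_age Integer starting age in years, 3-25. Ages outside that
#'   window are rejected rather than extrapolated.
#' @param horizon_age Model horizon; cycles stop when the cohort reaches this
#'   age (default 90).
#' @param ld_available_prob Probability the planned live donor is still
#'   available when needed (default 0.90, i.e. 10% unavailability). When the
#'   draw fails the remaining pathway becomes DD-DD.
#' @param preemptive_prob_LD,preemptive_prob_DD Probability the second
#'   transplant is preemptive (performed without returning to dialysis), by
#'   realized donor source (defaults 0.20 and 0.15). The third transplant is
#'   never preemptive.
#' @param force_preemptive If `TRUE`, the second transplant is always
#'   preemptive (the "always available and preemptive" scenario).
#' @param candidacy_multiplier Scalar in \[0, 1\] applied to the candidacy
#'   schedule (0.8 encodes "20% lower candidacy").
#' @param third_tx_enabled Allow a third (deceased-donor, non-preemptive)
#'   transplant (default `TRUE`).
#' @param pediatric_rate_override Optional replacement for the pediatric
#'   deceased-donor transplant rate (e.g. the adult rate).
#' @param young_mortality_override If `TRUE`, waiting-list mortality for ages
#'   3-9 is set equal to the 10-13 bracket value.
#' @param ld_failure_ratio_override Optional multiplier: live-donor
#'   graft-failure rates for age brackets starting in \[10, 25) are set to
#'   this fraction of the deceased-donor rates (0.5 in the sensitivity
#'   analysis).
#' @param recheck_candidacy If `TRUE`, candidacy is re-drawn every cycle spent
#'   waiting for a retransplant; by default it is evaluated once, at the age
#'   of graft failure.
#' @param ld_wait_receipt_prob Probability per cycle that an awaited live
#'   donor graft is received (default 1: an LD is assumed always faster than
#'   the waiting list).
#' @param cycle_correction Life-year accrual convention: `"none"` accrues a
#'   full year for every cycle begun alive (default); `"half"` averages the
#'   start- and end-of-cycle survival.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(sequence = c("LD-DD", "DD-LD", "DD-DD", "LD-LD"),
                            start_age,
                            horizon_age = 90,
                            ld_available_prob = 0.90,
                            preemptive_prob_LD = 0.20,
                            preemptive_prob_DD = 0.15,
                            force_preemptive = FALSE,
                            candidacy_multiplier = 1.0,
                            third_tx_enabled = TRUE,
                            pediatric_rate_override = NULL,
                            young_mortality_override = FALSE,
                            ld_failure_ratio_override = NULL,
                            recheck_candidacy = FALSE,
                            ld_wait_receipt_prob = 1.0,
                            cycle_correction = c("none", "half")) {
  sequence <- match.arg(sequence)
  cycle_correction <- match.arg(cycle_correction)
  start_age <- as.integer(start_age)
  if (is.na(start_age) || start_age < 3 || start_age > 25) {
    stop("start_age must be an integer in [3, 25]", call. = FALSE)
  }
  if (start_age >= horizon_age) stop("start_age must be below horizon_age", call. = FALSE)
  probs <- c(ld_available_prob, preemptive_prob_LD, preemptive_prob_DD,
             candidacy_multiplier, ld_wait_receipt_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(pediatric_rate_override) && pediatric_rate_override < 0) {
    stop("pediatric_rate_override must be non-negative", call. = FALSE)
  }
  if (!is.null(ld_failure_ratio_override) && ld_failure_ratio_override < 0) {
    stop("ld_failure_ratio_override must be non-negative", call. = FALSE)
  }
  structure(list(
    sequence = sequence,
    start_age = start_age,
    horizon_age = as.integer(horizon_age),
    ld_available_prob = ld_available_prob,
    preemptive_prob_LD = preemptive_prob_LD,
    preemptive_prob_DD = preemptive_prob_DD,
    force_preemptive = isTRUE(force_preemptive),
    candidacy_multiplier = candidacy_multiplier,
    third_tx_enabled = isTRUE(third_tx_enabled),
    pediatric_rate_override = pediatric_rate_override,
    young_mortality_override = isTRUE(young_mortality_override),
    ld_failure_ratio_override = ld_failure_ratio_override,
    recheck_candidacy = isTRUE(recheck_candidacy),
    ld_wait_receipt_prob = ld_wait_receipt_prob,
    cycle_correction = cycle_correction
  ), class = "scenario_config")
}

#' Copy a scenario config with a different starting age
#'
#' @param config A `scenario_config`.
#' @param start_age New starting age.
#' @return Modified copy.
#' @export
with_start_age <- function(config, start_age) {
  stopifnot(inherits(config, "scenario_config"))
  start_age <- as.integer(start_age)
  if (is.na(start_age) || start_age < 3 || start_age > 25) {
    stop("start_age must be an integer in [3, 25]", call. = FALSE)
  }
  config$start_age <- start_age
  config
}

#' Apply a scenario's rate substitutions to a rate table
#'
#' Applies `pediatric_rate_override`, `young_mortality_override` (ages 3-9
#' waiting-list mortality set to the value of the bracket containing age 10)
#' and `ld_failure_ratio_override` (LD graft-failure rates for brackets
#' starting in \[10, 25) set to `ratio *` the DD rates). Only the targeted
#' fields and brackets change.
#'
#' @param table A `rate_table`.
#' @param config A `scenario_config`.
#' @return A modified `rate_table`.
#' @export
apply_scenario_overrides <- function(table, config) {
  stopifnot(inherits(table, "rate_table"), inherits(config, "scenario_config"))
  if (!is.null(config$pediatric_rate_override)) {
    table$tx_rates$tx_rate_DD_pediatric <- config$pediatric_rate_override
  }
  b <- table$brackets
  if (config$young_mortality_override) {
    ref <- lookup_rate(table, "dialysis_mortality", 10)
    young <- b$age_lo < 10 & b$age_hi > 3
    b$dialysis_mortality[young] <- ref
  }
  if (!is.null(config$ld_failure_ratio_override)) {
    sel <- b$age_lo >= 10 & b$age_lo < 25
    b$graft_failure_LD[sel] <- config$ld_failure_ratio_override * b$graft_failure_DD[sel]
  }
  table$brackets <- b
  validate_rate_table(table)
  table
}

#' Monte Carlo uncertainty specification
#'
#' Controls the probabilistic sensitivity analysis: number of trials, the
#' log-scale standard deviation of the mean-one log-normal multipliers, the
#' RNG seed, and which age-stratified rate fields are perturbed.
#'
#' @param n_trials Number of Monte Carlo trials (default 1000).
#' @param sigma Log-scale standard deviation of the multipliers (default
#'   0.10; the source analysis does not state its dispersion).
#' @param seed Integer RNG seed.
#' @param perturbed_fields Age-stratified fields receiving independent
#'   log-normal multipliers per bracket (default: the mortality and
#'   graft-failure fields).
#' @return Object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(n_trials = 1000, sigma = 0.10, seed = 1L,
                             perturbed_fields = c("dialysis_mortality",
                                                  "graft_mortality",
                                                  "graft_failure_LD",
                                                  "graft_failure_DD")) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  bad <- setdiff(perturbed_fields, .bracket_fields)
  if (length(bad)) stop("unknown perturbed fields: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_trials = n_trials, sigma = sigma, seed = as.integer(seed),
                 perturbed_fields = perturbed_fields),
            class = "uncertainty_spec")
}
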