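#' Convert an annual event rate to a one-cycle transition probability
#'
#' Assumes a constant hazard within the yearly cycle, so an event with annual
#' rate \eqn{r} (events per person-year) occurs at least once during the cycle
#' with probability \eqn{1 - e^{-r}}.
#'
#' @param rate Non-negative annual rate(s) per person-year. Vectorized.
#' @return Probability in \[0, 1) per one-year cycle (1 for an infinite rate).
#' @examples
#' rate_to_prob(0.40)  # 0.32968
#' @export
rate_to_prob <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(is.na(rate)) || any(rate < 0)) {
    stop("rate must be non-negative and non-missing", call. = FALSE)
  }
  -expm1(-rate)
}

#' Convert a 5-year failure probability to an annual rate
#'
#' Inverts the constant-hazard relationship over a 5-year window:
#' \eqn{r = -\ln(1 - p_5)/5}. Composing [rate_to_prob()] over five 1-year
#' cycles on the returned rate recovers `p5`.
#'
#' @param p5 Probability of failure within 5 years, in \[0, 1). Vectorized.
#' @return Annual rate per person-year.
#' @examples
#' prob5_to_annual_rate(0.39347)  # ~0.10
#' @export
prob5_to_annual_rate <- function(p5) {
  stopifnot(is.numeric(p5))
  if (any(is.na(p5)) || any(p5 < 0) || any(p5 >= 1)) {
    stop("p5 must lie in [0, 1)", call. = FALSE)
  }
  -log1p(-p5) / 5
}

#' Per-cycle probabilities for competing events
#'
#' Resolves several mutually exclusive events with constant hazards
#' \eqn{r_1, \dots, r_k} acting over one cycle by proportional-hazards
#' allocation: event \eqn{i} receives probability
#' \eqn{(r_i/\sum r)(1 - e^{-\sum r})}, and the stay probability is
#' \eqn{e^{-\sum r}}. The allocation is order-invariant and the probabilities
#' sum to 1 exactly. With a single event it reduces to [rate_to_prob()].
#'
#' @param rates Numeric vector of non-negative annual rates.
#' @return List with `event` (per-event probabilities, same length and names
#'   as `rates`) and `stay` (probability no event occurs).
#' @export
competing_risk_probs <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) >= 1)
  if (any(is.na(rates)) || any(rates < 0)) {
    stop("rates must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(rates)
  if (total == 0) {
    ev <- rates * 0
  } else {
    ev <- rates / total * -expm1(-total)
  }
  list(event = ev, stay = exp(-total))
}
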