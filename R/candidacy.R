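#' Retransplant candidacy schedule
#'
#' Probability that a patient with a failed graft is medically eligible for
#' another transplant, as a non-increasing function of age. The default
#' anchors are full candidacy through age 30, declining to 80% by 50, 30% by
#' 60, 5% by 70 and 0 by 80; values between anchors are interpolated
#' piecewise-linearly (the minimal assumption; the source registry schedule
#' is only anchored at those ages).
#'
#' @param anchors Data frame with strictly increasing `age` and non-increasing
#'   `prob` in \[0, 1\].
#' @param interpolation Interpolation rule between anchors; only `"linear"`
#'   is implemented.
#' @return Object of class `candidacy_schedule`.
#' @export
candidacy_schedule <- function(anchors = data.frame(
                                 age = c(30, 50, 60, 70, 80),
                                 prob = c(1.0, 0.80, 0.30, 0.05, 0.0)
                               ),
                               interpolation = "linear") {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("age", "prob") %in% names(anchors)))
  if (any(diff(anchors$age) <= 0)) stop("anchor ages must be strictly increasing", call. = FALSE)
  if (any(anchors$prob < 0) || any(anchors$prob > 1)) stop("anchor probabilities must lie in [0,1]", call. = FALSE)
  if (any(diff(anchors$prob) > 0)) stop("candidacy must be non-increasing with age", call. = FALSE)
  interpolation <- match.arg(interpolation, "linear")
  structure(list(anchors = anchors, interpolation = interpolation),
            class = "candidacy_schedule")
}

#' Candidacy probability at a given age
#'
#' Evaluates the schedule at `age` (constant extrapolation beyond the first
#' and last anchors, so 1 below age 30 and 0 at/after 80 under the defaults)
#' and scales the result by `multiplier` (the "lower candidacy" scenarios).
#'
#' @param age Age(s) in years, in \[0, 120\].
#' @param schedule A [candidacy_schedule()].
#' @param multiplier Scalar in \[0, 1\] applied multiplicatively.
#' @return Probability (vectorized over `age`).
#' @export
candidacy_at_age <- function(age, schedule = candidacy_schedule(), multiplier = 1) {
  stopifnot(inherits(schedule, "candidacy_schedule"))
  if (any(age < 0) || any(age > 120)) stop("age must lie in [0, 120]", call. = FALSE)
  if (multiplier < 0 || multiplier > 1) stop("multiplier must lie in [0, 1]", call. = FALSE)
  a <- schedule$anchors
  stats::approx(a$age, a$prob, xout = age, rule = 2)$y * multiplier
}
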