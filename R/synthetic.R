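#' Specification for the synthetic rate-table generator
#'
#' Describes the statistical structure the generated tables must carry:
#' dialysis mortality exceeding with-transplant mortality at every age,
#' elevated waiting-list mortality at ages 3-9 relative to 10-13, DD
#' graft-failure rates at or above LD rates with the gap narrowing at ages
#' 10-24, and a graft-loss peak over ages 14-25.
#'
#' @param seed Integer RNG seed.
#' @param dd_p5_range Range of 5-year DD graft-failure probabilities from
#'   which non-peak brackets are drawn.
#' @param ld_dd_gap_young LD/DD failure-rate ratio range for brackets outside
#'   ages 10-24 (default 0.4-0.6, i.e. LD loss 40-60% lower).
#' @param ld_dd_gap_teen LD/DD ratio range for brackets starting in ages
#'   10-24 (default 0.6-0.8, i.e. only 20-40% lower).
#' @param young_child_excess_mortality Ratio of ages 3-9 to ages 10-13
#'   waiting-list mortality (default 2.5; 1 reproduces the equalized-mortality
#'   scenario).
#' @param adolescent_failure_peak Multiplier applied to graft-failure rates of
#'   brackets starting in ages 14-25 (default 1.6; > 1 makes those brackets
#'   the bracket-wise maxima).
#' @param noise Log-scale SD of multiplicative noise on the baseline mortality
#'   profiles (0 gives a deterministic table for a given seed and spec).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           dd_p5_range = c(0.18, 0.30),
                           ld_dd_gap_young = c(0.40, 0.60),
                           ld_dd_gap_teen = c(0.60, 0.80),
                           young_child_excess_mortality = 2.5,
                           adolescent_failure_peak = 1.6,
                           noise = 0.10) {
  stopifnot(length(dd_p5_range) == 2, dd_p5_range[1] > 0, dd_p5_range[2] < 1,
            all(ld_dd_gap_young > 0), all(ld_dd_gap_teen > 0),
            young_child_excess_mortality > 0, adolescent_failure_peak > 0,
            noise >= 0)
  if (max(ld_dd_gap_young, ld_dd_gap_teen) > 1) {
    stop("LD/DD failure ratios must not exceed 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), dd_p5_range = dd_p5_range,
                 ld_dd_gap_young = ld_dd_gap_young,
                 ld_dd_gap_teen = ld_dd_gap_teen,
                 young_child_excess_mortality = young_child_excess_mortality,
                 adolescent_failure_peak = adolescent_failure_peak,
                 noise = noise),
            class = "generator_spec")
}

# Registry-style default age brackets.
.default_brackets <- function() {
  data.frame(
    age_lo = c(0, 5, 10, 14, 18, 22, 30, 40, 50, 60, 70, 80),
    age_hi = c(5, 10, 14, 18, 22, 30, 40, 50, 60, 70, 80, 90)
  )
}

# Baseline age profiles (annual rates per person-year) used by the generator;
# magnitudes are synthetic, registry-plausible, not fitted to any table.
.base_graft_mortality <- c(0.008, 0.004, 0.003, 0.003, 0.004, 0.005,
                           0.007, 0.012, 0.022, 0.040, 0.080, 0.150)

#' Generate a synthetic age-stratified rate table
#'
#' Draws a [rate_table()] satisfying, by construction, the structural
#' constraints of [generator_spec()]; the result is verified with
#' [check_rate_structure()] before being returned and generation fails
#' loudly if a constraint is violated. Reproducible from the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return A `rate_table`.
#' @export
generate_rate_tables <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  b <- .default_brackets()
  nb <- nrow(b)
  noise <- function() exp(stats::rnorm(nb, 0, spec$noise))

  gmort <- .base_graft_mortality * noise()
  dial <- gmort * stats::runif(nb, 2.5, 4.5)
  # young-child waiting-list excess, anchored on the 10-13 bracket
  i1013 <- which(b$age_lo == 10)
  young <- b$age_lo < 10
  dial[young] <- spec$young_child_excess_mortality * dial[i1013]
  gmort[young] <- pmin(gmort[young], 0.8 * dial[young])

  peak <- b$age_lo >= 14 & b$age_lo <= 25
  p5_dd <- stats::runif(nb, spec$dd_p5_range[1], spec$dd_p5_range[2])
  r_dd <- prob5_to_annual_rate(p5_dd)
  r_dd[peak] <- r_dd[peak] * spec$adolescent_failure_peak
  if (spec$adolescent_failure_peak > 1) {
    cap <- 0.95 * min(r_dd[peak])
    r_dd[!peak] <- pmin(r_dd[!peak], cap)
  }
  teen <- b$age_lo >= 10 & b$age_lo < 25
  ratio <- numeric(nb)
  ratio[teen] <- stats::runif(sum(teen), spec$ld_dd_gap_teen[1], spec$ld_dd_gap_teen[2])
  ratio[!teen] <- stats::runif(sum(!teen), spec$ld_dd_gap_young[1], spec$ld_dd_gap_young[2])
  r_ld <- ratio * r_dd
  if (spec$adolescent_failure_peak > 1) {
    # the 10-13 bracket draws the narrow-gap ratio but is not a peak bracket,
    # so its LD rate can overtake the peak; cap to preserve the maxima
    r_ld[!peak] <- pmin(r_ld[!peak], 0.95 * min(r_ld[peak]))
  }

  b$dialysis_mortality <- dial
  b$graft_mortality <- gmort
  b$graft_failure_LD <- r_ld
  b$graft_failure_DD <- r_dd
  tbl <- rate_table(b)
  issues <- check_rate_structure(tbl, spec)
  if (length(issues)) {
    stop("generated table violates structural constraints: ",
         paste(issues, collapse = "; "), call. = FALSE)
  }
  tbl
}

#' Check the structural constraints of a rate table
#'
#' Predicate used both by the generator and by tests: dialysis mortality
#' must exceed with-graft mortality in every bracket; DD graft-failure rates
#' must be at or above LD rates everywhere; waiting-list mortality for ages
#' 3-9 must exceed the 10-13 bracket when the excess ratio is above 1 (and
#' equal it when the ratio is 1); brackets starting in ages 14-25 must be
#' the bracket-wise graft-failure maxima when a peak is requested.
#'
#' @param table A `rate_table`.
#' @param spec A `generator_spec` (controls which conditional constraints
#'   apply).
#' @return Character vector of violated-constraint descriptions; empty when
#'   all constraints hold.
#' @export
check_rate_structure <- function(table, spec = generator_spec()) {
  stopifnot(inherits(table, "rate_table"))
  b <- table$brackets[order(table$brackets$age_lo), ]
  out <- character(0)
  if (!all(b$dialysis_mortality > b$graft_mortality)) {
    out <- c(out, "dialysis mortality must exceed with-graft mortality in every bracket")
  }
  if (!all(b$graft_failure_DD >= b$graft_failure_LD)) {
    out <- c(out, "DD graft-failure rates must be >= LD rates in every bracket")
  }
  i1013 <- which(b$age_lo <= 10 & b$age_hi > 10)
  young <- b$age_lo < 10 & b$age_hi > 3
  if (length(i1013) == 1 && any(young)) {
    ref <- b$dialysis_mortality[i1013]
    if (spec$young_child_excess_mortality > 1 &&
        !all(b$dialysis_mortality[young] > ref)) {
      out <- c(out, "ages 3-9 waiting-list mortality must exceed the 10-13 bracket")
    }
    if (spec$young_child_excess_mortality == 1 &&
        !all(abs(b$dialysis_mortality[young] - ref) < 1e-12)) {
      out <- c(out, "ages 3-9 waiting-list mortality must equal the 10-13 bracket")
    }
  }
  if (spec$adolescent_failure_peak > 1) {
    peak <- b$age_lo >= 14 & b$age_lo <= 25
    for (f in c("graft_failure_LD", "graft_failure_DD")) {
      if (any(peak) && max(b[[f]][!peak]) >= min(b[[f]][peak])) {
        out <- c(out, paste0(f, ": ages 14-25 brackets must be the maxima"))
      }
    }
  }
  out
}

#' Deterministic calibration fixture
#'
#' A versioned, fully synthetic rate table and candidacy schedule shipped
#' with the package. Transplant rates are 0.40 / 0.15 / 0.12 per
#' person-waiting-year (pediatric DD, adult DD, third transplant) exactly;
#' every other magnitude is an invented, registry-plausible stand-in chosen
#' so the qualitative orderings of the published comparisons emerge
#' (live-donor-first superiority at the youngest and oldest starting ages,
#' near-equivalence around ages 10-15). It is not fitted to any registry
#' table.
#'
#' @return List with elements `table` (a `rate_table`) and `schedule`
#'   (a `candidacy_schedule`).
#' @export
calibration_fixture <- function() {
  b <- .default_brackets()
  b$dialysis_mortality <- c(0.055, 0.042, 0.012, 0.015, 0.025, 0.040,
                            0.055, 0.080, 0.110, 0.160, 0.220, 0.300)
  b$graft_mortality <- .base_graft_mortality
  p5_dd <- c(0.22, 0.20, 0.26, 0.40, 0.42, 0.34,
             0.24, 0.22, 0.22, 0.24, 0.28, 0.30)
  ratio <- c(0.50, 0.50, 0.65, 0.65, 0.65, 0.65,
             0.50, 0.50, 0.50, 0.50, 0.50, 0.50)
  r_dd <- prob5_to_annual_rate(p5_dd)
  b$graft_failure_DD <- r_dd
  b$graft_failure_LD <- ratio * r_dd
  list(table = rate_table(b, tx_rate_DD_pediatric = 0.40,
                          tx_rate_DD_adult = 0.15, tx_rate_third = 0.12),
       schedule = candidacy_schedule())
}
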