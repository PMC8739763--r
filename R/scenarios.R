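#' @title Scenario grids and age sweeps
#' @description Encodes the published comparison grid: the baseline
#'   availability triplet per starting age, the no-live-donor (DD-DD)
#'   comparison with candidacy and third-transplant variants, the six-item
#'   sensitivity suite, and integer-age sweeps of the net difference.
#' @name scenarios
#' @keywords internal
NULL

.report_row <- function(start_age, scenario, option1, option2, r1, r2, ci) {
  nd <- net_difference(r1, r2)
  data.frame(
    start_age = start_age,
    scenario = scenario,
    option1 = option1,
    option2 = option2,
    ly_option1 = r1$life_years,
    dd_option1 = r1$dd_kidneys_used,
    ly_option2 = r2$life_years,
    dd_option2 = r2$dd_kidneys_used,
    net_life_years = nd$net_life_years,
    net_dd_kidneys = nd$net_dd_kidneys,
    ci_low = if (is.null(ci)) NA_real_ else ci$ci_low,
    ci_high = if (is.null(ci)) NA_real_ else ci$ci_high,
    stringsAsFactors = FALSE
  )
}

.compare_pair <- function(config1, config2, table, schedule, spec,
                          start_age, scenario) {
  r1 <- solve_cohort(config1, table, schedule)
  r2 <- solve_cohort(config2, table, schedule)
  ci <- if (!is.null(spec)) {
    uncertainty_net_difference(config1, config2, table, schedule, spec)
  } else NULL
  .report_row(start_age, scenario, config1$sequence, config2$sequence, r1, r2, ci)
}

.as_report <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Baseline comparison grid (availability triplet per age)
#'
#' For each starting age, compares option 1 (LD-DD under baseline
#' assumptions) against three DD-LD variants of option 2: live donor not
#' available 10% of the time (baseline), always available, and always
#' available with a guaranteed preemptive second transplant.
#'
#' @param ages Starting ages (default `c(3, 5, 10, 15, 20, 25)`).
#' @param table A [rate_table()].
#' @param schedule A [candidacy_schedule()].
#' @param spec Optional [uncertainty_spec()]; when supplied each row carries
#'   a percentile 95% CI on the net life-years (slower).
#' @return A `comparison_report` data frame, three rows per age.
#' @export
run_baseline_grid <- function(ages = c(3, 5, 10, 15, 20, 25), table,
                              schedule = candidacy_schedule(), spec = NULL) {
  rows <- list()
  for (a in ages) {
    opt1 <- scenario_config("LD-DD", start_age = a)
    variants <- list(
      "LD not available 10% of the time" = scenario_config("DD-LD", start_age = a),
      "LD always available" = scenario_config("DD-LD", start_age = a,
                                              ld_available_prob = 1),
      "LD always available and preemptive" = scenario_config(
        "DD-LD", start_age = a, ld_available_prob = 1, force_preemptive = TRUE)
    )
    for (lab in names(variants)) {
      rows[[length(rows) + 1L]] <-
        .compare_pair(opt1, variants[[lab]], table, schedule, spec, a, lab)
    }
  }
  .as_report(rows)
}

#' No-live-donor comparison grid (LD-DD vs DD-DD)
#'
#' Compares LD-DD against DD-DD (a live donor never available for the second
#' transplant) under three scenarios: baseline assumptions, 20% lower
#' candidacy after a failed transplant (candidacy multiplier 0.8, applied to
#' both options), and no third transplant option (both options).
#'
#' @inheritParams run_baseline_grid
#' @return A `comparison_report` data frame, three rows per age.
#' @export
run_no_ld_grid <- function(ages = c(3, 5, 10, 15, 20, 25), table,
                           schedule = candidacy_schedule(), spec = NULL) {
  mods <- list(
    "Baseline assumptions" = list(),
    "20% lower candidacy after a failed transplant" = list(candidacy_multiplier = 0.8),
    "No third transplant option" = list(third_tx_enabled = FALSE)
  )
  rows <- list()
  for (a in ages) {
    for (lab in names(mods)) {
      c1 <- do.call(scenario_config, c(list("LD-DD", start_age = a), mods[[lab]]))
      c2 <- do.call(scenario_config, c(list("DD-DD", start_age = a), mods[[lab]]))
      rows[[length(rows) + 1L]] <-
        .compare_pair(c1, c2, table, schedule, spec, a, lab)
    }
  }
  .as_report(rows)
}

#' One-age sensitivity suite
#'
#' One row per sensitivity item for a single starting age, always with
#' LD-DD as option 1: a live-donor availability sweep over
#' \{0, 0.25, 0.5, 0.75, 1\}; the pediatric DD transplant rate set to the
#' adult rate (both options); candidacy multiplier 0.8 (both options);
#' preemptive second-transplant probabilities set to 0 and to 1 (both
#' options); waiting-list mortality for ages 3-9 equalized to the 10-13
#' bracket (both options); and LD graft-failure rates for ages 10-24 set to
#' half the DD rates (both options).
#'
#' @param age Single starting age.
#' @inheritParams run_baseline_grid
#' @return A `comparison_report` data frame.
#' @export
run_sensitivity_suite <- function(age, table, schedule = candidacy_schedule(),
                                  spec = NULL) {
  rows <- list()
  add <- function(lab, mods1, mods2) {
    c1 <- do.call(scenario_config, c(list("LD-DD", start_age = age), mods1))
    c2 <- do.call(scenario_config, c(list("DD-LD", start_age = age), mods2))
    rows[[length(rows) + 1L]] <<-
      .compare_pair(c1, c2, table, schedule, spec, age, lab)
  }
  for (p in c(0, 0.25, 0.5, 0.75, 1)) {
    add(sprintf("LD availability %.2f", p), list(), list(ld_available_prob = p))
  }
  adult <- table$tx_rates$tx_rate_DD_adult  # row tracks its input table
  add("Pediatric DD rate set to adult rate",
      list(pediatric_rate_override = adult),
      list(pediatric_rate_override = adult))
  add("20% lower candidacy",
      list(candidacy_multiplier = 0.8), list(candidacy_multiplier = 0.8))
  add("Never preemptive",
      list(preemptive_prob_LD = 0, preemptive_prob_DD = 0),
      list(preemptive_prob_LD = 0, preemptive_prob_DD = 0))
  add("Always preemptive",
      list(preemptive_prob_LD = 1, preemptive_prob_DD = 1),
      list(preemptive_prob_LD = 1, preemptive_prob_DD = 1))
  add("Ages 3-9 waiting-list mortality equal to 10-13",
      list(young_mortality_override = TRUE),
      list(young_mortality_override = TRUE))
  add("LD graft failure halved vs DD, ages 10-24",
      list(ld_failure_ratio_override = 0.5),
      list(ld_failure_ratio_override = 0.5))
  .as_report(rows)
}

#' Net-difference sweep over starting ages
#'
#' Evaluates both options at every requested integer starting age and
#' returns a plottable series of life-years and net differences.
#'
#' @param ages Integer starting ages (default 3:25).
#' @param config1,config2 Scenario templates; their `start_age` is replaced
#'   by each swept age.
#' @param table A [rate_table()].
#' @param schedule A [candidacy_schedule()].
#' @return Data frame with columns `start_age`, `ly_option1`, `ly_option2`,
#'   `net_life_years`, `net_dd_kidneys`.
#' @export
age_sweep <- function(ages = 3:25, config1, config2, table,
                      schedule = candidacy_schedule()) {
  out <- lapply(ages, function(a) {
    r1 <- solve_cohort(with_start_age(config1, a), table, schedule)
    r2 <- solve_cohort(with_start_age(config2, a), table, schedule)
    nd <- net_difference(r1, r2)
    data.frame(start_age = a, ly_option1 = r1$life_years,
               ly_option2 = r2$life_years,
               net_life_years = nd$net_life_years,
               net_dd_kidneys = nd$net_dd_kidneys)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Named scenario presets
#'
#' Option-pair templates for the published figure panels: `"baseline"`
#' (LD-DD vs DD-LD under default assumptions), `"optimal"` (live donor
#' always available), `"optimal_preemptive"` (always available and
#' preemptive), `"young_mortality_equalized"` (optimal-preemptive plus ages
#' 3-9 waiting-list mortality set to the 10-13 bracket, both options) and
#' `"composite_uniform"` (the previous preset plus the pediatric DD
#' transplant rate set to the adult rate, both options).
#'
#' @param name Preset name.
#' @param start_age Starting age for both configs.
#' @param adult_rate Adult DD transplant rate used by the composite preset's
#'   pediatric override (default 0.15).
#' @return List with elements `config1` and `config2`.
#' @export
scenario_preset <- function(name = c("baseline", "optimal", "optimal_preemptive",
                                     "young_mortality_equalized",
                                     "composite_uniform"),
                            start_age, adult_rate = 0.15) {
  name <- match.arg(name)
  m1 <- list()
  m2 <- switch(name,
    baseline = list(),
    optimal = list(ld_available_prob = 1),
    optimal_preemptive = list(ld_available_prob = 1, force_preemptive = TRUE),
    young_mortality_equalized = list(ld_available_prob = 1,
                                     force_preemptive = TRUE,
                                     young_mortality_override = TRUE),
    composite_uniform = list(ld_available_prob = 1, force_preemptive = TRUE,
                             young_mortality_override = TRUE,
                             pediatric_rate_override = adult_rate)
  )
  if (name %in% c("young_mortality_equalized", "composite_uniform")) {
    m1$young_mortality_override <- TRUE
  }
  if (name == "composite_uniform") m1$pediatric_rate_override <- adult_rate
  list(
    config1 = do.call(scenario_config, c(list("LD-DD", start_age = start_age), m1)),
    config2 = do.call(scenario_config, c(list("DD-LD", start_age = start_age), m2))
  )
}

#' Write / read a comparison report as CSV
#'
#' @param report A `comparison_report`.
#' @param path CSV path.
#' @return `path` invisibly for the writer; the report for the reader.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  # all-NA CI columns come back logical; keep the schema numeric
  for (col in c("ci_low", "ci_high")) {
    if (col %in% names(out)) out[[col]] <- as.numeric(out[[col]])
  }
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", nrow(x), " rows\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
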