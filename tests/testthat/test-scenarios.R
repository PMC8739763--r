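test_that("baseline grid produces the availability triplet per age", {
  rep <- run_baseline_grid(ages = c(5, 20), fixture$table, fixture$schedule)
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep), 6)
  expect_true(all(rep$option1 == "LD-DD"))
  expect_true(all(rep$option2 == "DD-LD"))
  for (a in c(5, 20)) {
    sub <- rep[rep$start_age == a, ]
    # option 1 is untouched by the option-2 availability scenario
    expect_equal(length(unique(sub$ly_option1)), 1)
    # more availability never hurts the DD-LD option
    expect_gte(sub$ly_option2[2], sub$ly_option2[1])
    # net difference recomputable from the row's own entries
    expect_equal(sub$net_life_years, sub$ly_option1 - sub$ly_option2)
  }
})

test_that("no-LD grid applies candidacy and third-transplant variants to both arms", {
  rep <- run_no_ld_grid(ages = c(5, 15), fixture$table, fixture$schedule)
  expect_equal(nrow(rep), 6)
  expect_true(all(rep$option2 == "DD-DD"))
  expect_true(all(rep$net_life_years > 0))
  for (a in c(5, 15)) {
    sub <- rep[rep$start_age == a, ]
    base <- sub[sub$scenario == "Baseline assumptions", ]
    lower_cand <- sub[grepl("candidacy", sub$scenario), ]
    no_third <- sub[grepl("third", sub$scenario), ]
    # both arms move when candidacy is reduced
    expect_lt(lower_cand$ly_option1, base$ly_option1)
    expect_lt(lower_cand$ly_option2, base$ly_option2)
    # removing the third transplant removes DD influx in option 2
    expect_lt(no_third$dd_option2, base$dd_option2)
    expect_lt(no_third$dd_option1, base$dd_option1)
  }
  # candidacy multiplier 1.0 reproduces the baseline scenario exactly
  r_base <- solve_cohort(scenario_config("DD-DD", start_age = 5), fixture$table,
                         fixture$schedule)
  r_one <- solve_cohort(scenario_config("DD-DD", start_age = 5,
                                        candidacy_multiplier = 1.0),
                        fixture$table, fixture$schedule)
  expect_identical(r_base$life_years, r_one$life_years)
})

test_that("sensitivity suite rows behave as documented", {
  rep <- run_sensitivity_suite(15, fixture$table, fixture$schedule)
  expect_equal(nrow(rep), 11)
  # availability 0 reduces DD-LD to DD-DD exactly
  row0 <- rep[rep$scenario == "LD availability 0.00", ]
  dd_dd <- solve_cohort(scenario_config("DD-DD", start_age = 15), fixture$table,
                        fixture$schedule)
  expect_equal(row0$ly_option2, dd_dd$life_years, tolerance = 1e-12)
  # availability sweep is monotone for option 2
  sweep_rows <- rep[grepl("^LD availability", rep$scenario), ]
  expect_true(all(diff(sweep_rows$ly_option2) >= -1e-12))
  # halving LD failure helps the LD-first arm and cannot touch DD-DD
  cfg_dd <- scenario_config("DD-DD", start_age = 15, ld_failure_ratio_override = 0.5)
  expect_equal(solve_cohort(cfg_dd, fixture$table, fixture$schedule)$life_years,
               dd_dd$life_years)
  cfg_ld0 <- scenario_config("LD-DD", start_age = 15)
  cfg_ld1 <- scenario_config("LD-DD", start_age = 15, ld_failure_ratio_override = 0.5)
  expect_gt(solve_cohort(cfg_ld1, fixture$table, fixture$schedule)$life_years,
            solve_cohort(cfg_ld0, fixture$table, fixture$schedule)$life_years)
})

test_that("pediatric rate override cannot matter for a start-age-20 cohort", {
  for (seqn in c("LD-DD", "DD-LD")) {
    c0 <- scenario_config(seqn, start_age = 20)
    c1 <- scenario_config(seqn, start_age = 20, pediatric_rate_override = 0.15)
    r0 <- solve_cohort(c0, fixture$table, fixture$schedule)
    r1 <- solve_cohort(c1, fixture$table, fixture$schedule)
    expect_identical(r0$occupancy, r1$occupancy)
  }
})

test_that("age_sweep returns one row per age and zeroes on identical options", {
  cfg <- scenario_config("LD-DD", start_age = 10)
  sw <- age_sweep(c(3, 9, 14, 25), cfg, cfg, fixture$table, fixture$schedule)
  expect_equal(nrow(sw), 4)
  expect_equal(sw$net_life_years, rep(0, 4))
  expect_equal(sw$net_dd_kidneys, rep(0, 4))
})

test_that("reports round-trip through CSV and reruns are byte-identical", {
  rep <- run_baseline_grid(ages = 10, fixture$table, fixture$schedule)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, p1)
  back <- read_report(p1)
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12)
  write_report(run_baseline_grid(ages = 10, fixture$table, fixture$schedule), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("scenario presets compose the documented overrides", {
  pr <- scenario_preset("composite_uniform", start_age = 5)
  expect_equal(pr$config2$ld_available_prob, 1)
  expect_true(pr$config2$force_preemptive)
  expect_true(pr$config1$young_mortality_override)
  expect_equal(pr$config1$pediatric_rate_override, 0.15)
  base <- scenario_preset("baseline", start_age = 5)
  expect_false(base$config2$force_preemptive)
  expect_equal(base$config2$ld_available_prob, 0.9)
})
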