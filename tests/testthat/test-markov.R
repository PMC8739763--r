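test_that("state space reflects sequence, availability and third-tx settings", {
  s_dd <- build_state_space(scenario_config("DD-DD", start_age = 10,
                                            third_tx_enabled = FALSE))
  expect_false(any(grepl("3", s_dd)))
  expect_false(any(grepl("LD", s_dd)))
  expect_true("W1" %in% s_dd)
  expect_equal(sum(s_dd == "DEAD"), 1)

  s_ld <- build_state_space(scenario_config("LD-DD", start_age = 10))
  expect_false("W1" %in% s_ld)
  expect_equal(s_ld[1], "T1_LD")

  s_ddld <- build_state_space(scenario_config("DD-LD", start_age = 10))
  expect_equal(s_ddld[1], "W1")
  expect_true(all(c("A2_LD", "A2_DD", "T2_LD", "T2_DD") %in% s_ddld))
  # with the live donor certain to be available the DD-second branch vanishes
  s_sure <- build_state_space(scenario_config("DD-LD", start_age = 10,
                                              ld_available_prob = 1))
  expect_false(any(c("A2_DD", "T2_DD") %in% s_sure))
  # deterministic ordering
  expect_identical(s_ddld, build_state_space(scenario_config("DD-LD", start_age = 10)))
})

test_that("transition rows are proper distributions with an absorbing DEAD", {
  cfg <- scenario_config("DD-LD", start_age = 5)
  states <- build_state_space(cfg)
  dead <- transition_row("DEAD", 40, fixture$table, cfg, fixture$schedule)
  expect_equal(unname(dead["DEAD"]), 1)
  for (s in states) {
    for (age in c(5, 17, 18, 35, 70, 85)) {
      row <- transition_row(s, age, fixture$table, cfg, fixture$schedule)
      expect_lt(abs(sum(row) - 1), 1e-12)
      expect_true(all(row >= 0))
    }
  }
})

test_that("zero-rate table keeps mass in place except deterministic LD receipt", {
  cfg <- scenario_config("DD-LD", start_age = 5)
  zt <- zero_rate_table(tx = 0)
  for (s in setdiff(build_state_space(cfg), c("A2_LD"))) {
    row <- transition_row(s, 20, zt, cfg, fixture$schedule)
    expect_equal(unname(row[s]), 1)
  }
  ld_wait <- transition_row("A2_LD", 20, zt, cfg, fixture$schedule)
  expect_equal(unname(ld_wait["T2_LD"]), 1)
})

test_that("waitlist transplant probability switches at the pediatric/adult boundary", {
  cfg <- scenario_config("DD-LD", start_age = 5)
  zt <- zero_rate_table(tx = 0)
  zt$tx_rates$tx_rate_DD_pediatric <- 0.40
  zt$tx_rates$tx_rate_DD_adult <- 0.15
  r17 <- transition_row("W1", 17, zt, cfg, fixture$schedule)
  r18 <- transition_row("W1", 18, zt, cfg, fixture$schedule)
  expect_equal(unname(r17["T1_DD"]), 1 - exp(-0.40), tolerance = 1e-12)
  expect_equal(unname(r18["T1_DD"]), 1 - exp(-0.15), tolerance = 1e-12)
})

test_that("solve_cohort honours trivial limits", {
  zt <- zero_rate_table()
  res <- solve_cohort(scenario_config("LD-DD", start_age = 25), zt, fixture$schedule)
  expect_equal(res$life_years, 65)
  expect_equal(res$dd_kidneys_used, 0)
  expect_true(all(abs(rowSums(res$occupancy) - 1) < 1e-12))

  # overwhelming dialysis mortality and no way off the list:
  # the DD-first cohort accrues the first cycle only
  hot <- zero_rate_table(tx = 0)
  hot$brackets$dialysis_mortality <- 60
  res2 <- solve_cohort(scenario_config("DD-LD", start_age = 10), hot, fixture$schedule)
  expect_lt(res2$life_years, 1 + 1e-6)
  expect_gte(res2$life_years, 1)  # the first cycle is begun alive
})

test_that("life-years are bounded and occupancy conserves mass on the fixture", {
  for (seqn in all_sequences) {
    cfg <- scenario_config(seqn, start_age = 7)
    res <- solve_cohort(cfg, fixture$table, fixture$schedule)
    expect_lte(res$life_years, 90 - 7)
    expect_gte(res$dd_kidneys_used, 0)
    expect_lte(res$dd_kidneys_used, 3)
    expect_lt(max(abs(rowSums(res$occupancy) - 1)), 1e-9)
    expect_equal(res$survival_curve[1], 1)
    expect_true(all(diff(res$survival_curve) <= 1e-12))
  }
})

test_that("half-cycle correction reduces accrual by at most half the deaths", {
  c_none <- scenario_config("LD-DD", start_age = 10)
  c_half <- scenario_config("LD-DD", start_age = 10, cycle_correction = "half")
  r_none <- solve_cohort(c_none, fixture$table, fixture$schedule)
  r_half <- solve_cohort(c_half, fixture$table, fixture$schedule)
  expect_lt(r_half$life_years, r_none$life_years)
  expect_gt(r_half$life_years, r_none$life_years - 0.5)
})

test_that("net_difference is antisymmetric and guards its inputs", {
  r1 <- solve_cohort(scenario_config("LD-DD", start_age = 10), fixture$table,
                     fixture$schedule)
  r2 <- solve_cohort(scenario_config("DD-LD", start_age = 10), fixture$table,
                     fixture$schedule)
  expect_equal(net_difference(r1, r1)$net_life_years, 0)
  expect_equal(net_difference(r1, r1)$net_dd_kidneys, 0)
  ab <- net_difference(r1, r2)
  ba <- net_difference(r2, r1)
  expect_equal(ab$net_life_years, -ba$net_life_years)
  expect_equal(ab$net_dd_kidneys, -ba$net_dd_kidneys)
  r3 <- solve_cohort(scenario_config("DD-LD", start_age = 12), fixture$table,
                     fixture$schedule)
  expect_error(net_difference(r1, r3), "share start_age")
})

test_that("cohort solver agrees with a quick microsimulation check", {
  cfg <- scenario_config("DD-LD", start_age = 8)
  det <- solve_cohort(cfg, fixture$table, fixture$schedule)
  sim <- simulate_cohort(cfg, fixture$table, fixture$schedule, n = 10000, seed = 11)
  expect_lt(abs(det$life_years - sim$mean_life_years), 3 * sim$se_life_years)
})

test_that("occupancy round-trips through tidy CSV", {
  res <- solve_cohort(scenario_config("LD-DD", start_age = 20), fixture$table,
                      fixture$schedule)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occupancy(res, path)
  df <- read.csv(path)
  expect_setequal(names(df), c("cycle", "age", "state", "probability"))
  back <- matrix(df$probability, nrow = nrow(res$occupancy))
  expect_equal(unname(back), unname(res$occupancy))
})
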