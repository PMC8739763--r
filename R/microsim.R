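#' Simulate a single patient trajectory
#'
#' Individual-level counterpart of [solve_cohort()]: each cycle's move is a
#' single categorical draw from the same transition distribution. Serves as
#' the stochastic oracle for the deterministic cohort solver.
#'
#' @param config A [scenario_config()].
#' @param table A [rate_table()].
#' @param schedule A [candidacy_schedule()].
#' @param rng_seed Integer seed; the trajectory is reproducible given the seed.
#' @return Object of class `trajectory`: data frame `path` with columns
#'   `cycle`, `age`, `state`, plus `life_years_realized` (cycles begun alive)
#'   and `dd_kidneys_realized`.
#' @export
simulate_individual <- function(config, table, schedule = candidacy_schedule(),
                                rng_seed = 1L) {
  sim <- simulate_cohort(config, table, schedule, n = 1L, seed = rng_seed,
                         keep_paths = TRUE)
  path <- data.frame(cycle = seq_len(nrow(sim$paths)) - 1L,
                     age = config$start_age + seq_len(nrow(sim$paths)) - 1L,
                     state = sim$paths[, 1L])
  # truncate after first DEAD entry
  d <- match("DEAD", path$state)
  if (!is.na(d)) path <- path[seq_len(d), ]
  structure(list(path = path,
                 life_years_realized = sim$life_years[1L],
                 dd_kidneys_realized = sim$dd_kidneys[1L]),
            class = "trajectory")
}

#' Simulate many individual trajectories
#'
#' Vectorized microsimulation of `n` independent patients through the
#' scenario's transition structure. The mean of `life_years` converges to
#' [solve_cohort()]'s expectation.
#'
#' @inheritParams simulate_individual
#' @param n Number of individuals.
#' @param seed Integer RNG seed.
#' @param keep_paths If `TRUE`, also return the (cycles+1) x n matrix of
#'   visited state labels.
#' @return List with integer vectors `life_years` and `dd_kidneys` (length
#'   `n`), their means `mean_life_years`, `mean_dd_kidneys`, the Monte Carlo
#'   standard error `se_life_years`, and optionally `paths`.
#' @export
simulate_cohort <- function(config, table, schedule = candidacy_schedule(),
                            n = 1000L, seed = 1L, keep_paths = FALSE) {
  stopifnot(n >= 1)
  tm <- .transition_model(config, table, schedule)
  set.seed(seed)
  S <- length(tm$states)
  dead_j <- match(tm$dead, tm$states)
  dd_j <- match(tm$dd_states, tm$states)
  cur <- rep.int(match(names(tm$init)[tm$init > 0], tm$states), n)
  ly <- integer(n)
  dd <- integer(n)
  n_cycles <- length(tm$ages)
  paths <- if (keep_paths) matrix(NA_character_, n_cycles + 1L, n) else NULL
  if (keep_paths) paths[1L, ] <- tm$states[cur]
  for (t in seq_len(n_cycles)) {
    P <- tm$mats[[t]]
    alive <- cur != dead_j
    ly[alive] <- ly[alive] + 1L
    nxt <- cur
    for (s in unique(cur[alive])) {
      idx <- which(cur == s)
      nxt[idx] <- sample.int(S, length(idx), replace = TRUE, prob = P[s, ])
    }
    dd <- dd + as.integer(nxt %in% dd_j & nxt != cur)
    cur <- nxt
    if (keep_paths) paths[t + 1L, ] <- tm$states[cur]
  }
  out <- list(
    life_years = ly,
    dd_kidneys = dd,
    mean_life_years = mean(ly),
    mean_dd_kidneys = mean(dd),
    se_life_years = stats::sd(ly) / sqrt(n)
  )
  if (keep_paths) out$paths <- paths
  out
}

#' Draw a log-normally perturbed rate table
#'
#' Each targeted age-stratified rate is multiplied by an independent
#' log-normal draw with log-scale mean \eqn{-\sigma^2/2} and log-scale SD
#' \eqn{\sigma}, so the multiplier has expectation 1 and the unperturbed
#' table is the mean of the sampling distribution. Untargeted fields and the
#' scalar transplant rates are unchanged. Uses the current RNG stream.
#'
#' @param table A [rate_table()].
#' @param spec An [uncertainty_spec()].
#' @return A perturbed `rate_table` (still passing all invariants).
#' @export
sample_parameters <- function(table, spec) {
  stopifnot(inherits(table, "rate_table"), inherits(spec, "uncertainty_spec"))
  if (spec$sigma == 0) return(table)
  nb <- nrow(table$brackets)
  for (f in spec$perturbed_fields) {
    mult <- stats::rlnorm(nb, meanlog = -spec$sigma^2 / 2, sdlog = spec$sigma)
    table$brackets[[f]] <- table$brackets[[f]] * mult
  }
  table
}

#' Monte Carlo uncertainty in the net difference between two options
#'
#' Probabilistic sensitivity analysis: for each trial one perturbed rate
#' table is drawn ([sample_parameters()]) and both options are solved on that
#' same table (common random parameters), pairing the draws across options;
#' the 95% CI is the 2.5th/97.5th percentile (order statistics) of the trial
#' net differences. The point estimate comes from the unperturbed solve.
#'
#' @param config1,config2 [scenario_config()] objects sharing `start_age`
#'   and `horizon_age` (option 1 and option 2).
#' @param table A [rate_table()].
#' @param schedule A [candidacy_schedule()].
#' @param spec An [uncertainty_spec()].
#' @return Object of class `uncertainty_result`: `point_estimate` (net
#'   life-years, option 1 minus option 2), `point_dd` (net DD kidneys,
#'   option 2 minus option 1), `ci_low`, `ci_high`, the per-trial vector
#'   `trials`, `n_trials`, `sigma` and `seed`.
#' @export
uncertainty_net_difference <- function(config1, config2, table,
                                       schedule = candidacy_schedule(),
                                       spec = uncertainty_spec()) {
  stopifnot(inherits(config1, "scenario_config"),
            inherits(config2, "scenario_config"),
            inherits(spec, "uncertainty_spec"))
  if (config1$start_age != config2$start_age ||
      config1$horizon_age != config2$horizon_age) {
    stop("options must share start_age and horizon_age", call. = FALSE)
  }
  r1 <- solve_cohort(config1, table, schedule)
  r2 <- solve_cohort(config2, table, schedule)
  point <- net_difference(r1, r2)
  set.seed(spec$seed)
  trials <- numeric(spec$n_trials)
  for (i in seq_len(spec$n_trials)) {
    pt <- sample_parameters(table, spec)
    trials[i] <- solve_cohort(config1, pt, schedule)$life_years -
      solve_cohort(config2, pt, schedule)$life_years
  }
  ci <- unname(stats::quantile(trials, c(0.025, 0.975), type = 1))
  structure(list(
    point_estimate = point$net_life_years,
    point_dd = point$net_dd_kidneys,
    ci_low = ci[1],
    ci_high = ci[2],
    trials = trials,
    n_trials = spec$n_trials,
    sigma = spec$sigma,
    seed = spec$seed
  ), class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> net life-years %.2f (95%% CI %.2f to %.2f; %d trials, sigma %.3g)\n",
              x$point_estimate, x$ci_low, x$ci_high, x$n_trials, x$sigma))
  invisible(x)
}

#' Persist per-trial uncertainty results as CSV
#'
#' @param result An `uncertainty_result`.
#' @param path Output CSV path; columns `trial`, `net_life_years`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(result, path) {
  stopifnot(inherits(result, "uncertainty_result"))
  utils::write.csv(
    data.frame(trial = seq_along(result$trials), net_life_years = result$trials),
    path, row.names = FALSE)
  invisible(path)
}
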