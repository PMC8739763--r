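#' @title Markov engine: state space, transition rows, cohort solver
#' @description Internal helpers plus the exported [build_state_space()],
#'   [transition_row()], [solve_cohort()] and [net_difference()].
#' @name markov_engine
#' @keywords internal
NULL

.sequence_sources <- function(sequence) {
  switch(sequence,
         "LD-DD" = c("LD", "DD"),
         "DD-LD" = c("DD", "LD"),
         "DD-DD" = c("DD", "DD"),
         "LD-LD" = c("LD", "LD"),
         stop("unknown sequence: ", sequence, call. = FALSE))
}

# Preemption probability for the (k+1)-th transplant of realized source r.
.preempt_prob <- function(config, next_k, src) {
  if (next_k >= 3) return(0)  # third transplant is never preemptive
  if (config$force_preemptive) return(1)
  if (src == "LD") config$preemptive_prob_LD else config$preemptive_prob_DD
}

#' Enumerate the reachable model states for a scenario
#'
#' States are labelled by stage and transplant index: `W1` (waiting list
#' before the first transplant, DD-first sequences only), `T<k>_<src>`
#' (functioning k-th graft from source `src`), `A<k>_<src>` (failed graft,
#' awaiting the k-th transplant of resolved source `src`), `NX` (dialysis
#' with no further transplant option) and the absorbing `DEAD`. Only states
#' reachable under the configured sequence, availability, preemption and
#' third-transplant settings are included; the ordering is deterministic.
#'
#' @param config A [scenario_config()].
#' @return Character vector of state labels.
#' @export
build_state_space <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  src <- .sequence_sources(config$sequence)
  states <- character(0)
  if (src[1] == "DD") states <- c(states, "W1")
  states <- c(states, paste0("T1_", src[1]))
  second <- if (src[2] == "LD") {
    if (config$ld_available_prob < 1) c("LD", "DD") else "LD"
  } else "DD"
  for (r in second) {
    if (.preempt_prob(config, 2L, r) < 1) states <- c(states, paste0("A2_", r))
    states <- c(states, paste0("T2_", r))
  }
  if (config$third_tx_enabled) states <- c(states, "A3_DD", "T3_DD")
  c(states, "NX", "DEAD")
}

# Per-age (0..89) rate lookups resolved once per solve: a matrix with one row
# per year of age. Scenario rate substitutions must already be applied.
.age_rate_matrix <- function(table, config) {
  ages <- 0:89
  b <- table$brackets[order(table$brackets$age_lo), ]
  i <- findInterval(ages, b$age_lo)
  tx_ped <- table$tx_rates$tx_rate_DD_pediatric
  tx_adult <- table$tx_rates$tx_rate_DD_adult
  cbind(
    dialysis_mortality = b$dialysis_mortality[i],
    graft_mortality = b$graft_mortality[i],
    graft_failure_LD = b$graft_failure_LD[i],
    graft_failure_DD = b$graft_failure_DD[i],
    tx_rate_waitlist = ifelse(ages < 18, tx_ped, tx_adult),
    tx_rate_third = table$tx_rates$tx_rate_third
  )
}

# Assemble the full transition matrix at a single age. `rv` is one row of
# .age_rate_matrix; `cand` is the (multiplier-scaled) candidacy at this age.
.transition_matrix <- function(states, rv, cand, config) {
  S <- length(states)
  P <- matrix(0, S, S, dimnames = list(states, states))
  idx <- stats::setNames(seq_len(S), states)
  add <- function(row, to, mass) {
    if (mass == 0) return(invisible())
    j <- idx[to]
    if (is.na(j)) stop("transition into unreachable state ", to, call. = FALSE)
    P[row, j] <<- P[row, j] + mass
  }
  max_tx <- if (config$third_tx_enabled) 3L else 2L
  src2 <- .sequence_sources(config$sequence)[2]

  # mass leaving a failed graft k, heading toward transplant k+1
  route_failure <- function(row, k, mass) {
    next_k <- k + 1L
    if (next_k > max_tx) {
      add(row, "NX", mass)
      return(invisible())
    }
    add(row, "NX", mass * (1 - cand))
    m <- mass * cand
    planned <- if (next_k == 2L) src2 else "DD"
    branches <- if (planned == "LD") {
      c(LD = m * config$ld_available_prob,
        DD = m * (1 - config$ld_available_prob))
    } else c(DD = m)
    for (r in names(branches)) {
      mr <- branches[[r]]
      if (mr == 0) next
      pe <- .preempt_prob(config, next_k, r)
      add(row, paste0("T", next_k, "_", r), mr * pe)
      add(row, paste0("A", next_k, "_", r), mr * (1 - pe))
    }
  }

  for (s in states) {
    if (s == "DEAD") {
      P[s, s] <- 1
    } else if (s == "NX") {
      pd <- rate_to_prob(rv[["dialysis_mortality"]])
      add(s, "DEAD", pd)
      P[s, s] <- 1 - pd
    } else if (s == "W1") {
      cr <- competing_risk_probs(c(rv[["dialysis_mortality"]], rv[["tx_rate_waitlist"]]))
      add(s, "DEAD", cr$event[1])
      add(s, paste0("T1_", .sequence_sources(config$sequence)[1]), cr$event[2])
      P[s, s] <- P[s, s] + cr$stay
    } else if (grepl("^T", s)) {
      k <- as.integer(substr(s, 2, 2))
      gsrc <- sub("^T._", "", s)
      gf <- if (gsrc == "LD") rv[["graft_failure_LD"]] else rv[["graft_failure_DD"]]
      cr <- competing_risk_probs(c(rv[["graft_mortality"]], gf))
      add(s, "DEAD", cr$event[1])
      route_failure(s, k, cr$event[2])
      P[s, s] <- P[s, s] + cr$stay
    } else if (grepl("^A", s)) {
      k <- as.integer(substr(s, 2, 2))
      wsrc <- sub("^A._", "", s)
      live <- 1
      if (config$recheck_candidacy) {
        add(s, "NX", (1 - cand))
        live <- cand
      }
      if (wsrc == "LD") {
        pd <- rate_to_prob(rv[["dialysis_mortality"]])
        w <- config$ld_wait_receipt_prob
        add(s, "DEAD", live * pd)
        add(s, paste0("T", k, "_LD"), live * (1 - pd) * w)
        P[s, s] <- P[s, s] + live * (1 - pd) * (1 - w)
      } else {
        txr <- if (k == 2L) rv[["tx_rate_waitlist"]] else rv[["tx_rate_third"]]
        cr <- competing_risk_probs(c(rv[["dialysis_mortality"]], txr))
        add(s, "DEAD", live * cr$event[1])
        add(s, paste0("T", k, "_DD"), live * cr$event[2])
        P[s, s] <- P[s, s] + live * cr$stay
      }
    } else {
      stop("unrecognised state label: ", s, call. = FALSE)
    }
  }
  P
}

# Precompute transition matrices for every cycle age of a scenario.
# Returns list(states, mats = list over ages start..horizon-1, init, dd_idx).
.transition_model <- function(config, table, schedule) {
  tbl <- apply_scenario_overrides(table, config)
  states <- build_state_space(config)
  rv <- .age_rate_matrix(tbl, config)
  ages <- config$start_age:(config$horizon_age - 1L)
  cand <- candidacy_at_age(ages, schedule, config$candidacy_multiplier)
  mats <- lapply(seq_along(ages), function(i) {
    a <- ages[i]
    row <- if (a <= 89) rv[a + 1L, ] else rv[90L, ]  # horizon is 90; ages stay < 90
    .transition_matrix(states, row, cand[i], config)
  })
  init <- stats::setNames(numeric(length(states)), states)
  start_state <- if (.sequence_sources(config$sequence)[1] == "LD") {
    paste0("T1_LD")  # received at time zero without waiting
  } else "W1"
  init[start_state] <- 1
  list(states = states, ages = ages, mats = mats, init = init,
       dd_states = grep("^T._DD$", states, value = TRUE),
       dead = "DEAD")
}

#' One-cycle transition distribution from a state
#'
#' Builds the probability distribution over next-cycle states for a patient
#' in `state` at `age`, under the given rates, scenario and candidacy
#' schedule. From a functioning graft the competing events are death with
#' function and graft failure; failure mass splits by candidacy at the
#' current age, live-donor availability (when the planned next graft is an
#' LD), then preemption. From waiting states the competing events are
#' dialysis death and transplant (pediatric rate below 18, adult rate from
#' 18, the third-transplant rate while awaiting a third graft).
#'
#' @param state State label from [build_state_space()].
#' @param age Age in years at the start of the cycle.
#' @param table A `rate_table` (scenario overrides are applied internally).
#' @param config A `scenario_config`.
#' @param schedule A `candidacy_schedule`.
#' @return Named numeric vector over the state space, summing to 1.
#' @export
transition_row <- function(state, age, table, config, schedule = candidacy_schedule()) {
  tbl <- apply_scenario_overrides(table, config)
  states <- build_state_space(config)
  if (!state %in% states) stop("state not in the scenario's state space: ", state, call. = FALSE)
  rv <- .age_rate_matrix(tbl, config)[age + 1L, ]
  cand <- candidacy_at_age(age, schedule, config$candidacy_multiplier)
  .transition_matrix(states, rv, cand, config)[state, ]
}

#' Solve the cohort model
#'
#' Propagates the state-occupancy distribution through yearly cycles from
#' `start_age` to `horizon_age`, accruing expected life-years (one year per
#' cycle begun alive by default, or a half-cycle-corrected average) and the
#' expected number of deceased-donor kidneys received (probability flux into
#' any functioning-DD-graft state).
#'
#' @param config A [scenario_config()].
#' @param table A [rate_table()].
#' @param schedule A [candidacy_schedule()].
#' @return Object of class `cohort_result` with elements `life_years`,
#'   `dd_kidneys_used`, `occupancy` (cycles+1 x states matrix; row `i` is the
#'   distribution at age `start_age + i - 1`), `survival_curve`, `start_age`,
#'   `horizon_age` and the `config`.
#' @export
solve_cohort <- function(config, table, schedule = candidacy_schedule()) {
  stopifnot(inherits(config, "scenario_config"), inherits(table, "rate_table"))
  tm <- .transition_model(config, table, schedule)
  n_cycles <- length(tm$ages)
  S <- length(tm$states)
  occ <- matrix(0, n_cycles + 1L, S, dimnames = list(NULL, tm$states))
  occ[1L, ] <- tm$init
  dead_j <- match(tm$dead, tm$states)
  dd_j <- match(tm$dd_states, tm$states)
  half <- identical(config$cycle_correction, "half")
  ly <- 0
  dd <- 0
  surv <- numeric(n_cycles + 1L)
  surv[1L] <- 1
  cur <- tm$init
  for (t in seq_len(n_cycles)) {
    P <- tm$mats[[t]]
    nxt <- as.vector(cur %*% P)
    alive0 <- 1 - cur[dead_j]
    alive1 <- 1 - nxt[dead_j]
    ly <- ly + if (half) (alive0 + alive1) / 2 else alive0
    if (length(dd_j)) {
      dd <- dd + sum(nxt[dd_j]) - sum(cur[dd_j] * diag(P)[dd_j])
    }
    occ[t + 1L, ] <- nxt
    surv[t + 1L] <- alive1
    cur <- nxt
  }
  structure(list(
    life_years = as.numeric(ly),
    dd_kidneys_used = as.numeric(dd),
    occupancy = occ,
    survival_curve = surv,
    start_age = config$start_age,
    horizon_age = config$horizon_age,
    config = config
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s, start age %d, horizon %d\n",
              x$config$sequence, x$start_age, x$horizon_age))
  cat(sprintf("  expected remaining life-years: %.2f\n", x$life_years))
  cat(sprintf("  expected DD kidneys used:      %.3f\n", x$dd_kidneys_used))
  invisible(x)
}

#' Net difference between two cohort results
#'
#' Convention follows the comparison tables: net life-years are option 1
#' minus option 2, while net deceased-donor kidneys are option 2 minus
#' option 1 (the extra DD organs the second strategy consumes).
#'
#' @param result1,result2 `cohort_result` objects sharing `start_age` and
#'   `horizon_age`.
#' @return List with `net_life_years` and `net_dd_kidneys`.
#' @export
net_difference <- function(result1, result2) {
  stopifnot(inherits(result1, "cohort_result"), inherits(result2, "cohort_result"))
  if (result1$start_age != result2$start_age ||
      result1$horizon_age != result2$horizon_age) {
    stop("results must share start_age and horizon_age", call. = FALSE)
  }
  list(net_life_years = result1$life_years - result2$life_years,
       net_dd_kidneys = result2$dd_kidneys_used - result1$dd_kidneys_used)
}

#' Write a state-occupancy trajectory as tidy CSV
#'
#' @param result A `cohort_result`.
#' @param path Output CSV path; columns `cycle`, `age`, `state`, `probability`.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(result, path) {
  stopifnot(inherits(result, "cohort_result"))
  occ <- result$occupancy
  df <- data.frame(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    age = rep(result$start_age + seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    probability = as.vector(occ)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
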