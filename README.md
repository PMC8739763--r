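# txseq

Decision-analytic Markov cohort model for **kidney transplant sequencing** in
young recipients: if a patient aged 3–25 with kidney failure has a live donor
(LD) available, should they use that kidney first and fall back on a deceased
donor (DD) if the graft fails (LD-DD), or take a DD kidney first — pediatric
recipients are heavily prioritized on the DD waiting list — and hold the LD in
reserve (DD-LD)? `txseq` answers in expected remaining life-years and in
expected DD organs consumed per recipient, for all four sequences LD-DD,
DD-LD, DD-DD and LD-LD.

## The model

Patients move through yearly cycles between health states — waiting list /
dialysis, functioning k-th graft (k ≤ 3, by donor source), failed graft
awaiting retransplant, dialysis with no further transplant option, dead —
from their starting age until age 90. Annual event rates are age-stratified
and converted to per-cycle transition probabilities under a constant-hazard
assumption:

- `p = 1 − exp(−r)` for a single event with annual rate `r`;
- competing events within a cycle are resolved by proportional-hazards
  allocation, `p_i = (r_i / Σr)(1 − exp(−Σr))`, so each row sums to 1 exactly;
- annual graft-loss rates derive from 5-year failure probabilities,
  `r = −ln(1 − p₅)/5`.

Structural assumptions (all configurable through `scenario_config()`): an
LD-first transplant happens at time zero without waiting; DD transplant rates
are 0.40 per patient-waiting-year below age 18 and 0.15 from 18 (0.12 while
awaiting a third graft); at graft failure, retransplant candidacy declines
with age (100% through 30, 80% by 50, 30% by 60, 5% by 70, 0 by 80); a planned
second LD is unavailable 10% of the time, after which the pathway becomes
DD-DD; second transplants are preemptive with probability 0.20 (LD) / 0.15
(DD); the third transplant is always DD and never preemptive.

Expected outcomes come from deterministic propagation of the state-occupancy
vector (`solve_cohort()`), cross-validated against an individual-level
microsimulation (`simulate_cohort()`). Uncertainty is probabilistic
sensitivity analysis: mean-one log-normal multipliers on the age-stratified
mortality and graft-failure rates, both options solved on each perturbed
table (common random parameters), percentile 95% CI over the trials
(`uncertainty_net_difference()`).

Because the registry tables behind the published analysis are not deposited,
the package ships a clearly-synthetic `calibration_fixture()` plus a seeded
generator (`generate_rate_tables()`) that reproduce the *structure* of those
inputs: very high waiting-list mortality at ages 3–9 versus 10–13, a
graft-loss peak at ages 14–25, and LD failure rates 40–60% below DD outside
ages 10–24 but only 20–40% below within.

## Worked example

```r
library(txseq)
fx <- calibration_fixture()

r1 <- solve_cohort(scenario_config("LD-DD", start_age = 5), fx$table, fx$schedule)
r2 <- solve_cohort(scenario_config("DD-LD", start_age = 5), fx$table, fx$schedule)
r1
#> <cohort_result> LD-DD, start age 5, horizon 90
#>   expected remaining life-years: 44.46
#>   expected DD kidneys used:      1.019
r2
#> <cohort_result> DD-LD, start age 5, horizon 90
#>   expected remaining life-years: 42.47
#>   expected DD kidneys used:      1.338

uncertainty_net_difference(
  scenario_config("LD-DD", start_age = 5),
  scenario_config("DD-LD", start_age = 5),
  fx$table, fx$schedule,
  uncertainty_spec(n_trials = 200, sigma = 0.10, seed = 42))
#> <uncertainty_result> net life-years 1.99 (95% CI 1.23 to 2.63; 200 trials, sigma 0.1)
```

Read: on the synthetic fixture, a five-year-old choosing LD-first gains about
2.0 expected life-years over DD-first and consumes about 0.32 fewer deceased
donor kidneys; the CI excludes zero. `age_sweep(3:25, ...)` shows the
characteristic U-shape: the advantage shrinks (here, reverses slightly)
around starting ages 10–15, where waiting-list mortality is lowest and the
pediatric DD transplant rate is highest, and grows again after 18 when the
adult transplant rate applies.

Scenario grids mirror the published comparisons: `run_baseline_grid()`
(availability triplet per age), `run_no_ld_grid()` (LD-DD vs DD-DD with
lower-candidacy and no-third-transplant variants), `run_sensitivity_suite()`
(availability sweep, adult pediatric rate, candidacy, preemption, equalized
young mortality, halved LD failure at 10–24).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/txseq", package = "txseq"))')
Rscript "$CLI" compare --start-age 5 --option1 LD-DD --option2 DD-LD \
        --trials 1000 --seed 7 --out out/
Rscript "$CLI" simulate-data --seed 12 --out data/   # synthetic rate-table CSV
```

Subcommands: `run`, `compare`, `sweep`, `sensitivity`, `simulate-data`,
`report`. Every run writes a `manifest.json` (seed, config echo, input
checksums); identical invocations produce identical outputs.

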