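---
title: "Modelling kidney transplant sequencing with txseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling kidney transplant sequencing with txseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txseq)
```

## The decision problem

A young patient (starting age 3–25) with kidney failure who has a willing
live donor (LD) can either use that kidney immediately, keeping a deceased
donor (DD) transplant as the fallback (**LD-DD**), or join the DD waiting
list first — pediatric candidates enjoy a DD transplant rate of 0.40 per
patient-waiting-year against 0.15 for adults — and keep the LD in reserve
(**DD-LD**). The reserve strategy risks the donor no longer being available
years later; the immediate strategy spends the LD while DD access is at its
best. `txseq` quantifies the trade-off in expected remaining life-years and
in expected DD kidneys consumed, to age 90, for the four sequences LD-DD,
DD-LD, DD-DD and LD-LD.

## Model structure

One cycle is one year. The state space (built per scenario by
`build_state_space()`) comprises: the pre-first-transplant waiting list
(`W1`, DD-first sequences only — LD-first recipients are transplanted at
time zero without waiting), a functioning k-th graft by donor source
(`T1_LD` … `T3_DD`, at most three transplants, the third always DD), failed
graft awaiting a resolved-source retransplant (`A2_LD`, `A2_DD`, `A3_DD`),
dialysis with no further transplant option (`NX`), and absorbing `DEAD`.

From a functioning graft the competing events are death-with-function and
death-censored graft failure. Failure mass is routed through three ordered
splits:

1. **Candidacy**, evaluated once at the age of failure: the probability of
   being medically eligible for retransplant is 1 through age 30, then
   declines piecewise-linearly through (50, 0.8), (60, 0.3), (70, 0.05) to
   (80, 0). Linear interpolation is our choice — only the anchor ages are
   anchored by the source schedule — and the anchors are configurable.
   Non-candidates move to `NX` permanently. A `recheck_candidacy` flag
   re-draws eligibility every waiting cycle instead; it is off by default
   because the schedule is indexed to age at failure.
2. **Availability**, when the *planned* next graft is an LD (the second
   graft in DD-LD and in LD-LD): a single Bernoulli split with success
   probability `ld_available_prob` (default 0.90). On failure the remaining
   pathway becomes DD-DD. Resolving availability before preemption lets the
   preemption probability depend on the realized source.
3. **Preemption**: with probability 0.20 (LD) or 0.15 (DD) the second
   transplant happens in the same cycle, without a return to dialysis;
   otherwise the patient enters the awaiting state. The third transplant is
   never preemptive. `force_preemptive = TRUE` (the "always available and
   preemptive" scenario) forces the second transplant only.

A non-candidate cannot receive a preemptive graft: candidacy is applied
first. This ordering is an assumption — the source framing does not pin it
down — and we flag it here because reversing it would inflate transplant
counts among non-candidates.

While awaiting an LD, the graft arrives the next cycle with probability 1
(`ld_wait_receipt_prob`, configurable): an LD is assumed always faster than
the waiting list. While awaiting a DD, receipt competes with dialysis death
at the waitlist rate (pediatric under 18, adult from 18; 0.12 for a third
graft).

## Rates, probabilities and numerical conventions

All inputs are annual rates per person-year in half-open age brackets
tiling [0, 90). Within a bracket and within a cycle the hazard is constant,
giving `p = 1 − exp(−r)` per cycle and `r = −ln(1 − p₅)/5` for the 5-year
graft-failure probabilities the failure rates derive from. Competing events
use proportional-hazards allocation `p_i = (r_i/Σr)(1 − exp(−Σr))`; unlike
sequential conditioning this is order-invariant, and rows sum to 1 to
machine precision (tested at 1e−12).

Life-years accrue one full year per cycle begun alive; `cycle_correction =
"half"` averages start- and end-of-cycle survival instead. The default is
"none" because the source analysis does not mention a half-cycle
correction; the toggle exists because cohort software commonly offers both,
and the gap between conventions is bounded by half the cycle deaths.

DD kidney use is the probability flux into any functioning-DD-graft state
from a different state (self-loops are staying, not a new organ), so it is
an expectation in [0, 3].

Starting ages outside 3–25 are rejected rather than extrapolated: the rate
structure below 3 (infant dialysis) and the sequencing question itself are
out of the modelled range.

## Uncertainty analysis

The published 95% CIs come from "Monte Carlo microsimulation (1000
trials)". Because those CIs attach to the *net difference between options*,
which individual-level noise alone cannot pair, we interpret the procedure
as probabilistic sensitivity analysis: each trial draws one perturbed rate
table and solves **both** options on it (common random parameters), and the
CI is the 2.5th/97.5th percentile — order statistics, distribution-free —
of the trial net differences. A pure individual-level mode
(`simulate_cohort()`, `simulate_individual()`) exists and serves as the
oracle for the deterministic solver. Both the pairing and the dispersion
are exposed in `uncertainty_spec()` and echoed in output metadata, since
the source states neither.

Perturbations are log-normal multipliers on the age-stratified mortality
and graft-failure rates, with log-scale mean −σ²/2 so the multiplier has
expectation 1 and the unperturbed table is the mean of the sampling
distribution — this keeps the point estimate interpretable. σ defaults to
0.10 per rate: the source gives no dispersion, and 0.10 puts ~95% of
multipliers within ±20%, a typical registry-uncertainty scale. At σ = 0 the
CI degenerates to the point estimate (tested).

## What the synthetic data do and do not establish

The registry rate tables behind the published numbers are not deposited.
`generate_rate_tables()` draws tables with the structure that analysis
relies on — dialysis mortality above with-graft mortality in every bracket;
waiting-list mortality at ages 3–9 well above ages 10–13 (default excess
ratio 2.5; set to 1 for the equalized-mortality scenario); a graft-loss
peak in brackets starting at ages 14–25; LD failure 40–60% below DD outside
ages 10–24 but only 20–40% below within — and verifies every constraint
programmatically before returning. One numerical guard: because the 10–13
bracket draws the narrow LD/DD gap but sits outside the failure peak, its
LD rate is capped below the peak-bracket LD minimum so the peak stays a
maximum for both sources.

`calibration_fixture()` is a frozen, deterministic table whose magnitudes
were chosen (and iterated a few times, as documented in its help page) so
that the *qualitative* published pattern emerges: LD-first superiority at
starting ages 3, 5, 20 and 25, a much smaller gap at 10–15, dominance
orderings LD-LD ≥ LD-DD ≥ DD-DD, and higher DD-kidney use under DD-first. A
green directional test therefore establishes that the mechanism reproduces
the shape of the published results under structurally faithful inputs — it
does **not** establish numeric agreement with the published life-year
tables, which would require the actual registry inputs transcribed into the
CSV schema (`read_rate_table()` accepts them directly, including
per-100-person-year units).

## Scenario grids

`run_baseline_grid()` reproduces the availability triplet (10% unavailable /
always available / always available and preemptive) per starting age with
LD-DD fixed as option 1; `run_no_ld_grid()` compares against DD-DD under
baseline, 20%-lower-candidacy and no-third-transplant variants — both
applied to *both* arms, which is what makes the option-1 column move in the
published table; `run_sensitivity_suite()` covers the six sensitivity items,
with the availability sweep on the grid {0, 0.25, 0.5, 0.75, 1} (the source
examined "the entire range"; the grid is our discretization).
"20% lower candidacy" is implemented as multiplying the age-specific
candidacy by 0.8 — the simplest reading of an operation the source does not
define, and labelled as such in output. The composite figure scenario
(optimal + equalized young mortality + adult DD rate for children) is the
`"composite_uniform"` preset of `scenario_preset()`.

## Known limitations

No sensitization or HLA dynamics (second-transplant rates are not reduced),
no donor-quality stratification, no memory of time-on-dialysis effects on
post-transplant survival, no costs or QALY weighting, no discounting. The
transplant-rate pediatric/adult split is the only age dependence of the
waitlist rate; whether the source stratified it further is unknown. Whether
patients ageing past a candidacy threshold *while waiting* should be
delisted is likewise unstated; the default keeps them listed, and
`recheck_candidacy` approximates the alternative.
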