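---
title: "A Markov cohort model for colorectal cancer screening strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for colorectal cancer screening strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

This vignette is the package's account of its science: the cohort model and
its assumptions, the parameters that matter, the conventions we had to fix
where the published base case leaves room, and what the packaged synthetic
inputs do and do not emulate.

## The decision problem

Four strategies are compared for a closed cohort of 100,000 average-risk
persons aged 50, followed through age 75 (26 annual cycles): yearly FIT,
yearly M3CRC (a stool bacterial biomarker panel read together with FIT),
colonoscopy every 10 years, and no screening. Stool-test positives proceed to
colonoscopy workup; polypectomy triggers surveillance colonoscopy every
3 years until a polyp-free examination, after which routine screening resumes
10 years later. The outcome measures are cancer cases prevented, discounted
life-years saved, and incremental cost-effectiveness ratios (ICERs) in USD
per life-year saved.

The model is an expected-value (fractional-person) cohort model: occupancy
masses flow deterministically between compartments, so results carry no Monte
Carlo error and need no seed. Compartments track the screening schedule
(due now; waiting *k* years after a normal colonoscopy; waiting *k* years for
surveillance), never-attenders, diagnosed cancer by stage and years since
diagnosis, cure, and three death states (cancer, other cause, procedure).
Conservation of the cohort is asserted at every cycle to $10^{-6}$ persons;
a breach aborts the run with the cycle index.

## Parameters

All probabilities are fractions in $[0,1]$ (configuration files may declare
`units: percent`). The base case bundles:

* test operating characteristics — FIT 73.0%/91.9% against preclinical CRC;
  M3CRC 66.5%/83.8% against the composite of non-advanced adenoma, advanced
  adenoma and CRC. Each test needs a target prevalence to turn these into a
  per-round positivity, `sens·π + (1−spec)(1−π)`. We use π = 0.004 for FIT
  (average-risk CRC prevalence) and π = 0.289 for M3CRC (23.9% + 4.6% + 0.4%,
  the published worldwide prevalences of the three composite components). An
  alternative suggested derivation — backing the composite prevalence out of
  the M3 polypectomy rate by Bayes' rule — yields π ≈ 0.56, which is far
  outside any published adenoma prevalence, so the direct published figures
  are used;
* compliance — 60% (FIT), 99% (M3CRC), 98.9% (colonoscopy), 100% for workup
  after a positive stool test. One knob per arm drives initial, repeated and
  surveillance offers alike;
* prevention fractions — 21.0% (FIT), 51.5% (M3CRC), 54.0% (colonoscopy):
  the fraction of cancers averted among actively covered persons, applied as
  an incidence multiplier `1 − prevention × covered`. `covered` counts this
  cycle's compliers plus everyone inside a surveillance or post-colonoscopy
  interval, divided by the living undiagnosed cohort;
* polypectomy rates — 73.0% at FIT-positive workup, 83.9% at M3CRC-positive
  workup. No rate is published for primary screening colonoscopies or for
  surveillance examinations; both default to 0.722, the therapeutic fraction
  implied by the published colonoscopy-arm procedure mix (367,841 of
  509,496). Giving surveillance its own arm-independent rate matters: polyp
  recurrence belongs to the patient, not to the stool test that referred
  them, and reusing the M3 workup rate (83.9%) at surveillance would give
  M3-arm patients systematically longer surveillance chains than
  colonoscopy-arm patients, inverting the published total-cost ordering;
* complications per colonoscopy — bleeding 0.98% (USD 3,320), perforation
  0.08% (USD 10,790), death 0.0029%. The death rate is read per colonoscopy,
  not per perforation, because it is listed alongside the per-procedure
  rates; a flag (`perforation_mortality_basis`) selects the other reading.
  Published bleeding counts are inconsistent with the printed 0.98% under
  any denominator we can identify (1,019 bleeds over 509,496 colonoscopies
  is ≈0.2%); we follow the printed rate and flag, rather than silently
  calibrate, the discrepancy;
* stage model — distribution at diagnosis 11.3/25.4/32.4/31.0% (stages
  I–IV), annual mortality 1.0/4.5/8.7/43.0%, care packages 17,071 / 19,755 /
  26,883 / 45,116 USD (diagnosis 6,091 + stage-specific treatment +
  follow-up 603; the printed stage-IV total is 45,115, one dollar below the
  sum of its own printed components, and the sum is used). The printed stage
  distribution sums to 100.1%; it is renormalised so that stage assignment
  conserves cases exactly, since cohort conservation is a hard invariant;
* incidence — 55.9, 89.8, 137, 200, 253.2, 330.5 per 100,000 across
  quinquennial ages 50–75;
* economics — 3%/year discount for costs and life-years; USD.

## The synthetic life table

The published analysis uses a national standard life table that is not
distributed with it. The package generates a stand-in from a Gompertz-type
hazard, $q(a) = 1 - \exp(-\lambda e^{\gamma (a-50)})$, closed at age 100.
The frozen constants $\lambda = 0.0024$, $\gamma = 0.10$ give
$q(50) = 0.0024$, survival to 75 of 0.774 and residual life expectancy at 50
of 32.9 years — Hong-Kong-like values, with the classic adult log-hazard
slope of about 0.1 per year. The constants live in one place
(`hk_life_table()`) and a real table can replace them via a two-column text
file (`read_life_table()`).

What this emulates: realistic competing mortality for a 50–75 cohort and a
plausible residual-life-expectancy scale for valuing premature deaths. What
it does not: the exact national table behind the published totals. Absolute
life-year quantities are therefore approximate by construction, and the
package's tests treat them as such: orderings and relative comparisons are
asserted against the published table, absolute life-year totals are not.

## Conventions and numerical choices

Where the published description is silent, a convention had to be fixed.
Each is a flag in `crc_parameters()$conventions`; defaults below.

* **Event timing** — screening at cycle start; incidence, deaths and care
  costs mid-cycle (`half_cycle = "mid"`, the standard half-cycle
  correction); costs discounted at their event time.
* **Case counting** (`discount_cases = FALSE`) — case tallies are reported
  undiscounted, the standard practice (discounting applies to costs and
  life-years). The published text suggests cases may also have been
  discounted; the flag provides that reading. Undiscounted counting is also
  the only reading compatible with the published no-screening total of 3,233
  cases under any Hong-Kong-like life table: the packaged base case yields
  3,487 undiscounted and about 2,200 discounted.
* **Life-years lost** — a cancer or procedure death at age $a$ in cycle $t$
  forfeits $\sum_{u\ge0} S(a+u\mid a)\,w(u)\,(1+d)^{-(t+\frac12+u)}$
  life-years, the half-cycle-weighted, discounted residual life expectancy
  (`ly_discount_from = "model_start"`; `"event"` drops the $t$ offset).
* **Compliance** (`compliance_model = "never"`) — the cohort splits at the
  first offer into lifetime attenders and never-attenders; attenders comply
  with every subsequent offer. The alternative (`"recurrent"`) redraws
  compliance independently each round. Participation in real programmes is
  strongly autocorrelated, and only the attender/never-attender reading
  reproduces the published direction of the compliance sensitivity analysis
  (ICER rising as compliance falls): under recurrent offers the marginal
  covered person-year shifts into the costly workup/surveillance states as
  compliance rises, and the ICER slope inverts. The two models coincide at
  100% compliance.
* **Diagnosed mortality** (`diagnosed_mortality = "replace"`) — stage
  mortality replaces background mortality when larger, avoiding double
  counting; an additive-hazards alternative sits behind the flag. Stage
  mortality starts the cycle after diagnosis; diagnosed patients are no
  longer at risk of a second incident cancer.
* **Cure** (`cure_horizon_years = 5`) — stages I–III leave the care model
  (no further cost or excess mortality) after five recurrence-free years,
  the top of the published three-to-five-year range; stage IV remains at
  risk until death. Cured patients do not re-enter the incidence pool.
* **Bleeding scope** (`bleeding_scope = "all"`) — complications are charged
  per colonoscopy performed, matching the published perforation arithmetic;
  `"therapeutic"` restricts bleeding to polypectomies.
* **Sweeps** — deterministic grids; threshold detection by bisection to a
  caller-chosen tolerance (default $10^{-4}$, suited to fractional
  parameters; use ~1 USD for cost parameters). Sweeps never mutate their
  input parameters.
* **Degenerate comparisons** — equal effects give an `undefined` flag;
  costlier-and-less-effective gives `dominated`; cheaper-and-more-effective
  reports the negative ratio with a `dominant` flag. No ratio is ever
  produced by silent division.

## Problem sizes

The packaged base case (100,000 persons, 26 cycles, four arms) runs in under
a second; the test suite's sensitivity sweeps use 5–10 point grids per
parameter and a bisection tolerance of 0.005 on test specificity, which keeps
the full suite in the low minutes while exercising every directional claim.

## Known limitations and divergences

* The published spreadsheet's procedure totals cannot be derived from its
  stated schedules: its FIT arm performs 236,913 tests over 26 years
  (about four per complier), implying an unstated participation-attrition
  assumption, and its M3CRC arm's 419,173 colonoscopies imply a per-round
  positivity below the floor $1-\text{spec} = 16.2\%$ set by its own printed
  specificity. A schedule-faithful engine therefore produces more procedures
  in the stool arms than the published table.
* The published per-stage care-cost totals (for example USD 170k per
  incident stage-IV case) exceed anything the printed stage packages and
  follow-up cost can generate; the ongoing-cost rule behind them is not
  stated. The package charges the printed package at diagnosis plus printed
  annual follow-up, and consequently carries a smaller care-cost mass.
* Both gaps compress the spread between the M3CRC and colonoscopy ICERs
  relative to the published base case. Directional claims survive (M3CRC's
  ICER rises as its specificity falls, and a crossing with colonoscopy
  exists), but the crossing sits nearer the base-case specificity than the
  published 20–50% band, and at very low colonoscopy prices the two arms'
  ICERs can swap.
* No adenoma natural-history submodel: prevention is a single published
  fraction per strategy, so stage-shift benefits of earlier detection are
  not modelled, and the stage distribution at diagnosis is identical across
  arms.
* Life-years only; no quality-of-life weighting, no indirect costs, no
  probabilistic sensitivity analysis — matching the scope of the published
  comparison.
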