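---
title: "Methods: the lifetime Markov cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lifetime Markov cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmscea)
```

## The decision problem

Two disease-modifying therapies (DMTs) for relapsing-remitting multiple
sclerosis (RRMS) — rituximab (1000 mg six-monthly) and natalizumab
(300 mg monthly) — differ sharply in annual acquisition cost and in
annual relapse probability. The package frames the comparison as a
cost-utility analysis from the societal perspective: which strategy
buys more quality-adjusted life years (QALYs) at what incremental cost
over a patient's remaining lifetime?

## Model structure and assumptions

The disease course is modelled as an annual-cycle Markov cohort over
four living Expanded Disability Status Scale (EDSS) bands — 0–2.5 and
3–5.5 (RRMS, on DMT) and 6–7.5 and 8–9.5 (secondary progressive, SPMS;
DMT stopped on entry) — plus absorbing death. Key assumptions:

* **Markov property.** Next-cycle state depends only on the current
  state. Transition probabilities are constant in time and age; no
  background life-table mortality is added beyond the per-state annual
  death probabilities (we take the published death column as the
  all-cause risk in each state).
* **Shared natural history.** Both arms use the *same* transition
  matrix; the drugs differ in relapse probability, cost and measured
  utilities, not in progression rates. A consequence used repeatedly in
  the tests: the occupancy stream is identical across arms, so any
  parameter shared by both arms cancels exactly from the incremental
  results.
* **Death composition.** Published tables print conditional
  living-to-living percentages (rows summing to ~100) next to a separate
  death column, so the rows cannot be used verbatim. We apply death
  first and distribute survivors proportionally to the renormalised
  living row, preserving both the printed conditional pattern and the
  printed death risks. Rows summing to 100 ± 0.05 (one row sums to
  100.005 after parsing) are renormalised; larger deviations are
  rejected rather than silently rescaled.
* **Relapse accrual.** Relapse is a counted outcome, not a cost or
  disutility: expected relapses per cycle are the arm's annual relapse
  probability times RRMS occupancy while the DMT is active, and nothing
  is accrued after DMT stop (the source ties relapse probabilities to
  the drugs and stops the drugs at SPMS, and reports no relapse-linked
  cost or utility decrement). The published base case's relapse totals
  are not in the same ratio as the relapse probabilities, implying an
  unstated accrual rule; we use the rule above and do not attempt to
  reverse-engineer the published totals.
* **Cycle timing.** Accruals use cycle-start occupancy; the first cycle
  is undiscounted (discount factor $(1+r)^{-k}$ with $k = 0, 1, \dots$).
  Both a half-cycle correction and first-cycle discounting exist as
  settings but default off, since the source describes neither.
* **Horizon.** Entry at age 34, 100% of the cohort in EDSS 0–2.5; the
  run ends at age 100 (66 cycles) or when living occupancy falls below
  $10^{-6}$.

## Parameters

| Parameter | Value | Units | Source/choice |
|---|---|---|---|
| Transition/death table | 4×4 + death column | %/year | published table |
| Annual relapse probability | 0.265 (nat), 0.104 (rit) | probability | published table |
| RRMS utilities | 0.754/0.530 (nat), 0.833/0.621 (rit) | EQ-5D-3L index | observed means |
| RRMS utility SDs | 0.186/0.120, 0.125/0.097 | — | observed SDs |
| Annual drug cost | 32,942.24 (nat), 2,038.51 (rit) | 2019 PPP$ | observed item means |
| Annual non-drug RRMS cost | 3,115.84 (nat), 3,360.77 (rit) | 2019 PPP$ | observed total minus drug |
| Discount rates | 5.8% costs, 3% outcomes | /year | stated |
| WTP threshold | 37,641 = 3 × 12,547 | PPP$/QALY | 3× per-capita GDP |
| SPMS utilities | 0.45 (6–7.5), 0.10 (8–9.5) | index | **placeholder** |
| SPMS non-drug cost | 3,000 | PPP$/year | **placeholder** |
| Cost coefficient of variation (PSA) | 0.2 | — | **assumption** |

The three flagged rows are not published anywhere in the source
material. The placeholders are plausible for their disability bands
(utilities fall steeply above EDSS 6; SPMS management costs are of the
same order as RRMS non-drug costs) and are deliberately **shared across
arms**, so they shift each arm's absolute lifetime totals but cancel
exactly from the incremental cost and incremental QALYs. This is why the
package reproduces the *incremental* verdict (rituximab dominant)
robustly while its absolute lifetime totals need not match the published
ones, which were computed with unpublished SPMS inputs and unpublished
cycle-timing conventions. The acceptance battery therefore checks
structural guarantees (mass conservation, matrix-power and
microsimulation oracles, moment recovery, dominance propagation, tornado
linearity) plus the sign of the incremental comparison across a grid of
SPMS placeholders and cost CVs, rather than asserting the unpublishable
absolute totals.

## The synthetic cohort generator

`generate_cohort()` emulates the study sample so every downstream stage
is testable without access to patient data: 60 patients per arm, 74.17%
female, ages Normal(33.4, 7.27²) / Normal(34.92, 5.94²) truncated to
18–65 years, everyone enrolled in EDSS 0–2.5 (a band mix is
configurable so both RRMS strata can be exercised), at least one year on
drug (inclusion criterion), and micro-costed annual cost lines (use
count × unit price, with direct non-medical and human-capital indirect
items carried as precomputed annual amounts).

Distributional choices the source does not specify, chosen once as
minimal standard forms: relapse counts are Poisson with mean
rate × years-on-drug; years-on-drug is 1 + Exponential(mean 2) capped at
10; cost lines carry mean-one multiplicative lognormal noise
(σ_log = 0.1). Utility targets are *not* emitted directly: a target
utility is drawn from a truncated normal and mapped to the EQ-5D-3L code
whose value-set score is nearest, so the scoring path is exercised
end-to-end. Because truncation biases a naive normal's mean (upward for
ages near the lower bound, downward for utilities near 1), the location
parameter is solved numerically so that the *truncated* mean equals the
target; sample means then converge to the targets as the cohort grows.

One statistical caveat, reflected in the tests: at ten times the study
size the sample means of age and utility sit within 1% of their targets,
but the pooled relapse rate (total relapses / total person-years)
carries Poisson sampling error of $\sqrt{r/\text{person-years}}$ ≈ 2–4%
at that size, so the relapse target is checked within three standard
errors rather than a fixed 1%.

What the generator does **not** emulate: longitudinal EDSS trajectories
(the Markov model owns disease course), correlation between utility and
relapse burden within patients, non-insurance heterogeneity, or real
EQ-5D response patterns — the bundled value set is synthetic (additive
decrements, floor −0.200) because the national tariff's coefficients are
not published; any real analysis should plug in the licensed value set
via `read_value_set()`. Passing tests demonstrate internal consistency
of the pipeline, not agreement with real Iranian patient data.

## Estimators

* **Utilities:** per-(arm, band) sample mean and SD with the n−1
  denominator (matching how reported SDs are conventionally computed);
  singleton strata report SD 0 with an explicit flag.
* **Relapse rate:** the pooled person-time estimator
  Σ relapses / Σ years-on-drug per arm. The source's further "divided by
  the number of patients" would yield a per-patient share an order of
  magnitude below the reported relapse summaries, so it is exposed
  behind `per_patient = TRUE` but off by default.
* **Costs:** item means per patient-year (absent items count as zero),
  category subtotals (DMC/DNMC/IC), grand total, and percentage shares
  at item-within-category and category-within-total levels; Rial amounts
  convert at 22,075 Rials per 2019 PPP$.
* **EQ-5D-3L coding** follows the instrument's standard 1–3 levels per
  dimension (the source's "0 to 1" phrasing describes the index scale,
  not the response coding).

## Sensitivity analyses

**PSA.** Utilities are beta-distributed and costs gamma-distributed,
both parameterised by the method of moments — the standard choice when
only a mean and SD are reported. Each of 5000 trials draws every
utility (per arm and state, independently; no correlation structure is
claimed by the source) and every cost parameter (CV 0.2 by default,
overridable), then reruns the full lifetime model for both arms.
Transition and relapse probabilities are *not* sampled (only "utility
and cost variables" are described as distributed). All draws are taken
vectorised from the master seed before any model evaluation, so results
are reproducible and independent of iteration order; a parameter with
SD 0 stays at its mean, making the PSA degenerate smoothly to the base
case. The CEAC reports, per threshold, the fraction of trials in which
each strategy has the higher net monetary benefit (ties split 0.5/0.5 —
a measure-zero event handled explicitly for determinism).

**Tornado.** Each cost and utility parameter is set to ±20% of base
(utilities capped at 1 with a warning) with everything else fixed, and
the model rerun. Because the base-case ICER is negative (dominance) and
negative ICERs do not rank, bars report both the incremental cost and
the incremental net monetary benefit, sorted by the NMB swing. The
widest bar is the natalizumab drug price, consistent with the published
one-way analysis.

## Numerical choices

Row renormalisation tolerance 0.05 on a 100-point row; composed matrix
rows checked to 1e-12; occupancy conservation asserted to 1e-9 across
the horizon; matrix-power oracle agreement to 1e-10; survival floor
1e-6; beta fitting requires sd² < mean(1−mean) and errors otherwise
(never clamps); degenerate inputs (empty cohorts, all-zero costs,
single-patient strata, zero-width tornado bars) return flagged zeros
rather than NaN.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 3–600 patients; the
convergence property uses 600 per arm; the microsimulation oracle
simulates 200,000 individual trajectories; moment recovery uses 10⁵
draws; the PSA acceptance check uses the full 5000 trials. The complete
suite runs in well under a minute on a single core.

## Known limitations

* Absolute lifetime totals depend on the SPMS placeholders; only
  incremental quantities are robust to them.
* No age-dependent background mortality, no relapse costs/disutilities,
  no treatment discontinuation other than the SPMS stopping rule, no
  comparators beyond the two drugs, and no parameter correlation in the
  PSA.
* The published cost-effectiveness-plane split (51.24% / 48.76% between
  the two accepting quadrants) depends on unpublished cost variances;
  the package reports its own split but does not assert that value.
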