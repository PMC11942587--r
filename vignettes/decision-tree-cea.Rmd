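---
title: "Decision-tree cost-effectiveness analysis with ceatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-effectiveness analysis with ceatree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ceatree)
```

## The model and its assumptions

`ceatree` evaluates decision trees for health economic evaluation. A model
has named strategies at a single root decision point; beneath each
strategy, chance nodes branch on parameter-referenced probabilities and
terminal nodes carry payoffs: a cost expression (a sum of per-category
cost parameters, each with a pathway multiplier) and an effect expression
(the utility of the terminal health state). Rollback computes each
strategy's expected cost and effect as the probability-weighted sum over
terminals; `enumerate_paths()` exposes the same quantity as an explicit
sum over root-to-leaf paths and serves as the test oracle for rollback.

Assumptions built into the tree formalism:

* **One-shot horizon.** All costs and effects accrue within the model
  horizon (90 days for the bundled model). There is no discounting — a
  deliberate choice, as discounting over a sub-year horizon would be
  cosmetic — and no state transitions over time; a cohort Markov model is
  out of scope.
* **Branch probabilities on the simplex.** At every chance node the
  resolved probabilities must sum to 1 within 1e-9. One branch per node
  may be declared `complement`, resolved as 1 minus the sum of its
  siblings (more than one is a validation error); explicit complements
  are how the bundled model keeps one-way analyses of a single branch
  probability well-formed.
* **Linear payoffs.** Expected cost is affine in every cost parameter
  (slope = total probability of the paths referencing it), which the
  one-way and tornado modules exploit and the tests verify.

All RMB amounts are carried at full double precision; rounding —
half-away-from-zero, the commercial convention under which the bundled
model's published USD conversions reproduce exactly — happens only at
reporting boundaries. USD figures are presentation-layer only; modelling
is in RMB at RMB 678.03 = USD 100.

## The bundled PICC model and its calibration

The shipped model (`picc_model_file()`, rebuilt by `build_picc_model()`)
compares chlorhexidine-coated (AGBA) and standard PICCs in a
haematology-trial population. Per strategy: an insertion node (success vs
second puncture), a complication node (CLABSI, unknown fever, local
complication, none), and per-complication resolution nodes (resolved
without catheter removal, resolved with removal, worsened) — 20 terminals
per arm.

The source trial published only aggregate figures, so the model mixes
trial counts, assumptions, and solved calibration values; the three are
kept distinct in the model metadata:

* **From trial counts**: arm sizes 113/111; second punctures 1/113 vs
  3/111; CLABSI 0/113 vs 3/111. The zero cell uses the Jeffreys point
  estimate (x+0.5)/(n+1) = 0.5/114 so its PSA beta/Dirichlet weight is
  proper rather than degenerate at 0.
* **Assumptions (configurable arguments of `build_picc_model()`)**: the
  36 unknown-fever cases were never split by arm, so the default assigns
  equal probability 36/224 to both arms rather than inventing a split;
  local-complication probabilities (0.04 / 0.06) and the resolution mixes
  (AGBA 0.70/0.25/0.05, standard 0.40/0.40/0.20) are assumed, with the
  standard arm worse. The published arm QALY gap of 0.05 is too large to
  arise from the CLABSI-count difference alone (arm complication
  probabilities would differ by only ~0.023, forcing utilities outside
  [0, 1]), so the arms must differ in severity of outcome; absent any
  published resolution counts, that difference is placed in the
  resolution mixes.
* **Solved by calibration**: with those probabilities fixed, expected
  effect is linear in the four state utilities, so two of them
  (complication-free and resolved-with-removal, with
  resolved-no-removal = 0.70 and worsened = 0.05 held fixed) are solved
  from a 2×2 linear system to hit 0.73/0.68 QALYs exactly; the builder
  verifies the solution lies in [0, 1] and respects the severity ordering
  (the default assumptions give 0.775 and 0.255). Likewise the per-arm
  `other_treatments` residual mean is solved so expected cost hits RMB
  19,696.23 / 21,987.32 exactly. Reproducing these published means is
  therefore a *calibration check of model construction*, not independent
  validation — the metadata says so explicitly. Utilities here are the
  published 90-day QALY accruals used as-is; no annualisation factor is
  applied, mirroring the source analysis' own accounting.

The source analysis' printed incremental figures are not mutually
consistent (ICER RMB 4271.31 vs 2291.10/0.05 = 45,822; USD 428.44 vs the
stated-rate conversion 337.91; threshold conversions USD 16,884 vs
16,683.63). The package computes the self-consistent arithmetic and
carries the printed figures verbatim in a `paper_reported` annotation
block written into every report; it deliberately does not pick a side.

## Parameters that matter

| Parameter (bundled model) | Unit | Default | Why |
|---|---|---|---|
| WTP threshold λ | RMB/QALY | 113,120 | 1.76 × GDP per capita, non-life-saving technology |
| Exchange rate | RMB/100 USD | 678.03 | 2020–2023 central-bank average |
| PSA iterations | — | 10,000 | matches the source analysis; cost MC-SE ≈ RMB 70 |
| Bootstrap resamples B | — | 10,000 | matches the source analysis |
| Cost CV | — | 0.3 | conventional for right-skewed cost data; gamma shape 1/CV² ≈ 11.1 |
| OWSA ranges | — | Wilson CI for counted probabilities, ±50 % (clamped) otherwise; ±25 % for costs | must choose something; recorded in output metadata |
| Resolution-mix effective sample size | — | 50 | Dirichlet concentration for the assumed (uncounted) mixes |

Distribution families are likewise defaults, not published facts: beta
(method-of-moments from counts) for lone probabilities, Dirichlet with
count-scaled concentrations for multinomial branch sets — sampled
*jointly*, which makes off-simplex draws structurally impossible — gamma
(mean-preserving, CV 0.3) for costs, utilities held fixed unless given a
distribution. Every default is overridable in the model file and echoed
in the run manifest.

## Sampling and reproducibility

One RNG stream per run, seeded explicitly; parameter draws consume the
stream in declaration order, so results do not depend on tree traversal
order. Identical seeds give bitwise-identical PSA clouds, cohorts, and
bootstrap intervals; `write_report()` output is byte-identical across
runs apart from the manifest timestamp. PSA evaluation is vectorised
over the draw matrix (10,000 iterations of the bundled model take about
a second).

## The synthetic cohort generator

`generate_cohort()` emulates what the analysis assumes about the trial's
unavailable patient-level data: exact arm sizes, binomial second
punctures, a complication multinomial, a conditional resolution
multinomial, gamma per-category costs whose means follow the same
pathway multipliers as the tree (laboratory tests double on complication
pathways; catheter expenses scale with catheters used, 1 + second
puncture + removal; complication treatment scales 1/1.8/4 with
severity), and per-state QALY accruals. `calibrate_costs()` solves the
residual category so the analytic expected arm totals equal the
published means to the cent; `expected_arm_cost()` exposes that
expectation in closed form as the truth for consistency tests.

What it does *not* emulate: time stamps and catheter-days, censoring,
within-patient correlation between cost categories (draws are
conditionally independent given the pathway), covariates, and any
patient-level QALY noise (QALYs are deterministic given the terminal
state). Tests passing on synthetic cohorts therefore demonstrate the
estimators' statistical behaviour under the model's own assumptions —
parameter recovery, bootstrap coverage, calibration consistency — not
fidelity to the real trial's microdata.

## Numerical choices

* Chance-node probability sums are checked to 1e-9; path-probability
  totals and oracle-vs-rollback agreement are asserted at the same
  tolerance.
* `icer()` treats ΔE = 0 as an explicit equal-effect status (no
  division); dominance requires strictly opposite signs, so ΔC = 0 with
  ΔE > 0 yields the numeric ICER 0.
* CEAC ties (equal NMB within relative 1e-12) are split equally among
  the tied strategies, keeping the per-λ probabilities summing to 1.
* Prediction intervals use type-7 linear-interpolation quantiles.
* BC bootstrap: z0 = Φ⁻¹(fraction of resample statistics below the
  observed value), clamped to [1/(B+1), B/(B+1)] so it stays finite;
  all-identical data short-circuit to a degenerate interval with z0 = 0
  and a warning. BCa (jackknife acceleration) is available behind
  `accelerated = TRUE`; the default follows the bias-corrected-only
  method the bundled analysis describes.
* The efficient frontier removes strict dominance by a cost-ordered
  sweep, then extended dominance by iteratively deleting the first
  strategy that breaks ICER monotonicity.

## Test design notes

Problem sizes in the test suite are chosen to make each statistical
assertion resolvable on a desktop in minutes: 200 random trees for the
rollback-vs-enumeration oracle; 10,000-iteration PSA convergence checks
against 3 Monte Carlo standard errors; bootstrap coverage on gamma(2)
data at n = 100, B = 2000 over 500 replications; cohort parameter
recovery at 10⁵ patients per arm over 200 replications. One check needs
care: empirical coverage of a nominal-95 % Wilson interval cannot be
distinguished from 95 % with a few hundred replications (the Monte Carlo
error of the empirical coverage is larger than the method's distance
from nominal), so the coverage bound is asserted on the *exact* coverage
computed by binomial enumeration, and the simulation is then required to
agree with that exact value within 3 Monte Carlo standard errors.

## One-way analyses and the WTP sweep

A deterministic base-case ICER does not depend on λ, so the WTP sweep
reports per-λ NMBs and decisions (and the λ-independent ICER or
dominance status separately) rather than pretending the ratio varies.
For the bundled model the sweep is flat in the interesting sense: the
coated catheter is cheaper and more effective at base case, so it is the
NMB-maximising choice at *every* λ > 0, and PSA acceptability at the
threshold quantifies how often sampled parameter uncertainty overturns
that (about 7 % of iterations at the defaults).

## Known limitations

* No Markov/state-transition evaluation, microsimulation, discounting,
  EVPI, or parameter correlation beyond the Dirichlet branch coupling.
* The bundled model's resolution mixes, local-complication rates and
  baseline cost-category means are assumptions calibrated to published
  totals; conclusions that depend on *within-total* cost composition
  should not be read off the fixture.
* `dominance_frontier()` assumes strategy outcomes share a common
  comparator scale; it does not handle clusters of equivalent strategies
  specially beyond exact-tie ordering.
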