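---
title: "A cohort model for the economics of semi-quantitative albuminuria screening"
author: "uacrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort model for the economics of semi-quantitative albuminuria screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uacrscreen)
```

## The question

Diabetic patients are advised to be screened annually for albuminuria
(urine albumin-creatinine ratio, uACR, at or above 30 mg/g), because
early micro-albuminuria predicts end-stage renal disease (ESRD),
cardiovascular disease (CVD) and death. The quantitative laboratory
assay is the reference test but requires a central laboratory, with the
associated specimen transport and a second patient visit. A
semi-quantitative point-of-care strip reports uACR in the three clinical
bins (`<30`, `30-300`, `>=300` mg/g) at a fraction of the price, but it
misclassifies: false positives trigger an unnecessary confirmatory
laboratory test, and false negatives leave albuminuric patients exposed
to the elevated hazards of ESRD, CVD and death for another year.

`uacrscreen` quantifies that trade-off. It computes the strip's
diagnostic accuracy from concordance tables, pools outcome hazard ratios
across studies, and runs a deterministic ten-year cohort model of the
two screening strategies to ask whether strip-first screening saves
money once the opportunity cost of its false results is priced in.

## Diagnostic accuracy

A `concordance_table` cross-tabulates the quantitative category (rows)
against the strip category (columns). Screening dichotomizes at 30 mg/g,
with the boundary values 30 and 300 belonging to the upper bin.
`accuracy_metrics()` reports sensitivity, specificity, and two
fractions expressed relative to *everyone screened* rather than to the
diseased/healthy margins: the over-detected fraction (false positives /
n, the people sent to an unneeded confirmatory test) and the
under-detected fraction (false negatives / n, the people whose
albuminuria the strip misses). The number needed to screen is the
reciprocal of sensitivity — the expected number of strip applications
per true case found; it is not defined at sensitivity zero and the
package refuses to return it there rather than yielding infinity.

```{r accuracy}
accuracy_metrics(development_subgroup_table())
```

Cohorts reported only as dichotomized counts (dipstick comparisons, the
external validation summaries) enter through
`dichotomous_concordance()`, which embeds a 2x2 table in the 3x3 layout
with exact margins.

## The two-strategy cohort model

`run_strategy()` tracks the expected fraction of a unit cohort through
annual cycles. Each cycle, in order:

1. everyone occupying the screening state is screened (test cost plus
   transport);
2. *quantitative arm*: screen-positives (fraction `1 - q_negative`)
   leave screening for medical care. *Semi-quantitative arm*:
   strip-positives receive a confirmatory quantitative test; the
   confirmed fraction (`tp_given_semiq_positive`) leaves, the false
   positives stay in the pool;
3. the remaining strata face annual probabilities of ESRD, CVD and
   death. Screen-negatives in the quantitative arm, strip
   true-negatives, and confirmed false positives use the
   normo-albuminuric incidence rates; the strip's false negatives
   (fraction `fn_given_semiq_negative` of strip-negatives) use rates
   scaled by the outcome hazard ratios. Everyone with an event leaves
   the cohort;
4. survivors re-enter the screening state and next year's screening
   results are re-drawn from the same proportions.

The four screening proportions are carried as beta counts `(a, b)` taken
straight from a concordance table's dichotomized margins (the
development subgroup gives `Beta(917, 193)`, `Beta(615, 495)`,
`Beta(36, 579)`, `Beta(157, 338)`); the deterministic engine uses the
mean `a/(a + b)` at full precision, and the counts remain available for
probabilistic sampling.

Incidence rates are converted to cycle probabilities by the
constant-hazard formula `p = 1 - exp(-rate * time)`, and the albuminuric
strata use `1 - exp(-rate * hr * time)` — the hazard ratio scales the
rate before conversion, not the probability after it. Within a cycle the
three events are converted independently and treated as mutually
exclusive: their sum is removed from the occupancy. A renormalized
competing-risk allocation (`p_k = r_k / sum(r) * (1 - exp(-sum(r)))`)
was considered and rejected because the annual probabilities here are
small enough (\< 2.1%) that the two differ in the fifth decimal, and the
independent-conversion convention is what the baseline totals are
calibrated under.

### Modelling assumptions worth stating

- **Memorylessness.** A patient's screening result does not persist: a
  false negative this year is re-drawn next year. This matches the
  re-entry semantics of the decision tree the model implements and
  makes every horizon total a geometric series — which is also how the
  test suite's independent closed-form oracle verifies the engine.
- **Absorbing exits.** Screen-positives and event-takers never return;
  no treatment effects, downstream state costs, or post-event survival
  are modelled. The model is a *cost-saving* comparison of screening
  cascades, not a cost-effectiveness model with QALYs.
- **Events of false positives are recorded but not costed.** Confirmed
  false positives remain in the pool and experience events at
  normo-albuminuric rates; those events remove them from screening but
  their medical costs are not tallied by default, because the cost
  comparison charges outcome costs only to the *screen-negative*
  ("under-detected") strata of each arm. `cost_breakdown(...,
  cost_false_positive_events = TRUE)` flips the convention if a user
  wants the more inclusive accounting.
- **No half-cycle correction.** Screening costs fall at cycle start and
  events within the same cycle; with annual cycles and an annual
  discount factor this keeps every cash flow a clean geometric series.

## Baseline inputs

| Input | Value | Units / note |
|---|---|---|
| Quantitative test | 17.76 | USD per test |
| Semi-quantitative test | 0.86 | USD per test |
| Transport | 9.265 | USD per trip; 2 trips per quantitative screen, 1 per strip screen, 1 per confirmatory test |
| ESRD: rate, HR, cost | 0.0006 /y, 3.432 (2.757–4.271), 6,810.38 | annual incidence (normo-albuminuric), pooled hazard ratio, USD per event |
| CVD: rate, HR, cost | 0.0154 /y, 1.315 (1.250–1.384), 13,149.62 | — |
| Death: rate, HR, cost | 0.0095 /y, 1.480 (1.408–1.556), 25,634.48 | cost is a willingness-to-pay value for one life-year |
| Discount rate | 3%/year | applied to all cash flows, first cycle undiscounted |
| Horizon | 10 | annual cycles |

Costs are 2016 Korean claims values expressed in USD (1 USD = 1,160
KRW). Two remarks on these defaults:

- The pairing of incidences and unit costs with outcomes follows the
  prose of the source material rather than its input-table row order,
  which lists the same six numbers against permuted outcome labels;
  the prose assignment is the one under which the model's per-outcome
  cost rows reproduce the published cost table, which the acceptance
  suite verifies against an independent closed-form oracle.
- Two pooled ESRD hazard ratios circulate in the source material
  (3.27 from one pooling, 3.432 in the input table). The baseline
  adopts 3.432 with CI 2.757–4.271 for the sensitivity range; the
  package's own pooling functions let a user re-derive either from a
  study table.

The cost of death is discounted like every other cash flow; nothing in
the accounting distinguishes willingness-to-pay values from claims
costs.

```{r model}
cmp <- compare_strategies(development_config())
cost_report(cmp)
```

## Discounting and cost accounting

Cycle `t` (1-based) cash flows are multiplied by `(1 + d)^-(t - 1)`:
the first screen happens today and is undiscounted. `cost_breakdown()`
keeps the seven components (two screening rows, two confirmatory rows,
three outcome rows) separately in crude and discounted form, and
`saved_cost()` differences the two strategies' totals. Every component
is linear in its unit cost given a fixed trace, which the suite
exploits: doubling all unit costs must exactly double every component.

## Hazard-ratio pooling

`pool_random()` implements DerSimonian–Laird: fixed-effects weights
`w_i = 1/se_i^2` give Cochran's `Q`, the method-of-moments
between-study variance `tau2 = max(0, (Q - (k-1)) / (sum(w) -
sum(w^2)/sum(w)))`, and final weights `1/(se_i^2 + tau2)`.
Heterogeneity is summarized by `I2 = max(0, (Q - (k-1))/Q)` and the
upper-tail chi-squared p-value on `k - 1` degrees of freedom. Study
inputs arrive as HR with 95% CI and are back-transformed with the
full-precision normal quantile 1.959964 (rounding it to 1.96 moves
back-transformed SEs in the fourth decimal). The bundled study table is
labelled *illustrative synthetic*: the per-study values behind the
baseline hazard ratios are not available as data, so pooled regression
against those baseline values is deliberately not asserted anywhere —
the pooling module is validated by hand-arithmetic oracles, an
independent implementation (`metafor`, in the test suite only), and
parameter-recovery simulation.

## Synthetic data and the micro-simulator

`generate_cohort()` draws true categories from a prior (default
`(0.826, 0.168, 0.006)`, the development subgroup's distribution) and
strip categories from a row-stochastic confusion matrix (default: the
row-normalized development subgroup table). Within-bin uACR values are
log-uniform (upper bin capped at 3000 mg/g) — values matter only through
their bin, so this is cosmetic realism. The generator emulates
*independent, cross-sectionally misclassified* tests: it does not model
longitudinal uACR trajectories, day-to-day biological variability, or
error correlation across repeat tests, so recovery tests on synthetic
cohorts demonstrate estimator correctness, not robustness to those
real-data features.

`microsimulate()` is the individual-level realization of the same
decision tree, with Bernoulli draws at every chance node and identical
cost accounting. Agreement between its Monte-Carlo means and the cohort
engine (within 3 standard errors at 100,000 patients, for screens,
confirmatory tests, per-outcome events, and crude and discounted
totals) is the package's main structural check that the deterministic
engine and the tree semantics coincide. All generators restore the
global RNG state on exit and are pure functions of their parameters and
seed.

## Sensitivity analysis

`one_way_sensitivity()` re-runs both strategies with a single scalar
input moved to a bound; `tornado()` does this over the default ranges —
unit costs and incidence rates at ±20%, hazard ratios across their 95%
CIs — and sorts by the induced range of the saving. The default basis is
the *discounted* saving. Under both the development and validation
parameterizations the saving stays positive across every range, with
the cost-of-death input producing the widest bar, mostly because death
carries both the largest unit cost and the second-largest incidence.

## Numerical choices and edge cases

- Proportions and probabilities are validated into `[0, 1]` at
  construction; combined per-cycle event probabilities above 1 abort
  the run with the offending configuration named.
- Tables with an empty quantitative-positive (or -negative) margin
  raise an error instead of returning `NaN` sensitivities; the same
  philosophy applies to NNS at sensitivity 0 and to empty study sets.
- A single-study "pooling" returns the study unchanged, including its
  reported (possibly log-asymmetric) interval, with `tau2 = 0` and
  `I2 = 0`.
- Deterministic results are exact to the geometric-series closed form
  at `1e-9` or better; the test suite checks mass conservation each
  cycle at `1e-12`.

Problem sizes used by the test suite — 100,000 simulated patients for
the micro-simulation checks, 500 replicates of `k = 30` studies for
DerSimonian–Laird recovery and coverage — were chosen so Monte-Carlo
standard errors are well below the effect sizes being verified.

## Known limitations

- Costs are 2016 Korean claims values; transport multiplicities and the
  willingness-to-pay value for death are setting-specific, so absolute
  savings do not transfer across health systems without re-running the
  model with local inputs (every one of them is a `model_config` field).
- The model has no treatment pathway after a positive diagnosis and no
  multi-year cost tail after an event; both strategies are charged as
  if care after exit were identical, so only the screening cascades and
  the under-detected event burden differentiate them.
- Confidence intervals for sensitivity/specificity and probabilistic
  (distributional) sensitivity analysis are out of scope; the beta
  counts carried by `screening_params` are the natural starting point
  if a user wants to add the latter.
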