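---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septicost)
```

`septicost` implements a decision-analytic cohort model of earlier sepsis
detection in the ICU. This vignette explains the model and its assumptions,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data machinery does and does not
establish.

## The decision tree

The population is adult ICU admissions *without* sepsis at admission.
Incidence (default 14.1%) splits the cohort into patients who do and do not
develop sepsis during the stay; the screening method's sensitivity and
specificity split each branch into TP/FN and TN/FP pathways. Both arms
share a single time axis: hours to treatment $t$ relative to the moment of
current-practice diagnosis. The algorithm arm treats true positives at
$t = -3$ h, the comparator at $t = 0$; false negatives in both arms are
treated at $t = +3$ h. A separate antibiotic-delay term (default 0 h) adds
to every pathway equally, so it cancels in the base-case comparison but is
sampled in the probabilistic analysis.

Two time-dependent risk functions carry the whole clinical effect:

* septic-shock probability: linear in $t$, anchored at 56.6% ($t=0$) and
  40% ($t=-3$), i.e. 5.5 percentage points per hour, clamped to $[0,1]$. A
  `time_dependent = FALSE` switch freezes it at 56.6% to express "earlier
  detection does not prevent shock".
* in-hospital mortality: $0.4281\,e^{0.0272 t}$ with septic shock and
  $0.0052\,t$ without (floored at 0 for $t \le 0$ — treating earlier than
  practice cannot create negative mortality). Alternative curve families
  are pluggable: a linear survival decrease of 7.6 percentage points per
  hour anchored at 40% mortality at $t=0$, and constant 33%/22%
  mortalities. Anchoring of the alternatives is interpretive, so published
  scenario rows using them are treated as direction checks, not exact
  targets.

Non-sepsis patients carry no in-hospital mortality in either arm: the
proportion is identical across arms, so any common assumption cancels, and
the diversity of other ICU diagnoses makes a single number meaningless.

Readmission (20.6% in the first year) is applied to **all** hospital
survivors, not only sepsis survivors. The published per-arm readmission
proportions (20.0%/19.8%) and costs (€835/€826 at €4166 per event) are
only reproducible under that reading — e.g.
$0.206 \times (1 - 0.0275) = 0.2003$ — so `all_survivors` is the default,
with a `sepsis_survivors` switch for the narrower reading.

## Costs and back-calculated constants

Per-patient cost is
prediction + ICU days × unit cost + ward days × unit cost +
readmissions × €4166 + 1-year-survivor probability × long-term lump. The
prediction cost (€1037) is charged once per ICU patient in the algorithm
arm: the published per-patient total and the national prediction cost
(€1037 × 36 900) are only consistent under that accounting, even though the
figure is described per sepsis patient — the tension is deliberate and the
per-ICU-day framing (€90/day → €146 per patient → €1037 per sepsis patient
detected) is kept as the separate `worked_example_prediction_cost()`.

Three unit costs are not published as primary inputs. They are
back-calculated from published aggregates and shipped as defaults:

| constant | derivation | value |
|---|---|---|
| ICU day | per-arm ICU cost ÷ per-arm ICU LOS | €6355.38 |
| ward day | per-arm ward cost ÷ per-arm ward LOS | €626.26 |
| long-term lump per 1-year survivor | per-arm long-term cost ÷ per-arm survivor probability | €1947.73 |

Each back-calculation was done independently in both arms; the arms agree
to better than 0.1%, and the shipped constant is the mean. The
cross-arm agreement is asserted in the test suite (the same lump must give
both arms' long-term costs within €1).

## Long-term projection and QALYs

Survivors are projected over a life table with annual death probabilities
$q(x)$, applying relative risks to sepsis survivors by band: 5.5 in model
years 1–5, 3.1 in years 6–10, 1.0 thereafter (the 60–70 age band, matching
the base-case entry age of 60). Septic-shock survivors face a 17.5%
first-year post-discharge mortality, which *replaces* the year-1
RR-adjusted hazard rather than stacking on it; non-shock sepsis survivors
use the RR-adjusted hazard from year 1. This convention keeps the QALY
model consistent with the survivor bookkeeping used to calibrate the
long-term lump (shock survivors × 0.825 + non-shock survivors).

QALYs are $\sum_k S(k)\,u(k)\,(1+r)^{-k}$ with annual year-end
discounting at $r = 3\%$ (the source states only the rate; annual year-end
is the conventional choice). Utilities are a population-norm baseline plus
band-wise decrements (−0.164 years 1–5, −0.124 years 6–10, 0 afterwards).
The baseline utility is not stated in the source; the default is 0.80,
configurable. It shifts absolute QALYs in both arms but not the cost
results, and only weakly the incremental QALYs.

The long-term consequence cost is carried as a discounted lump per 1-year
sepsis survivor because the per-item annual costs behind it are
unpublished; the consequence frequencies (impaired kidney function 14.1%,
amputation 8.5%, depression 2.8%, PTSD 9.9%) are reported descriptively.
To make the lump respond to the discount rate, the survival assumption and
the time horizon, it is modelled as an annual stream over the survivor's
remaining lifetime from year 2 onward (consequences apply after the first
year), calibrated so the reference conditions (3% discount, RR
5.5/3.1/1.0, lifetime horizon) reproduce €1947.73. A 1-year horizon
therefore zeroes it, a 0% discount rate raises it, and general-population
survival raises it; the two scenario rows that depend on the unpublished
cost *profile* (discount 0%, general-population survival) consequently
match published magnitudes only approximately (within ~10%), with correct
directions, and are not used as exact targets.

## The two-step mortality-curve estimation

The grouped delay-vs-mortality data behind the published curves are not
deposited, so the procedure is implemented and validated on synthetic data
with a known generating curve. Step 1 is a linear program over mortality
fractions $m(t_j)$ on a grid: minimise the total absolute deviation
between implied and observed interval death counts (an interval's implied
count is its patient count times the mean of $m$ over the grid points it
contains), subject to $0 \le m \le 1$ and monotonicity. The objective is
not stated in the source; L1 is the standard LP-compatible choice, and a
tiny penalty ($10^{-6} \sum_j m_j$) makes the solution unique where the
objective is flat. The LP is solved with the simplex implementation in
`boot`. Step 2 fits the parametric curve: exponential fits are linear
regressions on the log scale (deterministic and closed-form; the
alternative, direct nonlinear least squares, is not stated either), and
the linear-through-origin slope is $\sum t y / \sum t^2$.

On grouped data of 10 000 patients per 2-hour bin, the pipeline recovers
the generating coefficients within ±0.02 ($a$) and ±0.005 ($b$). Point
estimates at individual grid points carry binomial noise with standard
error $\approx \sqrt{p(1-p)/n} \approx 0.005$, so per-point agreement is
asserted within 4 binomial standard errors (and within 0.01 root mean
square), not with a fixed per-point constant that noise alone would
occasionally break.

## Probabilistic sensitivity analysis

Every stochastic parameter carries a (mean, SE, family) specification;
families are beta, gamma, log-normal or normal and are converted to
natural parameters by method of moments (exact round trips, asserted to
$10^{-9}$). The published single "hours to diagnosis" range is expanded
into independent normals for the TP lead time ($-3$, SE 0.5) and the FN
delay ($+3$, SE 0.5) — the joint behaviour is unstated, and independence
is the neutral default. Hazard-ratio rows for the under-60 and over-70
bands are carried in the list but are inert at the base-case age; the
duplicated over-70 label in the source is read as years 5–10 for the
second occurrence. Normal draws are used as drawn (no truncation is
stated); draws that break a structural ordering (early shock probability
above the reference, TP time above FN time) are re-clamped to the boundary
and counted, with a warning above 1% of draws.

Each parameter gets its own RNG stream seeded deterministically from the
master seed in list order, so conditioning one parameter on its mean (the
published scheme for ranking influence) leaves every other parameter's
draws bit-identical. No parameter correlations are modelled (none are
specified). A run is bit-reproducible given (seed, draw count).

## Synthetic data and what the tests show

The life table is a synthetic Gompertz table,
$q(x) = \min(1, A e^{Bx})$ with $A = 5\times10^{-5}$, $B = 0.095$,
terminal age 105 — a plausible high-income-country shape (remaining life
expectancy ≈ 22 years at 60), *not* an official national table. Absolute
QALY levels therefore carry the table's imprint; incremental cost results
do not (they depend on the life table only through the long-term lump
rescaling).

The microsimulation routes individual patients through the tree with
Bernoulli draws at every branch and deterministic per-leaf stays (a switch
draws gamma-distributed stays instead). At 2 million patients per arm,
every analytic expectation agrees with the simulated mean within 3
Monte-Carlo standard errors — the strongest internal check that the cohort
algebra (probability mixing, survivor bookkeeping, cost accounting) is
right. What none of this can show is external validity: the synthetic
generators emulate structure (grouped binomial counts, Gompertz hazards),
not the actual literature datasets, so passing tests certify the
implementation, not the epidemiology.

## Problem sizes and determinism

The shipped analyses use 1000 PSA draws, 2 million microsimulation
patients per arm, $10^6$-draw moment-recovery checks, and 10 000 patients
per interval for curve-fitting demonstrations; all complete in seconds to
a couple of minutes on one CPU. Every stochastic component takes an
explicit seed, and all deterministic outputs are byte-identical across
reruns.

## Known limitations

* No Markov morbidity structure beyond the survivor/consequence lump — the
  modelled pathway ends at "1-year sepsis survivor with a lifetime
  consequence stream".
* The consequence-cost time profile, the baseline utility and the life
  table are package choices where the source is silent; all are
  configurable, and the cost conclusions are insensitive to the first two.
* Alternative mortality-model anchorings (linear-survival and constant
  variants) are interpretive.
* Currency handling is a single EUR scalar; no conversion machinery.
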