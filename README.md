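# septicost

A decision-analytic cost-effectiveness model of earlier sepsis detection in
intensive care units, written for health economists and ICU researchers who
want a tested, fully reproducible implementation of the published
decision-tree model comparing a machine-learning sepsis prediction
algorithm against sepsis diagnosis in current clinical practice.

## The model

Adult ICU patients without sepsis at admission enter a decision tree.
Sepsis incidence π = 14.1% splits the cohort into sepsis and no-sepsis;
the screening method's sensitivity and specificity then split each branch
into true positives (TP), false negatives (FN), true negatives (TN) and
false positives (FP):

    P(TP) = π·sens    P(FN) = π·(1−sens)
    P(TN) = (1−π)·spec    P(FP) = (1−π)·(1−spec)

The clinical benefit of earlier detection enters through the total time to
treatment *t* (hours relative to current-practice diagnosis; the algorithm
treats TP patients at *t* = −3 h, both arms treat FN patients at +3 h):

* **septic-shock probability** — linear in *t*, anchored at 56.6% at 0 h and
  40% at −3 h (5.5 percentage points per hour), clamped to [0, 1];
* **in-hospital mortality** — for septic shock *y* = 0.4281·e^(0.0272·t),
  for sepsis without shock *y* = 0.0052·t (floored at 0 for t ≤ 0).

The exponential/linear coefficients are themselves estimable from grouped
delay-vs-mortality data by the model's two-step procedure: a linear program
solves for monotone cumulative mortality fractions at grid time points
(L1 deviation on death counts), then parametric curves are fitted to the
point estimates.

Costs per patient sum the prediction technology (€1037, algorithm arm),
ICU and ward stays (lengths of stay per leaf, mixed over shock status),
first-year readmissions (20.6% of hospital survivors × €4166), and a
discounted long-term consequence cost per 1-year sepsis survivor.
Effectiveness is measured in discounted QALYs from a life-table projection
with relative risks of 5.5 (years 1–5), 3.1 (years 6–10) and 1.0 (year 11+)
for sepsis survivors, a 17.5% first-year post-discharge mortality for
septic-shock survivors, utility decrements of −0.164/−0.124/0 by band, and
3% annual discounting. Incremental results scale to the national cohort of
36 900 ICU admissions without sepsis per year, and the ICER
ΔCost/ΔQALY is classified against €20 000 and €50 000 per QALY.

Three unit costs are not published as primary inputs (per ICU day, per ward
day, per 1-year survivor); they are back-calculated from the published
aggregate results — both arms give the same constants to < 0.1% — and
shipped as defaults (€6355.38, €626.26, €1947.73).

## Worked example

```r
library(septicost)
cfg <- default_base_case()
incremental(cfg)
#> <septicost_incremental> (algorithm - comparator)
#>   total cost/patient: 16436 vs 16512 EUR (delta -76.0)
#>   national cost impact: -2803287 EUR/year
#>   lives saved: 356; ICU days saved: 5860; ward days saved: 7886
#>   QALYs/patient: +0.0556; classification: dominant
```

Earlier detection saves €76 per ICU patient (total cost €16 436 vs
€16 512), dominated by a 0.16-day shorter ICU stay; scaled nationally this
is a €2.8M annual saving, 5860 ICU days and 356 lives per year, and the
algorithm arm gains QALYs while saving money (dominant).

```r
psa <- run_psa(cfg, n_draws = 1000, seed = 2022)
psa
#> <septicost_psa> 1000 draws, seed 2022
#>   delta cost/patient: median -66.6 [Q1 -246.1, Q3 +96.8] EUR
#>   fraction dominant: 0.617
#>   fraction below 20000 EUR/QALY: 0.991
#>   fraction below 50000 EUR/QALY: 1.000
```

Under full parameter uncertainty, 62% of simulations are dominant and 99%
fall below €20 000 per QALY.

The `analysis/` scripts run the whole study end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_base_case.R            # base-case tables
Rscript analysis/02_fit_mortality_curves.R # two-step curve estimation demo
Rscript analysis/03_scenarios.R            # one-way scenario table
Rscript analysis/04_psa.R                  # probabilistic sensitivity analysis
Rscript analysis/05_microsim_validation.R  # microsimulation oracle check
```

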