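#!/usr/bin/env Rscript
# Deterministic base case: per-patient and national results for the sepsis
# prediction algorithm versus diagnosis in current clinical practice.
# Writes results/base_case/{base_case.csv,base_case.json,manifest.json}.

suppressPackageStartupMessages(library(septicost))

cfg <- default_base_case()
stopifnot(length(validate_config(cfg)) == 0)

inc <- incremental(cfg)
print(inc)

cat(sprintf("\nPer-patient totals: algorithm %.0f EUR, current practice %.0f EUR\n",
            inc$algorithm$cost_total, inc$comparator$cost_total))
cat(sprintf("ICU stay: %.2f vs %.2f days; in-hospital mortality %.1f%% vs %.1f%%\n",
            inc$algorithm$expected_icu_days, inc$comparator$expected_icu_days,
            100 * inc$algorithm$in_hospital_mortality,
            100 * inc$comparator$in_hospital_mortality))
ex <- worked_example_prediction_cost(
  cfg$costs$prediction_price_per_icu_day,
  inc$algorithm$expected_icu_days, cfg$cohort$incidence)
cat(sprintf("Worked example at %.0f EUR/ICU-day: %.0f EUR per patient, %.0f EUR per sepsis patient detected\n",
            cfg$costs$prediction_price_per_icu_day, ex$per_patient,
            ex$per_sepsis_patient))

files <- write_base_case_report(cfg, "results/base_case")
cat("\nwrote:", paste(basename(files), collapse = ", "), "\n")
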