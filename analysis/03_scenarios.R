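#!/usr/bin/env Rscript
# Deterministic one-way scenario analyses over the shipped preset list
# (incidence, comparators, specificity, detection lead time, shock
# prevalence, mortality models, stays, unit costs, post-discharge and
# long-term variants). Writes results/scenarios/scenario_table.csv.

suppressPackageStartupMessages(library(septicost))

cfg <- default_base_case()
tab <- run_scenario_table(cfg)

cat(sprintf("base-case national cost impact: %+.0f EUR/year\n\n",
            attr(tab, "base_national_cost_impact")))
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %-50s %+12.0f EUR (%+.0f%%)\n", tab$name[i],
              tab$national_cost_impact[i], tab$pct_change_vs_base[i]))
}

write_scenario_report(cfg, "results/scenarios")
cat("\nwrote results/scenarios/scenario_table.csv\n")
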