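#' Shipped one-way scenario presets
#'
#' The deterministic scenario list mirrors the published one-way analyses:
#' incidence 30/20/10%, alternative comparators (SOFA, NEWS2), algorithm
#' specificity at the clinical-practice level, detection lead times of
#' -4/-2/-1 h, septic-shock prevalence variants (30% and time-independent
#' 56.6%), alternative in-hospital mortality models (linear survival
#' decrease per Kumar; constant mortality per Lengquist), lengths of stay
#' and unit costs +/-25%, post-discharge variants, long-term variants
#' (general-population survival, consequences off, 1-year horizon), and a
#' 0% discount rate.
#'
#' @return named list of scenario specs; each spec is a list with `name`
#'   and `overrides` (see [apply_overrides()])
#' @export
scenario_presets <- function() {
  sc <- function(name, overrides) list(name = name, overrides = overrides)
  list(
    sc("Incidence 30%", list("cohort.incidence" = 0.30)),
    sc("Incidence 20%", list("cohort.incidence" = 0.20)),
    sc("Incidence 10%", list("cohort.incidence" = 0.10)),
    sc("Comparator SOFA (sens 80.0%, spec 48.0%)",
       list("comparator_test.sensitivity" = 0.80,
            "comparator_test.specificity" = 0.48)),
    sc("Comparator NEWS2 (sens 84.0%, spec 37.0%)",
       list("comparator_test.sensitivity" = 0.84,
            "comparator_test.specificity" = 0.37)),
    sc("Algorithm specificity 78.5% (Sepsis-3)",
       list("algorithm_test.specificity" = 0.785)),
    sc("Detection 4 hours earlier", list("timing.t_tp_algorithm" = -4)),
    sc("Detection 2 hours earlier", list("timing.t_tp_algorithm" = -2)),
    sc("Detection 1 hour earlier", list("timing.t_tp_algorithm" = -1)),
    sc("Septic shock 30% at earlier detection",
       list("shock_risk.p_early" = 0.30)),
    sc("Septic shock 56.6% regardless of detection time",
       list("shock_risk.time_dependent" = FALSE)),
    sc("Mortality model: Kumar (linear survival decrease)",
       list("mortality.model" = "kumar")),
    sc("Mortality model: Lengquist (constant 33%/22%)",
       list("mortality.model" = "lengquist")),
    sc("Length of stay ICU and ward +25%",
       stats::setNames(rep(list(list(multiply = 1.25)), 8),
                       paste0("los.", c("icu_shock", "icu_noshock",
                                        "icu_true_negative", "icu_false_positive",
                                        "ward_shock", "ward_noshock",
                                        "ward_true_negative", "ward_false_positive")))),
    sc("Length of stay ICU and ward -25%",
       stats::setNames(rep(list(list(multiply = 0.75)), 8),
                       paste0("los.", c("icu_shock", "icu_noshock",
                                        "icu_true_negative", "icu_false_positive",
                                        "ward_shock", "ward_noshock",
                                        "ward_true_negative", "ward_false_positive")))),
    sc("Post-discharge shock mortality 0%",
       list("postdischarge.postdischarge_mortality_year1_shock" = 0)),
    sc("Readmission rate 0%",
       list("postdischarge.readmission_rate_year1" = 0)),
    sc("Readmission rate 40%",
       list("postdischarge.readmission_rate_year1" = 0.40)),
    sc("Unit cost of ICU and ward day +25%",
       list("costs.icu_day" = list(multiply = 1.25),
            "costs.ward_day" = list(multiply = 1.25))),
    sc("Unit cost of ICU and ward day -25%",
       list("costs.icu_day" = list(multiply = 0.75),
            "costs.ward_day" = list(multiply = 0.75))),
    sc("Unit cost of readmission +25%",
       list("costs.readmission_event" = list(multiply = 1.25))),
    sc("Unit cost of readmission -25%",
       list("costs.readmission_event" = list(multiply = 0.75))),
    sc("Long-term survival same as general population",
       list("longterm.rr_years_1_5" = 1, "longterm.rr_years_6_10" = 1,
            "longterm.rr_years_11_plus" = 1)),
    sc("Long-term consequences not included",
       list("longterm.include_longterm_consequences" = FALSE)),
    sc("Model time horizon 1 year",
       list("longterm.time_horizon_years" = 1)),
    sc("Discount rate 0%", list("longterm.discount_rate" = 0))
  )
}

#' Run one deterministic scenario
#'
#' Applies the scenario's overrides to the configuration, re-runs the full
#' incremental model, and reports the national cost impact and the percent
#' change versus the base case in the published sign convention (positive
#' percent = larger savings than base case).
#'
#' @param config base-case configuration
#' @param spec list with `name` and `overrides`
#' @param base optional precomputed base-case [incremental()] result
#' @return list with `name`, `per_patient_delta` (EUR),
#'   `national_cost_impact` (EUR/year) and `pct_change_vs_base`
#' @export
run_scenario <- function(config, spec, base = NULL) {
  if (is.null(base)) base <- incremental(config)
  cfg <- apply_overrides(config, spec$overrides)
  inc <- incremental(cfg)
  base_impact <- base$national[["cost_total"]]
  impact <- inc$national[["cost_total"]]
  list(name = spec$name,
       per_patient_delta = inc$per_patient[["cost_total"]],
       national_cost_impact = impact,
       pct_change_vs_base = (base_impact - impact) / abs(base_impact) * 100)
}

#' Run the full scenario table
#'
#' Evaluates every scenario in `specs` (defaulting to the shipped presets).
#' A failing scenario is reported in its row's `error` column without
#' aborting the batch.
#'
#' @param config base-case configuration
#' @param specs list of scenario specs (default [scenario_presets()])
#' @return data.frame with one row per scenario: `name`,
#'   `per_patient_delta`, `national_cost_impact`, `pct_change_vs_base`,
#'   `error`
#' @examples
#' \donttest{
#' tab <- run_scenario_table(default_base_case())
#' tab[tab$name == "Readmission rate 0%", ]
#' }
#' @export
run_scenario_table <- function(config, specs = scenario_presets()) {
  base <- incremental(config)
  rows <- lapply(specs, function(spec) {
    res <- tryCatch(run_scenario(config, spec, base = base),
                    error = function(e) list(name = spec$name,
                                             per_patient_delta = NA_real_,
                                             national_cost_impact = NA_real_,
                                             pct_change_vs_base = NA_real_,
                                             error = conditionMessage(e)))
    data.frame(name = res$name,
               per_patient_delta = res$per_patient_delta,
               national_cost_impact = res$national_cost_impact,
               pct_change_vs_base = res$pct_change_vs_base,
               error = if (is.null(res$error)) "" else res$error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_national_cost_impact") <- base$national[["cost_total"]]
  out
}
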