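#' Decision-tree leaf probabilities
#'
#' Splits the cohort by sepsis incidence and by the screening method's
#' sensitivity/specificity into the four mutually exclusive pathways:
#' true positive, false negative, true negative, false positive.
#'
#' @param incidence probability of developing sepsis after ICU admission
#' @param test list with `sensitivity` and `specificity`
#' @return list with `tp`, `fn`, `tn`, `fp` (sums to 1)
#' @examples
#' leaf_probabilities(0.141, list(sensitivity = 0.80, specificity = 0.851))
#' @export
leaf_probabilities <- function(incidence, test) {
  stopifnot(incidence >= 0, incidence <= 1)
  list(tp = incidence * test$sensitivity,
       fn = incidence * (1 - test$sensitivity),
       tn = (1 - incidence) * test$specificity,
       fp = (1 - incidence) * (1 - test$specificity))
}

# arm helpers -----------------------------------------------------------

arm_test <- function(config, arm) {
  switch(arm, algorithm = config$algorithm_test,
         comparator = config$comparator_test,
         stop("unknown arm: ", arm))
}

# total hours to treatment for TP and FN leaves of one arm
arm_times <- function(config, arm) {
  tp_offset <- switch(arm, algorithm = config$timing$t_tp_algorithm,
                      comparator = config$timing$t_tp_comparator,
                      stop("unknown arm: ", arm))
  ab <- config$timing$t_antibiotic_from_detection
  list(t_tp = tp_offset + ab, t_fn = config$timing$t_fn + ab)
}

#' Expected length of stay for one arm
#'
#' Probability-weighted mean over the four leaves. Sepsis leaves (TP, FN)
#' mix the septic-shock and non-shock lengths of stay using the shock
#' probability at the leaf's time to treatment; TN and FP use their fixed
#' values.
#'
#' @param config a `septicost_config`
#' @param arm `"algorithm"` or `"comparator"`
#' @return list with `icu_days` and `ward_days` per patient
#' @export
expected_los <- function(config, arm) {
  lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
  tt <- arm_times(config, arm)
  los <- config$los
  mix <- function(t, shock, noshock) {
    p <- shock_probability(config$shock_risk, t)
    p * shock + (1 - p) * noshock
  }
  icu <- lv$tp * mix(tt$t_tp, los$icu_shock, los$icu_noshock) +
    lv$fn * mix(tt$t_fn, los$icu_shock, los$icu_noshock) +
    lv$tn * los$icu_true_negative + lv$fp * los$icu_false_positive
  ward <- lv$tp * mix(tt$t_tp, los$ward_shock, los$ward_noshock) +
    lv$fn * mix(tt$t_fn, los$ward_shock, los$ward_noshock) +
    lv$tn * los$ward_true_negative + lv$fp * los$ward_false_positive
  list(icu_days = icu, ward_days = ward)
}

#' Expected in-hospital mortality for one arm
#'
#' Sum over the sepsis leaves of the leaf probability times the
#' shock-mixture mortality at the leaf's time to treatment. Non-sepsis
#' leaves contribute 0 (no in-hospital survival assumptions are made for
#' patients without sepsis; identical in both arms, so it cancels).
#'
#' @inheritParams expected_los
#' @return probability of in-hospital death
#' @export
in_hospital_mortality <- function(config, arm) {
  lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
  tt <- arm_times(config, arm)
  mort_at <- function(t) {
    p <- shock_probability(config$shock_risk, t)
    p * mortality_shock(config$mortality, t) +
      (1 - p) * mortality_nonshock(config$mortality, t)
  }
  lv$tp * mort_at(tt$t_tp) + lv$fn * mort_at(tt$t_fn)
}

#' Expected first-year readmission proportion for one arm
#'
#' The first-year readmission rate applied to hospital survivors. By
#' default the rate is applied to all survivors (sepsis and non-sepsis),
#' which is the accounting that reproduces the published per-arm
#' readmission proportions and costs; setting
#' `postdischarge.readmission_population = "sepsis_survivors"` restricts it
#' to sepsis survivors.
#'
#' @inheritParams expected_los
#' @return expected readmissions per patient
#' @export
readmission_proportion <- function(config, arm) {
  rate <- config$postdischarge$readmission_rate_year1
  if (identical(config$postdischarge$readmission_population, "sepsis_survivors")) {
    lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
    tt <- arm_times(config, arm)
    surv_at <- function(t) {
      p <- shock_probability(config$shock_risk, t)
      p * (1 - mortality_shock(config$mortality, t)) +
        (1 - p) * (1 - mortality_nonshock(config$mortality, t))
    }
    return(rate * (lv$tp * surv_at(tt$t_tp) + lv$fn * surv_at(tt$t_fn)))
  }
  rate * (1 - in_hospital_mortality(config, arm))
}

# probability of being a sepsis patient alive 1 year after discharge:
# shock survivors carry the first-year post-discharge mortality, non-shock
# survivors are assumed alive at 1 year.
sepsis_survivor_1yr <- function(config, arm) {
  lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
  tt <- arm_times(config, arm)
  pd <- config$postdischarge$postdischarge_mortality_year1_shock
  surv_at <- function(t) {
    p <- shock_probability(config$shock_risk, t)
    p * (1 - mortality_shock(config$mortality, t)) * (1 - pd) +
      (1 - p) * (1 - mortality_nonshock(config$mortality, t))
  }
  lv$tp * surv_at(tt$t_tp) + lv$fn * surv_at(tt$t_fn)
}

#' Evaluate one arm of the decision tree
#'
#' Assembles every per-patient expectation for one arm: leaf probabilities,
#' lengths of stay, in-hospital mortality, readmissions, shock
#' probabilities at the arm's treatment times, the one-year sepsis-survivor
#' probability, itemised costs, and discounted QALYs. The prediction cost is
#' charged once per ICU patient in the algorithm arm only.
#'
#' @inheritParams expected_los
#' @return a list of class `septicost_arm` with components `leaves`,
#'   `expected_icu_days`, `expected_ward_days`, `in_hospital_mortality`,
#'   `readmission_proportion`, `shock_probability_tp`,
#'   `shock_probability_fn`, `sepsis_survivor_1yr`, `cost_prediction`,
#'   `cost_icu`, `cost_ward`, `cost_readmission`, `cost_longterm`,
#'   `cost_total`, `qalys`.
#' @examples
#' evaluate_arm(default_base_case(), "comparator")$cost_total
#' @export
evaluate_arm <- function(config, arm) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
  tt <- arm_times(config, arm)
  los <- expected_los(config, arm)
  mort <- in_hospital_mortality(config, arm)
  readm <- readmission_proportion(config, arm)
  surv1 <- sepsis_survivor_1yr(config, arm)
  lump <- effective_longterm_lump(config)

  costs <- config$costs
  cost_prediction <- if (arm == "algorithm") costs$prediction_cost_per_patient else 0
  cost_icu <- los$icu_days * costs$icu_day
  cost_ward <- los$ward_days * costs$ward_day
  cost_readmission <- readm * costs$readmission_event
  cost_longterm <- longterm_consequence_cost(surv1, lump)

  out <- list(
    arm = arm,
    leaves = lv,
    expected_icu_days = los$icu_days,
    expected_ward_days = los$ward_days,
    in_hospital_mortality = mort,
    readmission_proportion = readm,
    shock_probability_tp = shock_probability(config$shock_risk, tt$t_tp),
    shock_probability_fn = shock_probability(config$shock_risk, tt$t_fn),
    sepsis_survivor_1yr = surv1,
    cost_prediction = cost_prediction,
    cost_icu = cost_icu,
    cost_ward = cost_ward,
    cost_readmission = cost_readmission,
    cost_longterm = cost_longterm,
    cost_total = cost_prediction + cost_icu + cost_ward +
      cost_readmission + cost_longterm,
    qalys = arm_qalys(config, lv, tt$t_tp, tt$t_fn)
  )
  class(out) <- "septicost_arm"
  out
}

#' Incremental (algorithm minus comparator) and national results
#'
#' Runs both arms, differences every outcome, scales the differences to the
#' national cohort of ICU admissions without sepsis, and classifies
#' cost-effectiveness (ICER or dominance).
#'
#' @param config a `septicost_config`
#' @return a list of class `septicost_incremental` with `algorithm` and
#'   `comparator` arm outcomes, `per_patient` and `national` named numeric
#'   vectors, `lives_saved_national`, `icu_days_saved_national`,
#'   `ward_days_saved_national`, and `icer`.
#' @examples
#' inc <- incremental(default_base_case())
#' round(inc$per_patient[["cost_total"]])
#' @export
incremental <- function(config) {
  alg <- evaluate_arm(config, "algorithm")
  comp <- evaluate_arm(config, "comparator")
  fields <- c("expected_icu_days", "expected_ward_days", "in_hospital_mortality",
              "readmission_proportion", "sepsis_survivor_1yr",
              "cost_prediction", "cost_icu", "cost_ward", "cost_readmission",
              "cost_longterm", "cost_total", "qalys")
  per_patient <- vapply(fields, function(f) alg[[f]] - comp[[f]], numeric(1))
  n <- config$cohort$n_icu_admissions_no_sepsis
  out <- list(
    algorithm = alg,
    comparator = comp,
    per_patient = per_patient,
    national = per_patient * n,
    lives_saved_national = -per_patient[["in_hospital_mortality"]] * n,
    icu_days_saved_national = -per_patient[["expected_icu_days"]] * n,
    ward_days_saved_national = -per_patient[["expected_ward_days"]] * n,
    icer = icer(per_patient[["cost_total"]], per_patient[["qalys"]])
  )
  class(out) <- "septicost_incremental"
  out
}

#' @export
print.septicost_incremental <- function(x, ...) {
  cat("<septicost_incremental> (algorithm - comparator)\n")
  cat(sprintf("  total cost/patient: %.0f vs %.0f EUR (delta %+.1f)\n",
              x$algorithm$cost_total, x$comparator$cost_total,
              x$per_patient[["cost_total"]]))
  cat(sprintf("  national cost impact: %+.0f EUR/year\n",
              x$national[["cost_total"]]))
  cat(sprintf("  lives saved: %.0f; ICU days saved: %.0f; ward days saved: %.0f\n",
              x$lives_saved_national, x$icu_days_saved_national,
              x$ward_days_saved_national))
  cat(sprintf("  QALYs/patient: %+.4f; classification: %s\n",
              x$per_patient[["qalys"]], x$icer$classification))
  invisible(x)
}

#' Worked example: prediction cost from a per-ICU-day price
#'
#' Converts a price per ICU day into the per-patient prediction cost
#' (price times expected ICU days) and the cost per sepsis patient detected
#' (per-patient cost divided by incidence).
#'
#' @param price_per_icu_day EUR per ICU day for the prediction algorithm
#' @param expected_icu_days expected ICU length of stay per patient
#' @param incidence sepsis incidence (> 0)
#' @return list with `per_patient` and `per_sepsis_patient` (EUR)
#' @examples
#' worked_example_prediction_cost(90, 1.62, 0.141)
#' @export
worked_example_prediction_cost <- function(price_per_icu_day, expected_icu_days,
                                           incidence) {
  if (incidence == 0) stop("incidence must be positive", call. = FALSE)
  per_patient <- price_per_icu_day * expected_icu_days
  list(per_patient = per_patient,
       per_sepsis_patient = per_patient / incidence)
}
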