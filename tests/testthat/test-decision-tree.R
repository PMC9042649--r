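test_that("leaf probabilities follow sensitivity/specificity splits", {
  lv <- leaf_probabilities(0.141, list(sensitivity = 0.80, specificity = 0.851))
  expect_equal(lv$tp, 0.1128)
  expect_equal(lv$fn, 0.0282)
  expect_equal(lv$tn, 0.731009)
  expect_equal(lv$fp, 0.127991)
  expect_equal(lv$tp + lv$fn + lv$tn + lv$fp, 1, tolerance = 1e-12)

  perfect <- leaf_probabilities(0.141, list(sensitivity = 1, specificity = 1))
  expect_equal(perfect$fn, 0)
  expect_equal(perfect$fp, 0)

  none <- leaf_probabilities(0, list(sensitivity = 0.8, specificity = 0.9))
  expect_equal(none$tp + none$fn, 0)
  expect_equal(none$tn + none$fp, 1)
})

test_that("expected lengths of stay reproduce the published per-arm values", {
  alg <- expected_los(base_cfg, "algorithm")
  comp <- expected_los(base_cfg, "comparator")
  expect_equal(alg$icu_days, 1.6241, tolerance = 1e-4)
  expect_equal(comp$icu_days, 1.7829, tolerance = 1e-4)
  expect_equal(round(alg$icu_days, 2), 1.62)
  expect_equal(round(comp$icu_days, 2), 1.78)
  # weighted-sum oracle over the four leaves, independent arithmetic
  lv <- base_leaves_alg
  p3 <- 0.40; pf <- 0.566 + (0.566 - 0.40) / 3 * 3
  ward_oracle <- lv$tp * (p3 * 17 + (1 - p3) * 5.7) +
    lv$fn * (pf * 17 + (1 - pf) * 5.7) + (lv$tn + lv$fp) * 5.7
  expect_equal(alg$ward_days, ward_oracle, tolerance = 1e-12)
  expect_equal(alg$ward_days, 6.4431, tolerance = 1e-4)
  expect_equal(round(comp$ward_days, 2), 6.66)
})

test_that("in-hospital mortality reproduces the published per-arm values", {
  expect_equal(round(in_hospital_mortality(base_cfg, "algorithm"), 5), 0.02751)
  expect_equal(round(in_hospital_mortality(base_cfg, "comparator"), 5), 0.03715)
  expect_equal(round(100 * in_hospital_mortality(base_cfg, "algorithm"), 1), 2.8)
  expect_equal(round(100 * in_hospital_mortality(base_cfg, "comparator"), 1), 3.7)
  cfg0 <- config_set(base_cfg, "cohort.incidence", 1e-12)
  expect_equal(in_hospital_mortality(cfg0, "algorithm"), 0, tolerance = 1e-10)
})

test_that("readmission proportions and survivor probabilities match", {
  expect_equal(round(100 * readmission_proportion(base_cfg, "algorithm"), 1), 20.0)
  expect_equal(round(100 * readmission_proportion(base_cfg, "comparator"), 1), 19.8)
  cfg <- config_set(base_cfg, "postdischarge.readmission_rate_year1", 0)
  expect_equal(readmission_proportion(cfg, "algorithm"), 0)
  expect_equal(sepsis_survivor_1yr_oracle(base_cfg, "algorithm"),
               evaluate_arm(base_cfg, "algorithm")$sepsis_survivor_1yr,
               tolerance = 1e-12)
  expect_equal(round(evaluate_arm(base_cfg, "algorithm")$sepsis_survivor_1yr, 5),
               0.10678)
  expect_equal(round(evaluate_arm(base_cfg, "comparator")$sepsis_survivor_1yr, 5),
               0.09551)
})

test_that("arm evaluation reproduces the published cost table", {
  alg <- evaluate_arm(base_cfg, "algorithm")
  comp <- evaluate_arm(base_cfg, "comparator")
  expect_equal(alg$cost_total, 16436, tolerance = 5 / 16436)
  expect_equal(comp$cost_total, 16512, tolerance = 5 / 16512)
  expect_equal(alg$cost_longterm, 208, tolerance = 1 / 208)
  expect_equal(comp$cost_longterm, 186, tolerance = 1 / 186)
  expect_equal(round(alg$cost_readmission), 835)
  expect_equal(round(comp$cost_readmission), 826)
  expect_equal(alg$cost_prediction, 1037)
  expect_equal(comp$cost_prediction, 0)
  # cost identity: total equals the sum of its components
  for (arm in list(alg, comp)) {
    expect_equal(arm$cost_total,
                 arm$cost_prediction + arm$cost_icu + arm$cost_ward +
                   arm$cost_readmission + arm$cost_longterm,
                 tolerance = 1e-10)
  }
})

test_that("incremental results reproduce the published national figures", {
  inc <- incremental(base_cfg)
  expect_equal(inc$per_patient[["cost_total"]], -76, tolerance = 1 / 76)
  expect_equal(inc$lives_saved_national, 356, tolerance = 1 / 356)
  expect_equal(inc$icu_days_saved_national, 5860, tolerance = 0.01)
  expect_equal(inc$ward_days_saved_national, 7886, tolerance = 0.01)
  # national values are exactly per-patient times the cohort
  expect_equal(inc$national, inc$per_patient * 36900, tolerance = 1e-12)
  expect_equal(inc$icer$classification, "dominant")
  expect_gt(inc$per_patient[["qalys"]], 0)
})

test_that("equalising the arms gives identically zero incrementals", {
  inc <- incremental(equalised_config())
  expect_equal(unname(inc$per_patient), rep(0, length(inc$per_patient)),
               tolerance = 1e-12)
  expect_equal(inc$lives_saved_national, 0, tolerance = 1e-9)
})

test_that("every expectation is a convex combination of leaf values", {
  los <- expected_los(base_cfg, "algorithm")
  expect_gte(los$icu_days, min(base_cfg$los$icu_true_negative,
                               base_cfg$los$icu_noshock))
  expect_lte(los$icu_days, base_cfg$los$icu_shock)
  expect_lte(in_hospital_mortality(base_cfg, "algorithm"), 1)
})

test_that("earlier detection never worsens stays, mortality or sepsis cost", {
  prev <- NULL
  for (t_tp in seq(0, -6, by = -0.5)) {
    cfg <- config_set(base_cfg, "timing.t_tp_algorithm", t_tp)
    arm <- evaluate_arm(cfg, "algorithm")
    cur <- c(arm$expected_icu_days, arm$expected_ward_days,
             arm$in_hospital_mortality, arm$cost_icu + arm$cost_ward)
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12), info = t_tp)
    prev <- cur
  }
})

test_that("the worked prediction-cost example reproduces the published figures", {
  ex <- worked_example_prediction_cost(90, 1.62, 0.141)
  expect_equal(ex$per_patient, 146, tolerance = 1 / 146)
  ex2 <- worked_example_prediction_cost(
    90, expected_los(base_cfg, "algorithm")$icu_days, 0.141)
  expect_equal(ex2$per_sepsis_patient, 1037, tolerance = 3 / 1037)
  expect_equal(worked_example_prediction_cost(0, 5, 0.2)$per_patient, 0)
  expect_error(worked_example_prediction_cost(90, 1.62, 0), "incidence")
})
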