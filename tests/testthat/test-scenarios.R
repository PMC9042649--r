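test_that("an empty scenario reproduces the base case exactly", {
  res <- run_scenario(base_cfg, list(name = "identity", overrides = list()))
  base <- incremental(base_cfg)
  expect_equal(res$national_cost_impact, base$national[["cost_total"]],
               tolerance = 1e-12)
  expect_equal(res$pct_change_vs_base, 0, tolerance = 1e-9)
})

test_that("the preset list covers every published scenario row", {
  expect_length(scenario_presets(), 26)
  tab <- run_scenario_table(base_cfg)
  expect_equal(nrow(tab), 26)
  expect_true(all(tab$error == ""))
})

test_that("cost-component scenarios match the published national impacts", {
  tab <- run_scenario_table(base_cfg)
  impact <- function(name) tab$national_cost_impact[tab$name == name]
  expect_equal(impact("Readmission rate 0%"), -3104513, tolerance = 0.01)
  expect_equal(impact("Readmission rate 40%"), -2511118, tolerance = 0.01)
  expect_equal(impact("Unit cost of ICU and ward day +25%"), -13344318,
               tolerance = 0.01)
  expect_equal(impact("Unit cost of ICU and ward day -25%"), 7746489,
               tolerance = 0.01)
  expect_equal(impact("Long-term consequences not included"), -3607600,
               tolerance = 0.01)
  expect_equal(impact("Model time horizon 1 year"), -3607600, tolerance = 0.01)
  # the two long-term rows are exactly equal to each other
  expect_equal(impact("Long-term consequences not included"),
               impact("Model time horizon 1 year"), tolerance = 1e-9)
  # LOS scaling and unit-cost scaling are the same operation on costs
  expect_equal(impact("Length of stay ICU and ward +25%"),
               impact("Unit cost of ICU and ward day +25%"), tolerance = 1e-9)
})

test_that("scenarios touching one linear component obey the additivity oracle", {
  base <- incremental(base_cfg)
  tab <- run_scenario_table(base_cfg)
  impact <- function(name) tab$national_cost_impact[tab$name == name]
  # readmission unit cost +25%: impact = base + 25% of the national
  # readmission increment
  expect_equal(impact("Unit cost of readmission +25%"),
               base$national[["cost_total"]] +
                 0.25 * base$national[["cost_readmission"]],
               tolerance = 1e-9)
  # long-term off: impact = base minus the national long-term increment
  expect_equal(impact("Long-term consequences not included"),
               base$national[["cost_total"]] -
                 base$national[["cost_longterm"]],
               tolerance = 1e-9)
  # ICU+ward cost +25%: base plus 25% of the hospitalisation increment
  expect_equal(impact("Unit cost of ICU and ward day +25%"),
               base$national[["cost_total"]] +
                 0.25 * (base$national[["cost_icu"]] +
                           base$national[["cost_ward"]]),
               tolerance = 1e-9)
})

test_that("scenario directions follow the published table", {
  tab <- run_scenario_table(base_cfg)
  impact <- function(name) tab$national_cost_impact[tab$name == name]
  base_impact <- attr(tab, "base_national_cost_impact")
  # higher incidence -> larger savings; incidence 10% flips to a cost
  expect_lt(impact("Incidence 30%"), impact("Incidence 20%"))
  expect_lt(impact("Incidence 20%"), base_impact)
  expect_gt(impact("Incidence 10%"), 0)
  # worse comparator specificity -> larger savings
  expect_lt(impact("Comparator SOFA (sens 80.0%, spec 48.0%)"), base_impact)
  expect_lt(impact("Comparator NEWS2 (sens 84.0%, spec 37.0%)"),
            impact("Comparator SOFA (sens 80.0%, spec 48.0%)"))
  # losing the algorithm's specificity advantage flips the sign
  expect_gt(impact("Algorithm specificity 78.5% (Sepsis-3)"), 0)
  # detection lead: -4 h saves more than base; -2 h and -1 h flip positive
  expect_lt(impact("Detection 4 hours earlier"), base_impact)
  expect_gt(impact("Detection 2 hours earlier"), 0)
  expect_gt(impact("Detection 1 hour earlier"),
            impact("Detection 2 hours earlier"))
  # both alternative mortality models remain cost saving
  expect_lt(impact("Mortality model: Kumar (linear survival decrease)"), 0)
  expect_lt(impact("Mortality model: Lengquist (constant 33%/22%)"), 0)
})

test_that("a time-independent shock risk removes the detection benefit", {
  cfg <- apply_overrides(base_cfg, list("shock_risk.time_dependent" = FALSE))
  alg <- evaluate_arm(cfg, "algorithm")
  comp <- evaluate_arm(cfg, "comparator")
  # TP patients gain nothing on stays: shock mix is identical across arms,
  # so the only LOS difference left comes from test characteristics
  expect_equal(alg$shock_probability_tp, comp$shock_probability_tp)
  inc <- incremental(cfg)
  expect_gt(inc$national[["cost_total"]], 0)  # no cost savings remain
})

test_that("a failing scenario is reported per row without aborting the batch", {
  specs <- list(list(name = "bad", overrides = list("no.such" = 1)),
                list(name = "ok", overrides = list("cohort.incidence" = 0.2)))
  tab <- run_scenario_table(base_cfg, specs)
  expect_match(tab$error[tab$name == "bad"], "no.such")
  expect_true(is.na(tab$national_cost_impact[tab$name == "bad"]))
  expect_equal(tab$error[tab$name == "ok"], "")
  expect_false(is.na(tab$national_cost_impact[tab$name == "ok"]))
})

test_that("the shipped scenario YAML mirrors the preset list", {
  path <- system.file("extdata", "scenarios.yaml", package = "septicost")
  expect_true(nzchar(path))
  y <- yaml::read_yaml(path)
  presets <- scenario_presets()
  expect_length(y, length(presets))
  expect_equal(vapply(y, `[[`, "", "name"),
               vapply(presets, `[[`, "", "name"))
})
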