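# shared fixtures for the test suite; everything is built in code

base_cfg <- default_base_case()

# hand-computed leaf probabilities for the base case
base_leaves_alg <- list(tp = 0.141 * 0.80, fn = 0.141 * 0.20,
                        tn = 0.859 * 0.851, fp = 0.859 * 0.149)

# equal-arms configuration: algorithm identical to the comparator
equalised_config <- function(cfg = base_cfg) {
  cfg$algorithm_test <- cfg$comparator_test
  cfg$timing$t_tp_algorithm <- cfg$timing$t_tp_comparator
  cfg$costs$prediction_cost_per_patient <- 0
  cfg
}

# independent hand-arithmetic oracle for the 1-year sepsis-survivor
# probability (leaf-by-leaf survival bookkeeping, no package internals)
sepsis_survivor_1yr_oracle <- function(cfg, arm) {
  test <- if (arm == "algorithm") cfg$algorithm_test else cfg$comparator_test
  t_tp <- if (arm == "algorithm") cfg$timing$t_tp_algorithm else
    cfg$timing$t_tp_comparator
  slope <- (cfg$shock_risk$p_ref - cfg$shock_risk$p_early) /
    abs(cfg$shock_risk$t_early)
  pshock <- function(t) min(1, max(0, cfg$shock_risk$p_ref + slope * t))
  ms <- function(t) cfg$mortality$a * exp(cfg$mortality$b * t)
  mn <- function(t) max(0, cfg$mortality$c * t)
  pd <- cfg$postdischarge$postdischarge_mortality_year1_shock
  leaf <- function(t) {
    p <- pshock(t)
    p * (1 - ms(t)) * (1 - pd) + (1 - p) * (1 - mn(t))
  }
  inc <- cfg$cohort$incidence
  inc * test$sensitivity * leaf(t_tp) +
    inc * (1 - test$sensitivity) * leaf(cfg$timing$t_fn)
}

# flat-hazard toy life table for closed-form checks
flat_life_table <- function(q = 0.01, max_age = 110) {
  tab <- data.frame(age = 0:max_age, qx = q)
  tab$qx[nrow(tab)] <- 1
  tab
}
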