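#' Method-of-moments distribution builders
#'
#' Convert a (mean, SE) pair into the natural parameters of a beta, gamma or
#' log-normal distribution such that the distribution's first two moments
#' reproduce the inputs exactly.
#'
#' * beta: `nu = mean(1-mean)/se^2 - 1`, `alpha = mean*nu`,
#'   `beta = (1-mean)*nu`; requires `se^2 < mean(1-mean)`.
#' * gamma: `shape = (mean/se)^2`, `scale = se^2/mean`.
#' * log-normal: `sigma^2 = log(1 + se^2/mean^2)`,
#'   `mu = log(mean) - sigma^2/2`.
#'
#' @param mean target mean
#' @param se target standard error (> 0)
#' @param parameter_name used in error messages
#' @return named list of distribution parameters
#' @examples
#' beta_from_moments(0.141, 0.0038)
#' gamma_from_moments(7.4, 0.1989)
#' @export
beta_from_moments <- function(mean, se, parameter_name = "parameter") {
  if (!(mean > 0 && mean < 1)) {
    stop(parameter_name, ": beta mean must be in (0,1)", call. = FALSE)
  }
  if (!(se > 0) || se^2 >= mean * (1 - mean)) {
    stop(parameter_name, ": beta moment condition se^2 < mean(1-mean) violated",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' @rdname beta_from_moments
#' @export
gamma_from_moments <- function(mean, se, parameter_name = "parameter") {
  if (!(mean > 0 && se > 0)) {
    stop(parameter_name, ": gamma requires mean > 0 and se > 0", call. = FALSE)
  }
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' @rdname beta_from_moments
#' @export
lognormal_from_moments <- function(mean, se, parameter_name = "parameter") {
  if (!(mean > 0 && se > 0)) {
    stop(parameter_name, ": lognormal requires mean > 0 and se > 0", call. = FALSE)
  }
  sigma2 <- log(1 + se^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# n draws from one spec row; se = 0 degenerates to the mean
draw_from_spec <- function(family, mean, se, n, parameter_name = "parameter") {
  if (se == 0) return(rep(mean, n))
  switch(family,
    beta = {
      p <- beta_from_moments(mean, se, parameter_name)
      stats::rbeta(n, p$alpha, p$beta)
    },
    gamma = {
      p <- gamma_from_moments(mean, se, parameter_name)
      stats::rgamma(n, shape = p$shape, scale = p$scale)
    },
    lognormal = {
      p <- lognormal_from_moments(mean, se, parameter_name)
      stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
    },
    normal = stats::rnorm(n, mean, se),
    stop(parameter_name, ": unknown family '", family, "'", call. = FALSE)
  )
}

# mapping from PSA parameter names to configuration paths; parameters
# without a path (age bands not used at the base-case age) are drawn but
# inert in the model.
psa_parameter_paths <- function() {
  c(incidence = "cohort.incidence",
    sensitivity_algorithm = "algorithm_test.sensitivity",
    specificity_algorithm = "algorithm_test.specificity",
    sensitivity_comparator = "comparator_test.sensitivity",
    specificity_comparator = "comparator_test.specificity",
    t_tp_algorithm = "timing.t_tp_algorithm",
    t_fn = "timing.t_fn",
    t_antibiotic_from_detection = "timing.t_antibiotic_from_detection",
    shock_probability_early = "shock_risk.p_early",
    shock_probability_ref = "shock_risk.p_ref",
    rr_mortality_shock = "mortality.rr_shock_multiplier",
    rr_mortality_nonshock = "mortality.rr_noshock_multiplier",
    hr_years_1_5_60_70 = "longterm.rr_years_1_5",
    hr_years_6_10_60_70 = "longterm.rr_years_6_10",
    icu_days_shock = "los.icu_shock",
    icu_days_noshock = "los.icu_noshock",
    icu_days_true_negative = "los.icu_true_negative",
    icu_days_false_positive = "los.icu_false_positive",
    ward_days_shock = "los.ward_shock",
    ward_days_noshock = "los.ward_noshock",
    ward_days_true_negative = "los.ward_true_negative",
    ward_days_false_positive = "los.ward_false_positive",
    postdischarge_mortality_shock = "postdischarge.postdischarge_mortality_year1_shock",
    readmission_rate = "postdischarge.readmission_rate_year1",
    utility_decrement_years_1_5 = "longterm.utility_decrement_years_1_5",
    utility_decrement_years_6_10 = "longterm.utility_decrement_years_6_10",
    utility_decrement_years_11_plus = "longterm.utility_decrement_years_11_plus",
    freq_impaired_kidney_function = "longterm.consequence_frequencies.impaired_kidney_function",
    freq_amputation = "longterm.consequence_frequencies.amputation",
    freq_depression = "longterm.consequence_frequencies.depression",
    freq_ptsd = "longterm.consequence_frequencies.ptsd")
}

# one independent RNG stream per parameter, derived from the master seed in
# the spec list's row order, so conditioning one parameter on its mean never
# shifts another parameter's draws.
psa_draw_matrix <- function(specs, n_draws, seed) {
  set.seed(seed)
  stream_seeds <- sample.int(2147483646L, nrow(specs))
  draws <- matrix(NA_real_, nrow = n_draws, ncol = nrow(specs),
                  dimnames = list(NULL, specs$name))
  for (i in seq_len(nrow(specs))) {
    set.seed(stream_seeds[i])
    draws[, i] <- draw_from_spec(specs$family[i], specs$mean[i], specs$se[i],
                                 n_draws, specs$name[i])
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Samples every parameter in the configuration's distribution list from its
#' method-of-moments distribution (one independent, seeded random stream per
#' parameter), overlays each draw on the configuration, re-runs the full
#' model (decision tree plus long-term projection), and records the
#' incremental cost and QALYs per draw. Draws whose sampled shock
#' prevalences cross (early > reference) are re-clamped to the boundary and
#' counted; a warning is issued if more than 1% of draws needed clamping.
#'
#' `conditioned_psa` re-runs the analysis with one named parameter held
#' constant at its mean while all others vary — the published scheme for
#' ranking parameter influence.
#'
#' @param config a `septicost_config`
#' @param n_draws number of simulations (published analysis: 1000)
#' @param seed master RNG seed
#' @param condition_on optional parameter name to hold at its mean
#' @return list of class `septicost_psa` with `n_draws`, `seed`,
#'   `condition_on`, `draws` (data.frame with per-draw `delta_cost`,
#'   `delta_qaly`, `classification`), `summary` (quartiles, median and
#'   whiskers of `delta_cost`), `fraction_dominant`,
#'   `fraction_below_threshold` (named by threshold), and `n_clamped`.
#' @examples
#' \donttest{
#' psa <- run_psa(default_base_case(), n_draws = 100, seed = 1)
#' psa$fraction_dominant
#' }
#' @export
run_psa <- function(config, n_draws = 1000, seed = 1, condition_on = NULL) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  specs <- config$psa_specs
  if (!is.null(condition_on)) {
    if (!condition_on %in% specs$name) {
      stop("unknown PSA parameter '", condition_on, "'; valid names: ",
           paste(specs$name, collapse = ", "), call. = FALSE)
    }
  }
  draws <- psa_draw_matrix(specs, n_draws, seed)
  if (!is.null(condition_on)) {
    draws[, condition_on] <- specs$mean[specs$name == condition_on]
  }
  paths <- psa_parameter_paths()

  delta_cost <- numeric(n_draws)
  delta_qaly <- numeric(n_draws)
  classification <- character(n_draws)
  n_clamped <- 0L
  for (d in seq_len(n_draws)) {
    cfg <- config
    for (nm in colnames(draws)) {
      path <- paths[nm]
      if (is.na(path)) next
      cfg <- config_set(cfg, unname(path), unname(draws[d, nm]))
    }
    # re-clamp draws that violate the shock-line ordering
    if (cfg$shock_risk$p_early > cfg$shock_risk$p_ref) {
      cfg$shock_risk$p_early <- cfg$shock_risk$p_ref
      n_clamped <- n_clamped + 1L
    }
    if (cfg$timing$t_tp_algorithm > cfg$timing$t_fn) {
      cfg$timing$t_tp_algorithm <- cfg$timing$t_fn
      n_clamped <- n_clamped + 1L
    }
    inc <- incremental_unvalidated(cfg)
    delta_cost[d] <- inc$per_patient[["cost_total"]]
    delta_qaly[d] <- inc$per_patient[["qalys"]]
    classification[d] <- inc$icer$classification
  }
  if (n_clamped > 0.01 * n_draws) {
    warning(sprintf("%d of %d PSA draws required re-clamping to the parameter support",
                    n_clamped, n_draws), call. = FALSE)
  }
  qs <- stats::quantile(delta_cost, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  iqr <- qs[4] - qs[2]
  res <- list(
    n_draws = n_draws, seed = seed, condition_on = condition_on,
    draws = data.frame(delta_cost = delta_cost, delta_qaly = delta_qaly,
                       classification = classification),
    summary = c(min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
                whisker_low = max(qs[1], qs[2] - 1.5 * iqr),
                whisker_high = min(qs[5], qs[4] + 1.5 * iqr),
                mean = mean(delta_cost)),
    fraction_dominant = mean(classification == "dominant"),
    n_clamped = n_clamped
  )
  class(res) <- "septicost_psa"
  res$fraction_below_threshold <- vapply(
    config$wtp_thresholds, function(w) threshold_fraction(res, w), numeric(1))
  names(res$fraction_below_threshold) <- as.character(config$wtp_thresholds)
  res
}

# incremental() without re-validating each PSA draw (draws live on their
# family's support by construction; clamping handled by the caller)
incremental_unvalidated <- function(config) {
  alg <- evaluate_arm_unvalidated(config, "algorithm")
  comp <- evaluate_arm_unvalidated(config, "comparator")
  per_patient <- c(cost_total = alg$cost_total - comp$cost_total,
                   qalys = alg$qalys - comp$qalys)
  list(per_patient = per_patient,
       icer = icer(per_patient[["cost_total"]], per_patient[["qalys"]]))
}

evaluate_arm_unvalidated <- function(config, arm) {
  lv <- leaf_probabilities(config$cohort$incidence, arm_test(config, arm))
  tt <- arm_times(config, arm)
  los <- expected_los(config, arm)
  readm <- readmission_proportion(config, arm)
  surv1 <- sepsis_survivor_1yr(config, arm)
  lump <- effective_longterm_lump(config)
  costs <- config$costs
  cost_total <- (if (arm == "algorithm") costs$prediction_cost_per_patient else 0) +
    los$icu_days * costs$icu_day + los$ward_days * costs$ward_day +
    readm * costs$readmission_event + surv1 * lump
  list(cost_total = cost_total,
       qalys = arm_qalys(config, lv, tt$t_tp, tt$t_fn))
}

#' @rdname run_psa
#' @param parameter_name parameter to hold at its mean
#' @export
conditioned_psa <- function(config, parameter_name, n_draws = 1000, seed = 1) {
  run_psa(config, n_draws = n_draws, seed = seed, condition_on = parameter_name)
}

#' Fraction of PSA draws cost-effective at a willingness-to-pay threshold
#'
#' A draw counts as below the threshold if it is dominant (cost-saving and
#' QALY-gaining) or if it gains QALYs at a cost per QALY under the
#' threshold. Dominated draws never count.
#'
#' @param result a `septicost_psa`
#' @param wtp willingness-to-pay threshold (EUR/QALY)
#' @return fraction in \[0,1\]
#' @export
threshold_fraction <- function(result, wtp) {
  d <- result$draws
  ok <- (d$classification == "dominant") |
    (d$delta_qaly > 0 & d$delta_cost / d$delta_qaly < wtp)
  mean(ok)
}

#' @export
print.septicost_psa <- function(x, ...) {
  cat(sprintf("<septicost_psa> %d draws, seed %d%s\n", x$n_draws, x$seed,
              if (is.null(x$condition_on)) "" else
                paste0(", conditioned on ", x$condition_on)))
  cat(sprintf("  delta cost/patient: median %+.1f [Q1 %+.1f, Q3 %+.1f] EUR\n",
              x$summary[["median"]], x$summary[["q1"]], x$summary[["q3"]]))
  cat(sprintf("  fraction dominant: %.3f\n", x$fraction_dominant))
  for (w in names(x$fraction_below_threshold)) {
    cat(sprintf("  fraction below %s EUR/QALY: %.3f\n", w,
                x$fraction_below_threshold[[w]]))
  }
  invisible(x)
}
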