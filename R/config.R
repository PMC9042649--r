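#' @keywords internal
clamp01 <- function(x) pmin(1, pmax(0, x))

#' Base-case model configuration
#'
#' Builds the complete parameter set for one model run of the sepsis
#' early-detection decision-tree model: cohort definition, test
#' characteristics of the prediction algorithm and of sepsis diagnosis in
#' current clinical practice, timing policy, septic-shock risk line,
#' in-hospital mortality curves, lengths of stay, unit costs, post-discharge
#' and long-term parameters, the probabilistic-sensitivity-analysis
#' distribution list, and the willingness-to-pay thresholds.
#'
#' Three unit costs (`icu_day`, `ward_day`, `longterm_cost_per_survivor`) are
#' not published as primary inputs; they are back-calculated from the
#' published per-arm aggregate results (per-arm hospitalisation cost divided
#' by per-arm expected length of stay, and long-term cost divided by the
#' model's one-year sepsis-survivor probability). Both arms give the same
#' constant to better than 0.1%, and the shipped default is the mean of the
#' two back-calculations.
#'
#' @return A named list of class `septicost_config`. See
#'   [validate_config()] for the field-level invariants.
#' @examples
#' cfg <- default_base_case()
#' cfg$cohort$incidence
#' @export
default_base_case <- function() {
  cfg <- list(
    cohort = list(
      incidence = 0.141,            # P(sepsis after ICU admission)
      mean_age = 60,
      n_icu_admissions_total = 45000,
      n_icu_admissions_no_sepsis = 36900
    ),
    algorithm_test = list(sensitivity = 0.800, specificity = 0.851),
    comparator_test = list(sensitivity = 0.792, specificity = 0.785),
    timing = list(
      t_tp_algorithm = -3,             # hours vs current-practice diagnosis
      t_tp_comparator = 0,
      t_fn = 3,                        # false negatives: 3 h extra delay
      t_antibiotic_from_detection = 0
    ),
    shock_risk = list(
      p_ref = 0.566,     # shock prevalence at t = 0 (current practice)
      p_early = 0.40,    # shock prevalence at t = t_early
      t_early = -3,
      time_dependent = TRUE
    ),
    mortality = list(
      model = "exponential_linear",   # or "kumar", "lengquist"
      a = 0.4281,        # shock mortality at t = 0
      b = 0.0272,        # exponential rate, 1/hour
      c = 0.0052,        # non-shock linear slope, 1/hour
      kumar_mortality_at_0 = 0.40,
      kumar_slope_per_hour = 0.076,
      lengquist_shock = 0.33,
      lengquist_nonshock = 0.22,
      rr_shock_multiplier = 1.0,
      rr_noshock_multiplier = 1.0
    ),
    los = list(
      icu_shock = 7.4, icu_noshock = 2.0,
      icu_true_negative = 1.0, icu_false_positive = 2.0,
      ward_shock = 17.0, ward_noshock = 5.7,
      ward_true_negative = 5.7, ward_false_positive = 5.7
    ),
    costs = list(
      icu_day = 6355.3843,            # EUR, back-calculated
      ward_day = 626.2624,            # EUR, back-calculated
      readmission_event = 4166,
      prediction_cost_per_patient = 1037,  # algorithm arm, once per ICU patient
      prediction_price_per_icu_day = 90,   # worked example only
      longterm_cost_per_survivor = 1947.7264  # EUR, back-calculated lump
    ),
    postdischarge = list(
      readmission_rate_year1 = 0.206,
      postdischarge_mortality_year1_shock = 0.175,
      readmission_population = "all_survivors"
    ),
    longterm = list(
      rr_years_1_5 = 5.5,
      rr_years_6_10 = 3.1,
      rr_years_11_plus = 1.0,
      utility_decrement_years_1_5 = -0.164,
      utility_decrement_years_6_10 = -0.124,
      utility_decrement_years_11_plus = 0,
      baseline_utility = 0.80,
      discount_rate = 0.03,
      consequence_frequencies = list(
        impaired_kidney_function = 0.141,
        amputation = 0.085,
        depression = 0.028,
        ptsd = 0.099
      ),
      include_longterm_consequences = TRUE,
      time_horizon_years = Inf        # lifetime: run to life-table exhaustion
    ),
    life_table = list(A = 5e-5, B = 0.095, max_age = 105),  # synthetic Gompertz
    psa_specs = default_psa_specs(),
    wtp_thresholds = c(20000, 50000)
  )
  class(cfg) <- "septicost_config"
  cfg
}

#' Default probabilistic-sensitivity-analysis distribution list
#'
#' One row per stochastic parameter: name, distribution family, mean and
#' standard error. The single published "hours to sepsis diagnosis" range is
#' expanded into two independent normal rows (the true-positive lead time and
#' the false-negative delay), each with SE 0.5 h. Hazard-ratio rows for the
#' under-60 and over-70 age bands are carried in the list but are inert at
#' the base-case age of 60, which uses the 60-70 band.
#'
#' @return A data.frame with columns `name`, `family`, `mean`, `se`.
#' @export
default_psa_specs <- function() {
  s <- function(name, family, mean, se) {
    data.frame(name = name, family = family, mean = mean, se = se,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("incidence", "beta", 0.141, 0.0038),
    s("sensitivity_algorithm", "beta", 0.800, 0.0183),
    s("specificity_algorithm", "beta", 0.851, 0.0068),
    s("sensitivity_comparator", "beta", 0.792, 0.0181),
    s("specificity_comparator", "beta", 0.785, 0.0063),
    s("t_tp_algorithm", "normal", -3, 0.5),
    s("t_fn", "normal", 3, 0.5),
    s("t_antibiotic_from_detection", "normal", 0, 0.5),
    s("shock_probability_early", "beta", 0.40, 0.04),
    s("shock_probability_ref", "beta", 0.566, 0.0091),
    s("rr_mortality_shock", "lognormal", 1.0, 0.255),
    s("rr_mortality_nonshock", "lognormal", 1.0, 0.588),
    s("hr_years_1_5_under60", "lognormal", 17.8, 2.653),
    s("hr_years_6_10_under60", "lognormal", 6.0, 1.301),
    s("hr_years_1_5_60_70", "lognormal", 5.5, 1.250),
    s("hr_years_6_10_60_70", "lognormal", 3.1, 0.791),
    s("hr_years_1_5_over70", "lognormal", 2.4, 0.791),
    s("hr_years_6_10_over70", "lognormal", 1.8, 1.684),
    s("icu_days_shock", "gamma", 7.4, 0.1989),
    s("icu_days_noshock", "gamma", 2.0, 0.1650),
    s("icu_days_true_negative", "gamma", 1.0, 0.0264),
    s("icu_days_false_positive", "gamma", 2.0, 0.0264),
    s("ward_days_shock", "gamma", 17.0, 0.4570),
    s("ward_days_noshock", "gamma", 5.7, 0.4703),
    s("ward_days_true_negative", "gamma", 5.7, 0.1505),
    s("ward_days_false_positive", "gamma", 5.7, 0.1505),
    s("postdischarge_mortality_shock", "beta", 0.175, 0.0175),
    s("readmission_rate", "beta", 0.206, 0.0042),
    s("utility_decrement_years_1_5", "normal", -0.164, 0.0395),
    s("utility_decrement_years_6_10", "normal", -0.124, 0.0394),
    s("utility_decrement_years_11_plus", "normal", 0, 0),
    s("freq_impaired_kidney_function", "beta", 0.141, 0.0044),
    s("freq_amputation", "beta", 0.085, 0.0035),
    s("freq_depression", "beta", 0.028, 0.0021),
    s("freq_ptsd", "beta", 0.099, 0.0038)
  )
}

# required scalar numeric leaves, as dotted paths (used by load/validate)
config_required_paths <- function() {
  c("cohort.incidence", "cohort.mean_age", "cohort.n_icu_admissions_total",
    "cohort.n_icu_admissions_no_sepsis",
    "algorithm_test.sensitivity", "algorithm_test.specificity",
    "comparator_test.sensitivity", "comparator_test.specificity",
    "timing.t_tp_algorithm", "timing.t_tp_comparator", "timing.t_fn",
    "timing.t_antibiotic_from_detection",
    "shock_risk.p_ref", "shock_risk.p_early", "shock_risk.t_early",
    "shock_risk.time_dependent",
    "mortality.model", "mortality.a", "mortality.b", "mortality.c",
    "mortality.rr_shock_multiplier", "mortality.rr_noshock_multiplier",
    "los.icu_shock", "los.icu_noshock", "los.icu_true_negative",
    "los.icu_false_positive", "los.ward_shock", "los.ward_noshock",
    "los.ward_true_negative", "los.ward_false_positive",
    "costs.icu_day", "costs.ward_day", "costs.readmission_event",
    "costs.prediction_cost_per_patient", "costs.prediction_price_per_icu_day",
    "costs.longterm_cost_per_survivor",
    "postdischarge.readmission_rate_year1",
    "postdischarge.postdischarge_mortality_year1_shock",
    "longterm.rr_years_1_5", "longterm.rr_years_6_10",
    "longterm.rr_years_11_plus", "longterm.baseline_utility",
    "longterm.discount_rate", "longterm.time_horizon_years",
    "life_table.A", "life_table.B", "life_table.max_age")
}

#' Get / set a configuration value by dotted path
#'
#' @param config a `septicost_config`
#' @param path dotted path such as `"cohort.incidence"`
#' @param value replacement value (for `config_set`)
#' @return `config_get` returns the value (or NULL if absent); `config_set`
#'   returns the modified config and errors on unknown paths.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) return(NULL)
    node <- node[[k]]
  }
  node
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  if (is.null(config_get(config, path))) {
    stop("unknown configuration path: ", path, call. = FALSE)
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config[[keys]] <- value
  config
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations as a character vector (empty when the configuration is valid);
#' nothing is raised.
#'
#' @param config a `septicost_config`
#' @return character vector of violation messages, each naming the offending
#'   field and the rule it breaks.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v

  num <- function(path) {
    x <- config_get(config, path)
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) NA_real_ else x
  }
  for (p in config_required_paths()) {
    if (is.null(config_get(config, p))) v <- c(v, paste0(p, ": missing field"))
  }
  if (length(v) > 0) return(v)  # field-level checks need the fields

  inc <- num("cohort.incidence")
  v <- add(!(inc > 0 && inc < 1), "cohort.incidence: must be in (0,1)")
  v <- add(num("cohort.n_icu_admissions_no_sepsis") >
             num("cohort.n_icu_admissions_total"),
           "cohort.n_icu_admissions_no_sepsis: exceeds n_icu_admissions_total")
  v <- add(num("cohort.n_icu_admissions_total") <= 0,
           "cohort.n_icu_admissions_total: must be positive")

  for (arm in c("algorithm_test", "comparator_test")) {
    for (f in c("sensitivity", "specificity")) {
      x <- num(paste0(arm, ".", f))
      v <- add(!(x > 0 && x <= 1), paste0(arm, ".", f, ": must be in (0,1]"))
    }
  }

  v <- add(num("timing.t_fn") < 0, "timing.t_fn: must be >= 0")
  v <- add(num("timing.t_tp_algorithm") > num("timing.t_fn"),
           "timing.t_tp_algorithm: must be <= t_fn")

  sr <- config$shock_risk
  v <- add(!(sr$p_early >= 0 && sr$p_early <= sr$p_ref && sr$p_ref <= 1),
           "shock_risk: requires 0 <= p_early <= p_ref <= 1")
  v <- add(sr$t_early >= 0, "shock_risk.t_early: must be negative")

  m <- config$mortality
  v <- add(!(m$a > 0 && m$a < 1), "mortality.a: must be in (0,1)")
  v <- add(m$b < 0, "mortality.b: must be >= 0")
  v <- add(m$c < 0, "mortality.c: must be >= 0")
  v <- add(!m$model %in% c("exponential_linear", "kumar", "lengquist"),
           "mortality.model: unknown model")

  los <- config$los
  for (f in names(los)) {
    v <- add(los[[f]] < 0, paste0("los.", f, ": must be >= 0"))
  }
  v <- add(los$icu_shock < los$icu_noshock,
           "los.icu_shock: must be >= los.icu_noshock")

  for (f in names(config$costs)) {
    v <- add(num(paste0("costs.", f)) < 0, paste0("costs.", f, ": must be >= 0"))
  }

  pd <- config$postdischarge
  v <- add(!(pd$readmission_rate_year1 >= 0 && pd$readmission_rate_year1 <= 1),
           "postdischarge.readmission_rate_year1: must be in [0,1]")
  v <- add(!(pd$postdischarge_mortality_year1_shock >= 0 &&
               pd$postdischarge_mortality_year1_shock <= 1),
           "postdischarge.postdischarge_mortality_year1_shock: must be in [0,1]")
  v <- add(!pd$readmission_population %in% c("all_survivors", "sepsis_survivors"),
           "postdischarge.readmission_population: unknown option")

  lt <- config$longterm
  for (f in c("rr_years_1_5", "rr_years_6_10", "rr_years_11_plus")) {
    v <- add(lt[[f]] < 1, paste0("longterm.", f, ": relative risk must be >= 1"))
  }
  v <- add(lt$discount_rate < 0, "longterm.discount_rate: must be >= 0")
  for (f in names(lt$consequence_frequencies)) {
    x <- lt$consequence_frequencies[[f]]
    v <- add(!(x >= 0 && x <= 1),
             paste0("longterm.consequence_frequencies.", f, ": must be in [0,1]"))
  }

  ltb <- config$life_table
  v <- add(!(ltb$A > 0 && ltb$B > 0), "life_table: A and B must be positive")
  v <- add(num("cohort.mean_age") >= ltb$max_age,
           "cohort.mean_age: must be below life_table.max_age")

  specs <- config$psa_specs
  if (!is.null(specs)) {
    for (i in seq_len(nrow(specs))) {
      r <- specs[i, ]
      if (!r$family %in% c("beta", "gamma", "lognormal", "normal")) {
        v <- c(v, paste0("psa_specs.", r$name, ": unknown family '", r$family, "'"))
        next
      }
      v <- add(r$se < 0, paste0("psa_specs.", r$name, ": se must be >= 0"))
      if (r$family == "beta") {
        ok <- r$mean > 0 && r$mean < 1 && r$se^2 < r$mean * (1 - r$mean)
        v <- add(!ok, paste0("psa_specs.", r$name,
                             ": beta moment condition se^2 < mean(1-mean) violated"))
      }
      if (r$family %in% c("gamma", "lognormal")) {
        v <- add(r$mean <= 0,
                 paste0("psa_specs.", r$name, ": mean must be > 0 for ", r$family))
      }
    }
  }
  v
}

#' Save / load a model configuration (YAML)
#'
#' `save_config` writes the configuration as YAML at full numeric precision;
#' `load_config` reads YAML (JSON, being a YAML subset, is accepted) and
#' reconstructs the configuration. The round trip is lossless: every numeric
#' field survives save-then-load exactly (to the last representable digit).
#' Missing required fields raise an error naming the dotted path; unknown
#' top-level keys are ignored with a warning.
#'
#' @param config a `septicost_config`
#' @param path file path
#' @return `load_config` returns a `septicost_config`; `save_config` returns
#'   `path` invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$psa_specs <- lapply(seq_len(nrow(config$psa_specs)), function(i) {
    as.list(config$psa_specs[i, ])
  })
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed configuration file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  template <- default_base_case()
  known <- names(template)
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    warning("ignoring unknown configuration key(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    x <- x[intersect(names(x), known)]
  }
  if (!is.null(x$psa_specs)) {
    x$psa_specs <- do.call(rbind, lapply(x$psa_specs, function(r) {
      data.frame(name = r$name, family = r$family, mean = r$mean, se = r$se,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(x$wtp_thresholds)) x$wtp_thresholds <- as.numeric(x$wtp_thresholds)
  class(x) <- "septicost_config"
  for (p in config_required_paths()) {
    if (is.null(config_get(x, p))) {
      stop("configuration file '", path, "' is missing required field: ", p,
           call. = FALSE)
    }
  }
  x
}

#' Apply named overrides to a configuration
#'
#' Overrides are given as a named list mapping dotted configuration paths to
#' either a replacement value or a one-element list `list(multiply = f)`
#' which scales the current value by `f`. Unknown paths raise an error naming
#' the path.
#'
#' @param config a `septicost_config`
#' @param overrides named list of path -> value or path -> list(multiply = f)
#' @return the modified configuration
#' @export
apply_overrides <- function(config, overrides) {
  for (path in names(overrides)) {
    val <- overrides[[path]]
    if (is.list(val) && !is.null(val$multiply)) {
      cur <- config_get(config, path)
      if (is.null(cur)) stop("unknown configuration path: ", path, call. = FALSE)
      val <- cur * val$multiply
    }
    config <- config_set(config, path, val)
  }
  config
}

#' @export
print.septicost_config <- function(x, ...) {
  cat("<septicost_config>\n")
  cat(sprintf("  cohort: incidence %.1f%%, mean age %d, national cohort %d\n",
              100 * x$cohort$incidence, x$cohort$mean_age,
              x$cohort$n_icu_admissions_no_sepsis))
  cat(sprintf("  algorithm sens/spec: %.1f%%/%.1f%%  comparator: %.1f%%/%.1f%%\n",
              100 * x$algorithm_test$sensitivity, 100 * x$algorithm_test$specificity,
              100 * x$comparator_test$sensitivity, 100 * x$comparator_test$specificity))
  cat(sprintf("  detection lead: %+g h (TP), %+g h (FN); mortality model: %s\n",
              x$timing$t_tp_algorithm, x$timing$t_fn, x$mortality$model))
  cat(sprintf("  PSA: %d parameter distributions; WTP thresholds: %s EUR/QALY\n",
              nrow(x$psa_specs), paste(x$wtp_thresholds, collapse = ", ")))
  invisible(x)
}
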