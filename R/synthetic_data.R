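#' Generate a synthetic Gompertz life table
#'
#' Annual death probabilities `q(x) = min(1, A * exp(B * x))` on an integer
#' age grid, forced to 1 at the maximum age. The default parameters produce
#' a plausible high-income-country table (remaining life expectancy at 60 of
#' roughly two decades); it is explicitly synthetic, not an official
#' national table.
#'
#' @param spec list with `A` (baseline hazard scale), `B` (aging rate,
#'   1/year) and `max_age`
#' @return data.frame with columns `age` (0..max_age) and `qx`
#' @examples
#' lt <- generate_life_table(list(A = 5e-5, B = 0.095, max_age = 105))
#' tail(lt)
#' @export
generate_life_table <- function(spec = list(A = 5e-5, B = 0.095, max_age = 105)) {
  stopifnot(spec$A > 0, spec$B > 0, spec$max_age > 0)
  age <- 0:spec$max_age
  qx <- pmin(1, spec$A * exp(spec$B * age))
  qx[length(qx)] <- 1
  data.frame(age = age, qx = qx)
}

#' Read / write a life table as CSV (columns age, qx)
#'
#' @param path file path
#' @param life_table data.frame with columns `age`, `qx`
#' @return `read_life_table` returns the table; `write_life_table` returns
#'   `path` invisibly.
#' @export
read_life_table <- function(path) {
  tab <- utils::read.csv(path)
  missing <- setdiff(c("age", "qx"), names(tab))
  if (length(missing) > 0) {
    stop("life table CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_life_table
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}

#' Generate grouped delay-vs-mortality data from a known curve
#'
#' Emulates the grouped literature data behind the two-step mortality-curve
#' estimation: for each treatment-delay interval, death counts are drawn
#' binomially with success probability equal to the generating curve
#' evaluated at the interval midpoint. Deterministic for a fixed seed.
#'
#' @param curves mortality-curve parameters (as in [mortality_shock()])
#' @param intervals data.frame with columns `interval_start`, `interval_end`
#'   (hours)
#' @param n_per_interval patients per interval
#' @param seed RNG seed
#' @param which `"shock"` (exponential curve) or `"nonshock"` (linear curve)
#' @return list with `intervals` (including `n_patients`, `n_deaths`),
#'   `grid` (the midpoints), and `generating_probability` per interval
#' @export
generate_grouped_mortality <- function(curves, intervals, n_per_interval, seed,
                                       which = c("shock", "nonshock")) {
  which <- match.arg(which)
  stopifnot(n_per_interval > 0)
  mid <- (intervals$interval_start + intervals$interval_end) / 2
  p <- if (which == "shock") mortality_shock(curves, mid) else
    mortality_nonshock(curves, mid)
  set.seed(seed)
  deaths <- stats::rbinom(length(p), n_per_interval, p)
  iv <- data.frame(interval_start = intervals$interval_start,
                   interval_end = intervals$interval_end,
                   n_patients = n_per_interval,
                   n_deaths = deaths)
  list(intervals = iv, grid = mid, generating_probability = p)
}

#' Microsimulation of the decision tree (Monte-Carlo oracle)
#'
#' Routes `n` individual patients through one arm of the decision tree with
#' Bernoulli draws at every branch: sepsis by incidence, detection by the
#' arm's sensitivity/specificity, septic shock and in-hospital death by the
#' time-dependent risk functions at the leaf's time to treatment,
#' readmission among hospital survivors, and first-year post-discharge
#' death among shock survivors. Lengths of stay and costs are assigned per
#' leaf and shock status (deterministic means by default; `gamma_los = TRUE`
#' draws gamma-distributed stays with the configured PSA standard errors).
#' Empirical means converge to the analytic arm expectations as n grows,
#' which is the module's purpose: an independent check of the cohort
#' algebra.
#'
#' @param config a `septicost_config`
#' @param arm `"algorithm"` or `"comparator"`
#' @param n number of simulated patients
#' @param seed RNG seed
#' @param gamma_los draw gamma-distributed lengths of stay instead of means
#' @param keep_patients return the per-patient data.frame (heavy for large n)
#' @return list of class `septicost_microsim` with `n`, `seed`, `means`
#'   (named vector over the arm outcome fields), `se` (Monte-Carlo standard
#'   errors), and optionally `patients`
#' @export
simulate_cohort <- function(config, arm, n, seed, gamma_los = FALSE,
                            keep_patients = (n <= 100000)) {
  stopifnot(n >= 1)
  set.seed(seed)
  test <- arm_test(config, arm)
  tt <- arm_times(config, arm)
  los <- config$los
  costs <- config$costs
  pd <- config$postdischarge

  sepsis <- stats::rbinom(n, 1, config$cohort$incidence) == 1
  flagged <- logical(n)  # detected positive by the screening method
  flagged[sepsis] <- stats::rbinom(sum(sepsis), 1, test$sensitivity) == 1
  flagged[!sepsis] <- stats::rbinom(sum(!sepsis), 1, 1 - test$specificity) == 1

  leaf <- character(n)
  leaf[sepsis & flagged] <- "tp"
  leaf[sepsis & !flagged] <- "fn"
  leaf[!sepsis & !flagged] <- "tn"
  leaf[!sepsis & flagged] <- "fp"

  t_leaf <- ifelse(leaf == "tp", tt$t_tp, tt$t_fn)
  shock <- logical(n)
  is_sepsis <- leaf %in% c("tp", "fn")
  shock[is_sepsis] <- stats::rbinom(sum(is_sepsis), 1,
    shock_probability(config$shock_risk, t_leaf[is_sepsis])) == 1

  death <- logical(n)
  p_death <- numeric(n)
  p_death[is_sepsis & shock] <-
    mortality_shock(config$mortality, t_leaf[is_sepsis & shock])
  p_death[is_sepsis & !shock] <-
    mortality_nonshock(config$mortality, t_leaf[is_sepsis & !shock])
  death[is_sepsis] <- stats::rbinom(sum(is_sepsis), 1, p_death[is_sepsis]) == 1

  pick <- function(table_shock, table_noshock, table_tn, table_fp) {
    ifelse(is_sepsis, ifelse(shock, table_shock, table_noshock),
           ifelse(leaf == "tn", table_tn, table_fp))
  }
  icu_days <- pick(los$icu_shock, los$icu_noshock,
                   los$icu_true_negative, los$icu_false_positive)
  ward_days <- pick(los$ward_shock, los$ward_noshock,
                    los$ward_true_negative, los$ward_false_positive)
  if (gamma_los) {
    specs <- config$psa_specs
    se_of <- function(nm) specs$se[match(nm, specs$name)]
    gdraw <- function(mean, se, m) {
      if (m == 0) return(numeric(0))
      par <- gamma_from_moments(mean, se)
      stats::rgamma(m, shape = par$shape, scale = par$scale)
    }
    groups <- list(
      list(sel = is_sepsis & shock, icu = "icu_days_shock", ward = "ward_days_shock",
           micu = los$icu_shock, mward = los$ward_shock),
      list(sel = is_sepsis & !shock, icu = "icu_days_noshock", ward = "ward_days_noshock",
           micu = los$icu_noshock, mward = los$ward_noshock),
      list(sel = leaf == "tn", icu = "icu_days_true_negative",
           ward = "ward_days_true_negative",
           micu = los$icu_true_negative, mward = los$ward_true_negative),
      list(sel = leaf == "fp", icu = "icu_days_false_positive",
           ward = "ward_days_false_positive",
           micu = los$icu_false_positive, mward = los$ward_false_positive))
    for (g in groups) {
      m <- sum(g$sel)
      icu_days[g$sel] <- gdraw(g$micu, se_of(g$icu), m)
      ward_days[g$sel] <- gdraw(g$mward, se_of(g$ward), m)
    }
  }

  survivor <- !death
  readmitted <- logical(n)
  readmitted[survivor] <- stats::rbinom(sum(survivor), 1,
                                        pd$readmission_rate_year1) == 1
  if (identical(pd$readmission_population, "sepsis_survivors")) {
    readmitted[!is_sepsis] <- FALSE
  }

  pd_death <- logical(n)
  at_risk <- is_sepsis & shock & survivor
  pd_death[at_risk] <- stats::rbinom(sum(at_risk), 1,
    pd$postdischarge_mortality_year1_shock) == 1
  survivor_1yr <- is_sepsis & survivor & !pd_death

  lump <- effective_longterm_lump(config)
  cost <- (if (arm == "algorithm") costs$prediction_cost_per_patient else 0) +
    icu_days * costs$icu_day + ward_days * costs$ward_day +
    readmitted * costs$readmission_event + survivor_1yr * lump

  vals <- cbind(expected_icu_days = icu_days,
                expected_ward_days = ward_days,
                in_hospital_mortality = as.numeric(death),
                readmission_proportion = as.numeric(readmitted),
                sepsis_survivor_1yr = as.numeric(survivor_1yr),
                cost_total = cost)
  means <- colMeans(vals)
  se <- apply(vals, 2, stats::sd) / sqrt(n)

  out <- list(n = n, seed = seed, arm = arm, means = means, se = se)
  if (keep_patients) {
    out$patients <- data.frame(leaf = leaf, shock = shock, death = death,
                               icu_days = icu_days, ward_days = ward_days,
                               readmitted = readmitted,
                               survivor_1yr = survivor_1yr, cost = cost)
  }
  class(out) <- "septicost_microsim"
  out
}
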