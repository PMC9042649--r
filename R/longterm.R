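#' Project annual survival from a life table with band-wise relative risks
#'
#' Starting from `start_age`, applies the annual death probability
#' `q(age + k - 1) * rr(k)` in model year k, with the relative risk taken
#' from the band map (`rr_years_1_5` for years 1-5, `rr_years_6_10` for
#' years 6-10, `rr_years_11_plus` thereafter). Adjusted probabilities are
#' clamped at 1, so survival is non-increasing and reaches 0 at the end of
#' the table.
#'
#' @param life_table data.frame with columns `age` and `qx` (see
#'   [generate_life_table()])
#' @param start_age age at model entry (years; must lie inside the table)
#' @param rr_bands list with `rr_years_1_5`, `rr_years_6_10`,
#'   `rr_years_11_plus` (use 1,1,1 for the general population)
#' @param discount_rate annual discount rate (for the returned discount
#'   factors)
#' @return data.frame with columns `year` (1..K), `q_adjusted`, `survival`
#'   (probability of being alive at the end of the year), and `discount`
#'   (`(1+r)^-year`).
#' @export
project_survival <- function(life_table, start_age,
                             rr_bands = list(rr_years_1_5 = 1,
                                             rr_years_6_10 = 1,
                                             rr_years_11_plus = 1),
                             discount_rate = 0) {
  if (start_age < min(life_table$age) || start_age >= max(life_table$age)) {
    stop("start_age ", start_age, " outside life table range", call. = FALSE)
  }
  ages <- seq(start_age, max(life_table$age) - 1)
  qx <- life_table$qx[match(ages, life_table$age)]
  k <- seq_along(ages)
  rr <- ifelse(k <= 5, rr_bands$rr_years_1_5,
               ifelse(k <= 10, rr_bands$rr_years_6_10, rr_bands$rr_years_11_plus))
  q_adj <- pmin(1, qx * rr)
  data.frame(year = k,
             q_adjusted = q_adj,
             survival = cumprod(1 - q_adj),
             discount = (1 + discount_rate)^(-k))
}

band_value <- function(year, y1_5, y6_10, y11p) {
  ifelse(year <= 5, y1_5, ifelse(year <= 10, y6_10, y11p))
}

#' Discounted quality-adjusted life-years over a survival projection
#'
#' Sums `survival(k) * utility(k) * (1+r)^-k` over the projection years,
#' where the utility in year k is the baseline utility plus the band-wise
#' decrement (clamped below at 0, with a warning if clamping occurs).
#' Patients who die in hospital accrue 0 QALYs. The optional
#' `first_year_mortality` replaces the year-1 adjusted death probability
#' (used for the post-discharge mortality of septic-shock survivors).
#'
#' @param projection output of [project_survival()]
#' @param utility_params list with `baseline_utility` and the three
#'   `utility_decrement_*` fields (decrements 0 for non-sepsis patients)
#' @param in_hospital_death if TRUE the patient accrues no QALYs
#' @param first_year_mortality optional probability overriding year-1
#'   mortality in the projection
#' @param horizon_years truncate the sum after this many years (default
#'   lifetime)
#' @return discounted QALYs (scalar)
#' @export
discounted_qalys <- function(projection, utility_params,
                             in_hospital_death = FALSE,
                             first_year_mortality = NULL,
                             horizon_years = Inf) {
  if (isTRUE(in_hospital_death)) return(0)
  S <- projection$survival
  if (!is.null(first_year_mortality)) {
    q <- projection$q_adjusted
    q[1] <- first_year_mortality
    S <- cumprod(1 - q)
  }
  u <- utility_params$baseline_utility +
    band_value(projection$year,
               utility_params$utility_decrement_years_1_5,
               utility_params$utility_decrement_years_6_10,
               utility_params$utility_decrement_years_11_plus)
  if (any(u < 0)) {
    warning("utility below 0 after decrement; clamped to 0", call. = FALSE)
    u <- pmax(0, u)
  }
  keep <- projection$year <= horizon_years
  sum(S[keep] * u[keep] * projection$discount[keep])
}

#' Long-term consequence cost per patient
#'
#' The expected long-term-consequence cost is the probability of being a
#' sepsis patient alive one year after discharge times the discounted
#' lifetime consequence cost per such survivor (a calibrated lump).
#'
#' @param sepsis_survivor_1yr probability of being a 1-year sepsis survivor
#' @param cost_per_survivor discounted lifetime consequence cost per 1-year
#'   survivor (EUR)
#' @return expected cost per ICU patient (EUR)
#' @export
longterm_consequence_cost <- function(sepsis_survivor_1yr, cost_per_survivor) {
  stopifnot(sepsis_survivor_1yr >= 0, cost_per_survivor >= 0)
  sepsis_survivor_1yr * cost_per_survivor
}

# Discounted annuity of the consequence-cost stream for a 1-year sepsis
# survivor: an annual stream from model year 2 onward (consequences apply
# after the first year), weighted by RR-adjusted survival conditioned on
# having survived year 1, discounted at `rate`, truncated at the horizon.
consequence_annuity <- function(life_table, start_age, rr_bands, rate,
                                horizon_years = Inf) {
  proj <- project_survival(life_table, start_age, rr_bands, rate)
  if (nrow(proj) < 2 || horizon_years < 2) return(0)
  cond <- cumprod(1 - proj$q_adjusted[-1])  # survival from year 2, given alive at 1
  yrs <- proj$year[-1]
  keep <- yrs <= horizon_years
  sum(cond[keep] * (1 + rate)^(-yrs[keep]))
}

# Effective consequence lump under the config's discount rate, RR bands and
# horizon. The shipped per-survivor lump is calibrated at the reference
# conditions (3% discount, RR 5.5/3.1/1.0, lifetime horizon); under other
# conditions it is rescaled by the ratio of consequence annuities so that,
# e.g., a 0% discount rate or general-population survival raises the
# lifetime consequence cost.
effective_longterm_lump <- function(config) {
  lt <- config$longterm
  if (!isTRUE(lt$include_longterm_consequences)) return(0)
  tab <- generate_life_table(config$life_table)
  ref <- consequence_annuity(tab, config$cohort$mean_age,
                             list(rr_years_1_5 = 5.5, rr_years_6_10 = 3.1,
                                  rr_years_11_plus = 1.0),
                             rate = 0.03, horizon_years = Inf)
  cur <- consequence_annuity(tab, config$cohort$mean_age,
                             list(rr_years_1_5 = lt$rr_years_1_5,
                                  rr_years_6_10 = lt$rr_years_6_10,
                                  rr_years_11_plus = lt$rr_years_11_plus),
                             rate = lt$discount_rate,
                             horizon_years = lt$time_horizon_years)
  config$costs$longterm_cost_per_survivor * cur / ref
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost incremental cost (EUR, algorithm minus comparator)
#' @param delta_qaly incremental QALYs
#' @return list with `classification` (`"dominant"`, `"dominated"`,
#'   `"tradeoff"`, or `"undefined"` when delta_qaly = 0) and `ratio`
#'   (EUR/QALY, NA unless both differences share a sign)
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(classification = "undefined", ratio = NA_real_))
  }
  if (delta_cost <= 0 && delta_qaly > 0) {
    return(list(classification = "dominant", ratio = NA_real_))
  }
  if (delta_cost >= 0 && delta_qaly < 0) {
    return(list(classification = "dominated", ratio = NA_real_))
  }
  list(classification = "tradeoff", ratio = delta_cost / delta_qaly)
}

# Expected discounted QALYs for one arm: mixture over tree leaves.
# Utilities: sepsis patients carry the band-wise decrements; non-sepsis
# patients the baseline utility. Year-1 mortality: shock survivors face the
# post-discharge mortality (replacing the RR-adjusted hazard); non-shock
# sepsis survivors the RR-adjusted hazard; non-sepsis patients the plain
# life-table hazard.
arm_qalys <- function(config, leaves, t_tp, t_fn) {
  lt <- config$longterm
  tab <- generate_life_table(config$life_table)
  age <- config$cohort$mean_age
  r <- lt$discount_rate
  H <- lt$time_horizon_years

  proj_sepsis <- project_survival(tab, age,
                                  list(rr_years_1_5 = lt$rr_years_1_5,
                                       rr_years_6_10 = lt$rr_years_6_10,
                                       rr_years_11_plus = lt$rr_years_11_plus),
                                  r)
  proj_gen <- project_survival(tab, age, discount_rate = r)

  u_sepsis <- list(baseline_utility = lt$baseline_utility,
                   utility_decrement_years_1_5 = lt$utility_decrement_years_1_5,
                   utility_decrement_years_6_10 = lt$utility_decrement_years_6_10,
                   utility_decrement_years_11_plus = lt$utility_decrement_years_11_plus)
  u_gen <- list(baseline_utility = lt$baseline_utility,
                utility_decrement_years_1_5 = 0, utility_decrement_years_6_10 = 0,
                utility_decrement_years_11_plus = 0)

  q_shock_survivor <- discounted_qalys(
    proj_sepsis, u_sepsis,
    first_year_mortality = config$postdischarge$postdischarge_mortality_year1_shock,
    horizon_years = H)
  q_nonshock_survivor <- discounted_qalys(proj_sepsis, u_sepsis, horizon_years = H)
  q_nosepsis <- discounted_qalys(proj_gen, u_gen, horizon_years = H)

  leaf_q <- function(t) {
    p_shock <- shock_probability(config$shock_risk, t)
    ms <- mortality_shock(config$mortality, t)
    mn <- mortality_nonshock(config$mortality, t)
    p_shock * (1 - ms) * q_shock_survivor +
      (1 - p_shock) * (1 - mn) * q_nonshock_survivor
  }
  leaves$tp * leaf_q(t_tp) + leaves$fn * leaf_q(t_fn) +
    (leaves$tn + leaves$fp) * q_nosepsis
}
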