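- name: Incidence 30%
  overrides:
    cohort.incidence: 0.3
- name: Incidence 20%
  overrides:
    cohort.incidence: 0.2
- name: Incidence 10%
  overrides:
    cohort.incidence: 0.1
- name: Comparator SOFA (sens 80.0%, spec 48.0%)
  overrides:
    comparator_test.sensitivity: 0.8
    comparator_test.specificity: 0.48
- name: Comparator NEWS2 (sens 84.0%, spec 37.0%)
  overrides:
    comparator_test.sensitivity: 0.84
    comparator_test.specificity: 0.37
- name: Algorithm specificity 78.5% (Sepsis-3)
  overrides:
    algorithm_test.specificity: 0.785
- name: Detection 4 hours earlier
  overrides:
    timing.t_tp_algorithm: -4.0
- name: Detection 2 hours earlier
  overrides:
    timing.t_tp_algorithm: -2.0
- name: Detection 1 hour earlier
  overrides:
    timing.t_tp_algorithm: -1.0
- name: Septic shock 30% at earlier detection
  overrides:
    shock_risk.p_early: 0.3
- name: Septic shock 56.6% regardless of detection time
  overrides:
    shock_risk.time_dependent: no
- name: 'Mortality model: Kumar (linear survival decrease)'
  overrides:
    mortality.model: kumar
- name: 'Mortality model: Lengquist (constant 33%/22%)'
  overrides:
    mortality.model: lengquist
- name: Length of stay ICU and ward +25%
  overrides:
    los.icu_shock:
      multiply: 1.25
    los.icu_noshock:
      multiply: 1.25
    los.icu_true_negative:
      multiply: 1.25
    los.icu_false_positive:
      multiply: 1.25
    los.ward_shock:
      multiply: 1.25
    los.ward_noshock:
      multiply: 1.25
    los.ward_true_negative:
      multiply: 1.25
    los.ward_false_positive:
      multiply: 1.25
- name: Length of stay ICU and ward -25%
  overrides:
    los.icu_shock:
      multiply: 0.75
    los.icu_noshock:
      multiply: 0.75
    los.icu_true_negative:
      multiply: 0.75
    los.icu_false_positive:
      multiply: 0.75
    los.ward_shock:
      multiply: 0.75
    los.ward_noshock:
      multiply: 0.75
    los.ward_true_negative:
      multiply: 0.75
    los.ward_false_positive:
      multiply: 0.75
- name: Post-discharge shock mortality 0%
  overrides:
    postdischarge.postdischarge_mortality_year1_shock: 0.0
- name: Readmission rate 0%
  overrides:
    postdischarge.readmission_rate_year1: 0.0
- name: Readmission rate 40%
  overrides:
    postdischarge.readmission_rate_year1: 0.4
- name: Unit cost of ICU and ward day +25%
  overrides:
    costs.icu_day:
      multiply: 1.25
    costs.ward_day:
      multiply: 1.25
- name: Unit cost of ICU and ward day -25%
  overrides:
    costs.icu_day:
      multiply: 0.75
    costs.ward_day:
      multiply: 0.75
- name: Unit cost of readmission +25%
  overrides:
    costs.readmission_event:
      multiply: 1.25
- name: Unit cost of readmission -25%
  overrides:
    costs.readmission_event:
      multiply: 0.75
- name: Long-term survival same as general population
  overrides:
    longterm.rr_years_1_5: 1.0
    longterm.rr_years_6_10: 1.0
    longterm.rr_years_11_plus: 1.0
- name: Long-term consequences not included
  overrides:
    longterm.include_longterm_consequences: no
- name: Model time horizon 1 year
  overrides:
    longterm.time_horizon_years: 1.0
- name: Discount rate 0%
  overrides:
    longterm.discount_rate: 0.0
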