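cohort:
  incidence: 0.14099999999999999
  mean_age: 60.0
  n_icu_admissions_total: 45000.0
  n_icu_admissions_no_sepsis: 36900.0
algorithm_test:
  sensitivity: 0.80000000000000004
  specificity: 0.85099999999999998
comparator_test:
  sensitivity: 0.79200000000000004
  specificity: 0.78500000000000003
timing:
  t_tp_algorithm: -3.0
  t_tp_comparator: 0.0
  t_fn: 3.0
  t_antibiotic_from_detection: 0.0
shock_risk:
  p_ref: 0.56599999999999995
  p_early: 0.40000000000000002
  t_early: -3.0
  time_dependent: yes
mortality:
  model: exponential_linear
  a: 0.42809999999999998
  b: 0.0272
  c: 0.0052
  kumar_mortality_at_0: 0.40000000000000002
  kumar_slope_per_hour: 0.076
  lengquist_shock: 0.33000000000000002
  lengquist_nonshock: 0.22
  rr_shock_multiplier: 1.0
  rr_noshock_multiplier: 1.0
los:
  icu_shock: 7.40000000000000036
  icu_noshock: 2.0
  icu_true_negative: 1.0
  icu_false_positive: 2.0
  ward_shock: 17.0
  ward_noshock: 5.70000000000000018
  ward_true_negative: 5.70000000000000018
  ward_false_positive: 5.70000000000000018
costs:
  icu_day: 6355.38429999999971187
  ward_day: 626.26239999999995689
  readmission_event: 4166.0
  prediction_cost_per_patient: 1037.0
  prediction_price_per_icu_day: 90.0
  longterm_cost_per_survivor: 1947.72640000000001237
postdischarge:
  readmission_rate_year1: 0.20599999999999999
  postdischarge_mortality_year1_shock: 0.17499999999999999
  readmission_population: all_survivors
longterm:
  rr_years_1_5: 5.5
  rr_years_6_10: 3.10000000000000009
  rr_years_11_plus: 1.0
  utility_decrement_years_1_5: -0.16400000000000001
  utility_decrement_years_6_10: -0.124
  utility_decrement_years_11_plus: 0.0
  baseline_utility: 0.80000000000000004
  discount_rate: 0.03
  consequence_frequencies:
    impaired_kidney_function: 0.14099999999999999
    amputation: 0.08500000000000001
    depression: 0.028
    ptsd: 0.099
  include_longterm_consequences: yes
  time_horizon_years: .inf
life_table:
  A: 5.00000000000000024e-05
  B: 0.095
  max_age: 105.0
psa_specs:
- name: incidence
  family: beta
  mean: 0.14099999999999999
  se: 0.0038
- name: sensitivity_algorithm
  family: beta
  mean: 0.80000000000000004
  se: 0.0183
- name: specificity_algorithm
  family: beta
  mean: 0.85099999999999998
  se: 0.0068
- name: sensitivity_comparator
  family: beta
  mean: 0.79200000000000004
  se: 0.0181
- name: specificity_comparator
  family: beta
  mean: 0.78500000000000003
  se: 0.0063
- name: t_tp_algorithm
  family: normal
  mean: -3.0
  se: 0.5
- name: t_fn
  family: normal
  mean: 3.0
  se: 0.5
- name: t_antibiotic_from_detection
  family: normal
  mean: 0.0
  se: 0.5
- name: shock_probability_early
  family: beta
  mean: 0.40000000000000002
  se: 0.04
- name: shock_probability_ref
  family: beta
  mean: 0.56599999999999995
  se: 0.0091
- name: rr_mortality_shock
  family: lognormal
  mean: 1.0
  se: 0.255
- name: rr_mortality_nonshock
  family: lognormal
  mean: 1.0
  se: 0.58799999999999997
- name: hr_years_1_5_under60
  family: lognormal
  mean: 17.80000000000000071
  se: 2.65300000000000002
- name: hr_years_6_10_under60
  family: lognormal
  mean: 6.0
  se: 1.30099999999999993
- name: hr_years_1_5_60_70
  family: lognormal
  mean: 5.5
  se: 1.25
- name: hr_years_6_10_60_70
  family: lognormal
  mean: 3.10000000000000009
  se: 0.79100000000000004
- name: hr_years_1_5_over70
  family: lognormal
  mean: 2.39999999999999991
  se: 0.79100000000000004
- name: hr_years_6_10_over70
  family: lognormal
  mean: 1.80000000000000004
  se: 1.68399999999999994
- name: icu_days_shock
  family: gamma
  mean: 7.40000000000000036
  se: 0.19889999999999999
- name: icu_days_noshock
  family: gamma
  mean: 2.0
  se: 0.16500000000000001
- name: icu_days_true_negative
  family: gamma
  mean: 1.0
  se: 0.0264
- name: icu_days_false_positive
  family: gamma
  mean: 2.0
  se: 0.0264
- name: ward_days_shock
  family: gamma
  mean: 17.0
  se: 0.45700000000000002
- name: ward_days_noshock
  family: gamma
  mean: 5.70000000000000018
  se: 0.4703
- name: ward_days_true_negative
  family: gamma
  mean: 5.70000000000000018
  se: 0.15049999999999999
- name: ward_days_false_positive
  family: gamma
  mean: 5.70000000000000018
  se: 0.15049999999999999
- name: postdischarge_mortality_shock
  family: beta
  mean: 0.17499999999999999
  se: 0.0175
- name: readmission_rate
  family: beta
  mean: 0.20599999999999999
  se: 0.0042
- name: utility_decrement_years_1_5
  family: normal
  mean: -0.16400000000000001
  se: 0.0395
- name: utility_decrement_years_6_10
  family: normal
  mean: -0.124
  se: 0.0394
- name: utility_decrement_years_11_plus
  family: normal
  mean: 0.0
  se: 0.0
- name: freq_impaired_kidney_function
  family: beta
  mean: 0.14099999999999999
  se: 0.0044
- name: freq_amputation
  family: beta
  mean: 0.08500000000000001
  se: 0.0035
- name: freq_depression
  family: beta
  mean: 0.028
  se: 0.0021
- name: freq_ptsd
  family: beta
  mean: 0.099
  se: 0.0038
wtp_thresholds:
- 20000.0
- 50000.0
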