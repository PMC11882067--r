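population:
  total_population: 10718565.0
  frac_age_50_74: 0.25869999999999999
  male_fraction: 0.48699999999999999
  smoking_rate: 0.24990000000000001
  uptake_rate: 0.29999999999999999
  lc_incidence_50_74: 0.0064
  mean_start_age: 58.0
  max_screening_age: 74.0
  clinical_stage_distribution:
    stage_I: 0.09590959095909592
    stage_II: 0.09590959095909592
    stage_III: 0.28142814281428141
    stage_IV: 0.52675267526752678
scan_round1:
  round_label: round1
  p_regular:
    negative: 0.79210000000000003
    indeterminate: 0.192
    positive: 0.0159
  p_indeterminate:
    negative: 0.94569999999999999
    positive: 0.0543
  p_negative_truth:
    true_negative: 0.99929999999999997
    false_negative: 0.0007
  p_positive_truth:
    true_positive: 0.38669999999999999
    false_positive: 0.61329999999999996
  screen_stage_distribution:
    stage_I: 0.64859999999999995
    stage_II: 0.0946
    stage_III: 0.18920000000000001
    stage_IV: 0.06759999999999999
  interval_years: 1.0
scan_round2:
  round_label: round2
  p_regular:
    negative: 0.92169999999999996
    indeterminate: 0.0658
    positive: 0.0125
  p_indeterminate:
    negative: 0.9123
    positive: 0.0877
  p_negative_truth:
    true_negative: 0.99729999999999996
    false_negative: 0.0027
  p_positive_truth:
    true_positive: 0.44350000000000001
    false_positive: 0.55649999999999999
  screen_stage_distribution:
    stage_I: 0.75860000000000005
    stage_II: 0.06900000000000001
    stage_III: 0.13789999999999999
    stage_IV: 0.0345
  interval_years: 2.5
subsequent_rounds_use: round2
utilities:
  pre_progression_by_stage:
    stage_I: 0.70999999999999996
    stage_II: 0.68000000000000005
    stage_III: 0.67000000000000004
    stage_IV: 0.66000000000000003
  post_progression_by_stage:
    stage_I: 0.67000000000000004
    stage_II: 0.67000000000000004
    stage_III: 0.66000000000000003
    stage_IV: 0.66000000000000003
  population_norm_by_age_band:
    50-59: 0.77000000000000002
    60-69: 0.67000000000000004
    70-79: 0.56999999999999995
    80+: 0.52000000000000002
  recovery_years: 5.0
  post_progression_disutility_stage4: 0.0
costs:
  sms_cost: 0.20000000000000001
  phone_cost: 4.0
  ct_total: 91.0
  ct_scan_only: 71.0
  ct_reading: 20.0
  diag_screen: 651.0
  diag_clinical: 774.0
  first_line_per_cycle_by_stage:
    stage_I: 2458.0
    stage_II: 2329.0
    stage_III: 7920.0
    stage_IV: 8959.0
  aftercare_preprog_first2y: 100.0
  aftercare_preprog_after2y: 77.0
  aftercare_years: 5.0
  second_line_by_stage:
    stage_I: 4448.0
    stage_II: 4448.0
    stage_III: 6812.0
    stage_IV: 8198.0
  aftercare_postprog_per_cycle: 423.0
  end_of_life_by_stage:
    stage_I: 2159.0
    stage_II: 2159.0
    stage_III: 1033.0
    stage_IV: 1014.0
economics:
  discount_rate_costs: 0.035
  discount_rate_effects: 0.035
  wtp: 20000.0
  horizon_years: 42.0
  cycle_months: 3.0
  n_rounds: 17.0
  half_cycle_correction: no
survival_inputs:
  dfs_1y_by_stage:
    stage_I: 0.878
    stage_II: 0.81789999999999996
    stage_III: 0.48920000000000002
    stage_IV: 0.376
  os_5y_by_stage:
    stage_I: 0.7863
    stage_II: 0.54900000000000004
    stage_III: 0.29239999999999999
    stage_IV: 0.0591
  curve_source: packaged
  curve_n_subjects: 2000.0
  pinned_family:
    os_stage_I: exponential
    os_stage_II: exponential
    os_stage_III: exponential
    os_stage_IV: exponential
    dfs_stage_I: exponential
    dfs_stage_II: exponential
    dfs_stage_III: exponential
    dfs_stage_IV: exponential
  missed_survival: stage_II
  missed_recovery: no
life_table:
  q50: 0.0035
  log_slope: 0.08500000000000001
  max_age: 105.0
  mortality_multiplier: 1.0
psa:
  se_fraction: 0.10000000000000001
  dirichlet_concentration: 100.0
rng_seed: 1
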