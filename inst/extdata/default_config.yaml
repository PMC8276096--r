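settings:
  cycle_days: 21.0
  horizon_years: 10.0
  annual_discount_rate: 0.03
  wtp_per_qaly: 100000.0
  body_surface_area: 1.8
  creatinine_clearance: 70.0
  half_cycle_correction: no
survival:
  aep:
    os:
      family: loglogistic
      theta: 0.003072
      kappa: 2.29744
    pfs:
      family: loglogistic
      theta: 0.008895
      kappa: 2.852489
  dep_hr:
    os:
      hr: 1.04
      low: 0.83
      high: 1.25
    pfs:
      hr: 1.01
      low: 0.81
      high: 1.21
  ep:
    os:
      family: weibull
      lambda: 0.016073
      gamma: 1.593409
    pfs:
      family: weibull
      lambda: 0.042826
      gamma: 1.712046
extrapolation:
  cutoff_months: 24.0
  os_mode: parametric_continuation
  pfs_mode: parametric_continuation
  hazard_table_csv: ~
prices:
  atezolizumab: 7.83
  durvalumab: 7.6
  etoposide: 1.51
  carboplatin: 0.06
  topotecan: 12.75
ae_costs:
  aep: 4959.82
  dep: 4743.05
  ep: 6100.94
  topotecan: 14487.33
care_costs:
  admin_first_hour: 142.55
  admin_additional_hour: 30.68
  monthly_physician_visit: 148.33
  three_monthly_imaging: 122.71
  monthly_supportive_care: 637.0
  death_cost: 9433.0
utilities:
  pfs: 0.673
  ps: 0.473
disutilities:
  aep: 0.09
  dep: 0.094
  ep: 0.112
subsequent_therapy:
  aep: 0.517
  dep: 0.42
  ep: 0.516
treatment:
  chemo_cycles: 4.0
  ici_cycles:
    aep: 7.0
    dep: 7.0
  ici_duration_mode: median_cycles
  induction_infusion_hours:
    chemo_immuno: 4.0
    chemo_only: 3.0
  maintenance_infusion_hours: 1.0
  etoposide_mg_per_m2: 100.0
  etoposide_days_per_cycle: 3.0
  carboplatin_auc: 5.0
  ici_dose_mg:
    atezolizumab: 1200.0
    durvalumab: 1500.0
  topotecan_mg_per_m2: 1.5
  topotecan_days_per_cycle: 5.0
  topotecan_max_cycles: 4.0
  topotecan_infusions_per_cycle: 5.0
  disutility_policy: during_first_line
psa:
  n_draws: 10000.0
  seed: 2.0210629e+07
sensitivity:
- name: Atezolizumab price/mg
  path: prices.atezolizumab
  low: 5.87
  high: 9.78
  distribution: gamma
- name: Durvalumab price/mg
  path: prices.durvalumab
  low: 5.7
  high: 9.5
  distribution: gamma
- name: Etoposide price/mg
  path: prices.etoposide
  low: 1.13
  high: 1.89
  distribution: gamma
- name: Carboplatin price/mg
  path: prices.carboplatin
  low: 0.04
  high: 0.07
  distribution: gamma
- name: Topotecan price/mg
  path: prices.topotecan
  low: 9.56
  high: 15.94
  distribution: gamma
- name: AE cost (1st-line AEP)
  path: ae_costs.aep
  low: 3719.87
  high: 6199.78
  distribution: gamma
- name: AE cost (1st-line DEP)
  path: ae_costs.dep
  low: 3557.29
  high: 5928.81
  distribution: gamma
- name: AE cost (1st-line EP)
  path: ae_costs.ep
  low: 4508.96
  high: 7514.93
  distribution: gamma
- name: AE cost (2nd-line topotecan)
  path: ae_costs.topotecan
  low: 10865.5
  high: 18109.16
  distribution: gamma
- name: Administration IV, first hour
  path: care_costs.admin_first_hour
  low: 106.91
  high: 178.19
  distribution: gamma
- name: Administration IV, additional hour
  path: care_costs.admin_additional_hour
  low: 23.01
  high: 38.35
  distribution: gamma
- name: Monthly physician visit
  path: care_costs.monthly_physician_visit
  low: 111.25
  high: 185.41
  distribution: gamma
- name: Three-monthly imaging
  path: care_costs.three_monthly_imaging
  low: 92.03
  high: 153.39
  distribution: gamma
- name: Monthly supportive care
  path: care_costs.monthly_supportive_care
  low: 477.75
  high: 796.25
  distribution: gamma
- name: Death associated costs
  path: care_costs.death_cost
  low: 7074.75
  high: 11791.25
  distribution: gamma
- name: Utility PFS
  path: utilities.pfs
  low: 0.538
  high: 0.808
  distribution: beta
- name: Utility PS
  path: utilities.ps
  low: 0.378
  high: 0.568
  distribution: beta
- name: Disutility AEP
  path: disutilities.aep
  low: 0.072
  high: 0.108
  distribution: beta
- name: Disutility DEP
  path: disutilities.dep
  low: 0.075
  high: 0.113
  distribution: beta
- name: Disutility EP
  path: disutilities.ep
  low: 0.09
  high: 0.134
  distribution: beta
- name: Subsequent therapy AEP
  path: subsequent_therapy.aep
  low: 0.414
  high: 0.62
  distribution: beta
- name: Subsequent therapy DEP
  path: subsequent_therapy.dep
  low: 0.336
  high: 0.504
  distribution: beta
- name: Subsequent therapy EP
  path: subsequent_therapy.ep
  low: 0.413
  high: 0.619
  distribution: beta
- name: Body surface area
  path: settings.body_surface_area
  low: 1.35
  high: 2.25
  distribution: gamma
- name: Creatinine clearance
  path: settings.creatinine_clearance
  low: 52.5
  high: 87.5
  distribution: gamma
- name: OS HR DEP vs AEP
  path: survival.dep_hr.os.hr
  low: 0.83
  high: 1.25
  distribution: lognormal
- name: PFS HR DEP vs AEP
  path: survival.dep_hr.pfs.hr
  low: 0.81
  high: 1.21
  distribution: lognormal
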