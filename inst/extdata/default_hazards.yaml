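# Default hazard-model parameters.
#
# All baseline rates are declared calibration parameters. The defaults were
# tuned once to the soft calibration targets recorded under
# `calibration_targets` and then frozen; they are not estimates from any
# individual-level dataset.
#
# Units: rates are per person-year; exposure in mg-years; ages in years.

exposure_threshold: 5000          # cumulative LDL-C exposure threshold, mg-years
mi_excess_slope: 2.5e-4           # exponential excess-risk slope per mg-year above threshold
ihd_excess_slope: 0.8e-4          # flatter excess-risk slope for IHD (calibrated lower than MI)
excess_cap: 4000                  # saturation of the excess exposure term, mg-years above threshold
frailty_sd_log: 1.3               # log-sd of person-level cardiac frailty on MI/IHD (mean 1)
stroke_rr_per_mmol: 0.84          # relative risk per 1 mmol/L LDL-C decrease (16% reduction)
stroke_ldl_ref: 3.0               # reference LDL-C (mmol/L) at which the stroke baseline applies
stroke_onset_age: 60              # no ischaemic stroke hazard before this age
recurrent_multiplier: 0.3         # MI hazard multiplier after a prior MI/IHD (secondary prevention)
ihd_recurrent_multiplier: 2.0     # IHD hazard multiplier after a prior MI/IHD (chronic coronary disease)
hf_prior_ihd_multiplier: 3.0      # HF hazard multiplier after prior IHD

# proportional multipliers on the MI and IHD hazards per ratio stratum 1..4
# (IHD calibrated lower and flatter than MI)
ratio_multiplier: [1.0, 2.35, 10.0, 240.0]
ihd_ratio_multiplier: [1.0, 1.7, 5.0, 85.0]

mi_baseline:
  female: {rate0: 1.6e-6, slope: 0.075}
  male:   {rate0: 4.7e-6, slope: 0.075}
ihd_baseline:
  female: {rate0: 6.1e-6, slope: 0.070}
  male:   {rate0: 6.1e-6, slope: 0.070}
stroke_baseline:                   # rate at the onset age; slope beyond onset
  female: {rate0: 0.85e-3, slope: 0.085}
  male:   {rate0: 1.28e-3, slope: 0.085}
hf_baseline:
  female: {rate0: 5.4e-6, slope: 0.090}
  male:   {rate0: 4.8e-6, slope: 0.090}
gompertz:                          # other-cause mortality: makeham + scale * exp(shape*age)
  female: {makeham: 2.0e-4, scale: 8.8e-6, shape: 0.105}
  male:   {makeham: 3.0e-4, scale: 1.45e-5, shape: 0.102}

# per-event fatality probability by sex and ratio stratum 1..4, scaled by a
# logistic age ramp (events at young ages are more survivable)
case_fatality_age: {young: 0.45, old: 1.25, midpoint: 72, width: 8.0}
case_fatality:
  mi:
    female: [0.52, 0.53, 0.53, 0.62]
    male:   [0.49, 0.52, 0.54, 0.64]
  ihd:
    female: [0.86, 0.64, 0.42, 0.34]
    male:   [0.76, 0.51, 0.35, 0.36]
  is:
    female: [0.48, 0.48, 0.49, 0.50]
    male:   [0.47, 0.47, 0.49, 0.49]
  hf:
    female: [0.12, 0.14, 0.18, 0.34]
    male:   [0.14, 0.16, 0.23, 0.39]

# multiplicative relative risks; sbp_per10 applies per 10 mmHg above 120
comorbidity_rr:
  mi:  {smoker: 2.0, diabetes: 1.9, hypertension: 1.4, af: 1.2, sbp_per10: 1.08}
  ihd: {smoker: 1.9, diabetes: 1.8, hypertension: 1.4, af: 1.2, sbp_per10: 1.08}
  is:  {smoker: 1.9, diabetes: 1.5, hypertension: 1.5, af: 1.8, sbp_per10: 1.12}
  hf:  {smoker: 1.3, diabetes: 1.8, hypertension: 1.6, af: 1.8, sbp_per10: 1.10}

# soft targets the defaults were calibrated to (documented, not enforced)
calibration_targets:
  stratum1_lifetime_mi_pct: 5
  stratum4_lifetime_mi_pct: 73
  stratum1_life_expectancy_years: 80
  male_female_mi_ratio_strata_1_3: 2
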