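# Default synthetic-population parameters.
#
# Lifetime lipid set-points are trivariate log-normal (LDL-C, HDL-C,
# triglycerides) per sex and ratio stratum, rejection-sampled into the
# stratum's HDL-C/LDL-C ratio window. `target_mean` holds the per-sex
# stratum means the generator aims to reproduce after rejection; `mu_log`
# holds the calibrated latent log-means that achieve them (recalibrated and
# frozen whenever targets or spreads change). Comorbidity prevalence curves
# are logistic in age: plateau / (1 + exp(-(age - midpoint)/width)).

n_per_stratum: 1000
sex_split: 0.5
seed: 1
rejection_floor: 1.0e-3

lipids:
  sd_log: {ldl: 0.20, hdl: 0.12, tg: 0.35}
  correlation: {ldl_hdl: -0.10, ldl_tg: 0.30, hdl_tg: -0.40}
  target_mean:
    female: {ldl: [2.63, 3.73, 4.02, 3.45], hdl: [1.68, 1.49, 1.21, 0.77]}
    male:   {ldl: [2.53, 3.44, 3.93, 3.54], hdl: [1.50, 1.36, 1.17, 0.74]}
  mu_log:      # calibrated: post-rejection means reproduce target_mean
    female: {ldl: [0.98539, 1.26788, 1.31476, 0.93204],
             hdl: [0.49856, 0.41065, 0.21330, -0.14856]}
    male:   {ldl: [0.97930, 1.24011, 1.33024, 1.08914],
             hdl: [0.37325, 0.29842, 0.16462, -0.24192]}
  tg_mean:
    female: [1.10, 1.30, 1.50, 1.80]
    male:   [1.20, 1.40, 1.60, 1.90]

comorbidities:
  smoker:
    midpoint: 18
    width: 2.0
    plateau:
      female: [0.14, 0.18, 0.24, 0.30]
      male:   [0.18, 0.24, 0.30, 0.38]
  diabetes:
    midpoint: 62
    width: 11.0
    plateau:
      female: [0.10, 0.14, 0.20, 0.30]
      male:   [0.12, 0.16, 0.24, 0.34]
  hypertension:
    midpoint: 55
    width: 12.0
    plateau:
      female: [0.38, 0.44, 0.52, 0.60]
      male:   [0.40, 0.46, 0.54, 0.62]
  af:
    midpoint: 78
    width: 6.0
    plateau:
      female: [0.05, 0.06, 0.08, 0.10]
      male:   [0.06, 0.07, 0.09, 0.12]

biometrics:
  hba1c:
    mean:
      female: [5.35, 5.45, 5.60, 5.85]
      male:   [5.40, 5.50, 5.65, 5.90]
    sd: 0.45
    floor: 4.0
  sbp:
    mean:
      female: [116, 120, 125, 130]
      male:   [120, 124, 129, 134]
    sd: 13.0
    floor: 85.0
  bmi:
    mean:
      female: [26.0, 26.7, 27.4, 28.2]
      male:   [26.8, 27.4, 28.0, 28.8]
    sd: 4.2
    floor: 16.0
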