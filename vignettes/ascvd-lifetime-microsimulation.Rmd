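---
title: "Lifetime ASCVD burden across lipid risk strata: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime ASCVD burden across lipid risk strata: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ascvdsim` is a patient-level discrete-event microsimulation of lifetime
atherosclerotic cardiovascular disease (ASCVD). Synthetic birth cohorts,
stratified by the HDL-C/LDL-C ratio, are advanced year by year under five
competing hazards — myocardial infarction (MI), ischaemic heart disease
(IHD), ischaemic stroke (IS), heart failure (HF) and other-cause death — and
aggregated into life expectancy, lifetime QALYs, event counts per 100,000
births and cumulative-incidence curves. This vignette documents the model,
its parameters, the synthetic-data generator, the numerical choices, and the
limitations a user should know about.

## Risk stratification

Two stratifications run through everything:

* **Ratio strata** on HDL-C/LDL-C: group 1 (low risk) ratio >= 0.45, group 2
  in [0.35, 0.45), group 3 in [0.25, 0.35), group 4 (very high risk) < 0.25.
  Intervals are lower-closed; a ratio of exactly 0.45 is group 1. The
  cutoffs are a `risk_group_spec()` argument, not constants.
* **LDL-C strata** at 3.1, 4.0 and 5.0 mmol/L, also lower-closed (an LDL-C
  of exactly 3.1 falls in group 2).

Because stratification is by ratio, the very-high-risk group is dominated by
low HDL-C rather than extreme LDL-C: its mean LDL-C (about 3.5 mmol/L) is
*lower* than group 3's. Several downstream patterns (notably the LDL-group
cross-tabulations) inherit this.

## Hazard model

All rates are per person-year and are updated at the start of each annual
cycle. With age $a$, sex $s$, ratio stratum $g$, LDL-C $L$ (mmol/L) and
cumulative exposure $E$ (mg-years):

$$\lambda_{MI} = b_{MI,s}\,e^{\beta_{MI} a}\; m_g\; F\; R\;
  C_{MI}\; e^{\,\kappa\,\min(\max(E - E_0,\,0),\,E_{cap})}$$

* **Cumulative LDL-C exposure** accrues from birth as
  $dE = L \times 38.67 \times dt$ (38.67 mg/dL per mmol/L; `mgdl_per_mmol`).
  Below the threshold $E_0 = 5000$ mg-years the exposure term is 1; above
  it, excess risk grows exponentially with slope $\kappa$
  (`mi_excess_slope`, default 2.5e-4 per mg-year), continuous at the
  threshold. The exponent saturates at `excess_cap` (default 4000 mg-years
  above threshold): atherosclerotic burden stops compounding at extreme
  exposures, which keeps very old survivors from facing unbounded rates.
* **Ratio multiplier** $m_g$ (`ratio_multiplier`) carries the HDL-driven
  risk gradient across strata. MI and IHD have separate vectors
  (`ratio_multiplier`, `ihd_ratio_multiplier`) and separate excess slopes:
  a single shared gradient cannot reproduce both the steep MI gradient and
  the flatter IHD gradient between the low and moderate strata at the same
  time. The multiplier — not exposure alone — is what permits events well
  before the threshold age in the very-high-risk group.
* **Frailty** $F$ is a person-level log-normal multiplier on MI/IHD (mean 1,
  log-sd `frailty_sd_log`, default 1.3), drawn once per person from their
  counter-based substream. It represents unobserved individual risk
  variation (genetics, unmeasured exposures). Without it the stratum-4
  cohort is homogeneous: everyone who escapes an early infarction meets an
  enormous old-age hazard, other-cause deaths all but vanish, and the
  observed mix of high lifetime MI counts with substantial other-cause
  mortality is unreachable.
* **Recurrence** $R$: after a first MI/IHD the MI hazard is multiplied by
  `recurrent_multiplier` (default 0.3 — secondary prevention after a first
  coronary event), while the IHD hazard is multiplied by
  `ihd_recurrent_multiplier` (default 2.0 — survivors of infarction
  commonly develop chronic coronary disease). The published fatal/total
  ratios are close to plausible per-event fatalities, which implies
  survivors rarely re-infarct; a recurrence multiplier above 1 on MI makes
  an eventual fatal re-strike nearly certain and was rejected.
* **Comorbidities** $C$: multiplicative relative risks for smoking,
  diabetes, hypertension, atrial fibrillation, and systolic blood pressure
  per 10 mmHg above 120 (`comorbidity_rr`, per event type).

The other hazards:

$$\lambda_{IS} = b_{IS,s}\,e^{\beta_{IS}(a - 60)^+}\;
  0.84^{\,L_{ref} - L}\; C_{IS}, \qquad
  \lambda_{HF} = b_{HF,s}\,e^{\beta_{HF} a}\, C_{HF}\,
  \pi^{\mathbf{1}[\text{prior IHD}]}, \qquad
  \lambda_{O} = \mu_s + \alpha_s e^{\gamma_s a}.$$

* The stroke hazard is zero before the onset age (60 years) and scales as a
  power law in LDL-C with `stroke_rr_per_mmol = 0.84`: each 1 mmol/L LDL-C
  decrease lowers the hazard by exactly 16%, at any reference point.
* Heart failure deliberately has **no lipid term** — two persons differing
  only in lipids have identical HF hazards — but takes comorbidity relative
  risks and a multiplier after prior IHD.
* Other-cause mortality is Gompertz–Makeham per sex, calibrated so the
  event-free life expectancies sit near 83 (female) and 81 (male) years.

**Case fatality** is a per-event Bernoulli draw with probability configured
per event type, sex and stratum, scaled by a logistic age ramp
(`case_fatality_age`: factor about 0.45 at young ages rising to 1.25 past
age 72, capped at 0.97). Events at 40 are substantially more survivable than
events at 85; with a flat fatality the very-high-risk stratum loses most of
its cohort decades too early. Other-cause death is always fatal.

## Discrete-event engine

Within each annual step the five rates are held at their start-of-step
values; each active cause draws one candidate exponential event time, and
the earliest candidate inside the step fires (at most one clinical event per
person-step; recurrences can fire in later steps). Exposure and age advance
to the event time for fatal events and to the step end otherwise. Survivors
at the age cap (110) receive a forced terminal other-cause death, so no
trajectory is immortal under any miscalibration.

Every uniform the engine consumes is a pure function of
`(seed, person_id, step, channel)` (`substream_uniform`): a murmur3-style
counter hash, exact in doubles. Channels 1–5 are the event clocks, 6 the
fatality draw, 7–10 the comorbidity onsets, 11 the frailty draw. Results are
therefore invariant to cohort ordering and chunking, and a single person can
be re-simulated bit-identically outside their cohort. An earlier purely
affine mixer left exact lattice relationships between channels (the fatality
draw was a deterministic shift of the clock draw); the nonlinear finalizer
is load-bearing, and the test suite checks cross-channel independence.

## Synthetic population generator

The generator emulates the statistical shape of a national birth cohort
stratified by lipid risk:

* **Lipids** are lifetime set-points: one trivariate log-normal draw
  (LDL-C, HDL-C, triglycerides) per person, per sex and stratum, with
  triglycerides positively correlated with LDL-C (+0.3) and negatively with
  HDL-C (−0.4). Lipid levels are treated as stable with age; there is no
  within-life drift in v1, so medication-induced lipid change is out of
  scope. Draws are rejection-sampled into the stratum's ratio window; an
  acceptance rate below `rejection_floor` (1e-3) raises an error rather
  than sampling forever. The latent log-means in
  `inst/extdata/default_population.yaml` were calibrated by fixed-point
  iteration so the post-rejection stratum means reproduce the per-sex
  target means stored next to them (agreement < 0.01 mmol/L). The LDL
  log-sd (0.20) was chosen so the LDL > 5 mmol/L group is populated well
  enough for LDL-stratified analyses; with a narrower spread that group is
  nearly empty in ratio-stratified cohorts.
* **Sexes** split deterministically 50/50 per stratum (equal sub-cohorts by
  construction, not in expectation).
* **Comorbidities** follow logistic-in-age prevalence curves with per-sex,
  per-stratum plateaus (smoking from the late teens; diabetes and
  hypertension rising through midlife; atrial fibrillation late). During
  simulation, flags switch on — never off — with the incremental onset
  probability $(p(a{+}dt) - p(a))/(1 - p(a))$, so cross-sectional
  prevalence follows the configured curve. HbA1c, SBP and BMI are normal
  draws (floored) per sex and stratum.

What the generator does **not** emulate: real CDC/UK-Biobank microdata,
ethnicity-specific lipid distributions, secular trends, measurement error,
or lipid-comorbidity correlation beyond the stratum structure. Passing tests
therefore show internal consistency of the model world, not fidelity to any
particular national population.

## Outcomes

* **Life expectancy** is the mean death age; pooled rows are computed from
  the union of persons (identical to averaging per-sex values for equal
  sub-cohorts).
* **QALYs** integrate baseline utility (default $0.930 - 0.002a$, floored
  at 0.35) times multiplicative decrements for prevalent conditions
  (post-MI 0.88, IHD 0.92, post-stroke 0.82, HF 0.78, diabetes 0.96), per
  year lived. Decrements activate at the first annual boundary at or after
  the event. Discounting defaults to 0: the published QALY/LE ratios
  (~0.84 across strata with very different life expectancies) are
  inconsistent with material discounting.
* **Event tables** count first occurrences per person per type, per 100,000
  births; `fatal` counts persons with a fatal event of the type. HF is
  counted only when the first HF has no prior IHD in the history. Whether
  published "totals" count persons or events is ambiguous; v1 counts
  persons, documented here.
* **Mortality-adjusted cumulative risk** is the net-risk transform: one
  minus the Kaplan–Meier survivor function (via `survival::survfit`) with
  first events of the type as events and competing death as censoring —
  the product-integral of the cause-specific hazard alone. "Mortality
  adjusted" is not further specified in the source material; the net-risk
  construction is this package's definition, and alternative estimators
  (e.g. subdistribution risk) can be computed from the same event
  histories.

## Calibration

All baseline rates are declared calibration parameters
(`inst/extdata/default_hazards.yaml`); none are estimates from
individual-level data. The defaults were tuned once to the documented soft
targets — stratum-1 lifetime MI risk near 5%, stratum-4 near 73%, stratum-1
life expectancy near 80 years, male:female MI ratio near 2 in strata 1–3 —
and then frozen. At n = 4000/stratum the frozen defaults give stratum life
expectancies 80.6/79.3/77.6/63.1 years and lifetime MI risks
4.8/12.1/31.6/71.0%.

Known residuals of the default calibration, left as documented limitations
rather than re-tuned: ischaemic-stroke totals in strata 2–3 run above their
soft targets (about 14% vs 11% and 14% vs 9%) — with the stroke-LDL scaling
fixed at 0.84/mmol and matched life expectancies, the model cannot also
reproduce a flat-then-falling stroke profile across strata; stratum-4
other-cause deaths are about 20% vs a target of 31%; and stratum-4 lifetime
MI sits at 71% vs 73%.

## Numerical choices and degenerate inputs

* Annual cycles (`time_step = 1`, configurable in (0, 1]); rates
  piecewise-constant per cycle; competing clocks resolved by minimum
  candidate time, ties broken by fixed cause order (a probability-zero
  event).
* Exposure-threshold detection scans a grid and reports the **largest grid
  point still at the hazard plateau** (relative tolerance 1e-9) — the
  departure point itself, not the first strictly-exceeding point.
* Table statistics round half-away-from-zero with a `sqrt(eps)` guard so
  decimal-printed values round as their exact decimal representations
  (13.35 → 13.4 even though the double is 13.3499…).
* Empty cohorts simulate to empty results; `n_per_stratum = 0` is a
  validation error; zero hazards produce exactly one terminal record at the
  age cap.

## Limitations

Beyond the generator caveats above: no treatment or adherence modelling
(statin-era secondary prevention enters only through the recurrence
multiplier), no haemorrhagic stroke, no costs, no calendar-time or period
effects (pure birth-cohort time), MI/IHD modelled as separate competing
event types with correlated risk rather than a progressive disease chain,
and absolute simulated table values are calibration summaries, not
estimates with uncertainty.
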