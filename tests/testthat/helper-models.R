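# Builders for degenerate hazard worlds and minimal cohorts used across the
# unit tests. All start from the packaged defaults and switch off everything
# not under test (no frailty, no fatality age ramp, flat baselines).

zero_rate <- list(rate0 = 0, slope = 0)

both_sexes <- function(x) list(female = x, male = x)

# A hazard model with constant per-year rates for each cause and a single
# case-fatality probability everywhere. Stroke onset at age 0 so `is` acts
# as a plain constant hazard.
constant_model <- function(mi = 0, ihd = 0, is = 0, hf = 0, other = 0,
                           cf = 0.5, ...) {
  hazard_model(
    mi_baseline = both_sexes(list(rate0 = mi, slope = 0)),
    ihd_baseline = both_sexes(list(rate0 = ihd, slope = 0)),
    stroke_baseline = both_sexes(list(rate0 = is, slope = 0)),
    stroke_onset_age = 0,
    hf_baseline = both_sexes(list(rate0 = hf, slope = 0)),
    gompertz = both_sexes(list(makeham = other, scale = 1e-300, shape = 0.1)),
    mi_excess_slope = 0,
    ihd_excess_slope = 0,
    frailty_sd_log = 0,
    ratio_multiplier = rep(1, 4),
    ihd_ratio_multiplier = rep(1, 4),
    recurrent_multiplier = 1,
    ihd_recurrent_multiplier = 1,
    case_fatality_age = NULL,
    case_fatality = list(mi = both_sexes(rep(cf, 4)),
                         ihd = both_sexes(rep(cf, 4)),
                         is = both_sexes(rep(cf, 4)),
                         hf = both_sexes(rep(cf, 4))),
    ...)
}

# Minimal cohort of n persons at age 0 with fixed lipids.
flat_cohort <- function(n, ldl = 3, hdl = 1.5, sex = NULL, stratum = 1L) {
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  structure(data.frame(
    person_id = seq_len(n), sex = sex, age = rep(0, n),
    ldl_c = rep_len(ldl, n), hdl_c = rep_len(hdl, n), tg = rep(1.3, n),
    stratum = rep_len(as.integer(stratum), n),
    cumulative_ldl_exposure = rep(0, n),
    alive = rep(TRUE, n), prior_mi = rep(FALSE, n), prior_ihd = rep(FALSE, n),
    prior_is = rep(FALSE, n), prior_hf = rep(FALSE, n),
    stringsAsFactors = FALSE), class = c("ascvd_cohort", "data.frame"))
}

# Assemble an ascvd_sim by hand from death ages and an event list.
manual_sim <- function(death_age, events, sex = NULL) {
  n <- length(death_age)
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  persons <- data.frame(person_id = seq_len(n), sex = sex,
                        ldl_c = rep(3, n), hdl_c = rep(1.5, n),
                        stratum = rep(1L, n),
                        death_age = death_age, stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events), class = "ascvd_sim")
}

# A fixed reference person for hazard-function evaluations.
ref_person <- function(...) {
  p <- list(age = 50, sex = "male", stratum = 1L, ldl_c = 3,
            cumulative_ldl_exposure = 0, smoker = FALSE, diabetes = FALSE,
            hypertension = FALSE, af = FALSE, sbp = 120,
            prior_mi = FALSE, prior_ihd = FALSE, frailty = 1)
  utils::modifyList(p, list(...))
}
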