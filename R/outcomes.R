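# Cohort-level outcomes: life expectancy, lifetime QALYs, per-100,000-births
# event tables, crude cumulative incidence and mortality-adjusted (net)
# cumulative risk.

#' Health-related quality-of-life model
#'
#' Baseline utility declines linearly with age (floored), multiplied by
#' one multiplicative decrement per prevalent condition. Decrements take
#' effect at the first step boundary at or after the triggering event, in
#' line with the engine's annual cycles. Discounting is annual; the default
#' rate is 0 (undiscounted lifetime QALYs).
#'
#' @param u0 Baseline utility at age 0 (in \[0, 1\]).
#' @param age_slope Utility decline per year of age.
#' @param floor Lower bound on baseline utility.
#' @param decrements Named multiplicative factors in (0, 1\] applied while a
#'   condition is prevalent: `mi`, `ihd`, `is`, `hf`, `diabetes`.
#' @param discount_rate Annual discount rate (default 0).
#' @param baseline Optional function `(age, sex) -> utility` overriding the
#'   linear form.
#' @return A `utility_model` list.
#' @export
utility_model <- function(u0 = 0.930, age_slope = 0.002, floor = 0.35,
                          decrements = list(mi = 0.88, ihd = 0.92, is = 0.82,
                                            hf = 0.78, diabetes = 0.96),
                          discount_rate = 0, baseline = NULL) {
  stopifnot(u0 >= 0, u0 <= 1, floor >= 0, floor <= 1, discount_rate >= 0)
  if (any(unlist(decrements) <= 0 | unlist(decrements) > 1))
    stop("utility decrements must lie in (0, 1]", call. = FALSE)
  structure(list(u0 = u0, age_slope = age_slope, floor = floor,
                 decrements = decrements, discount_rate = discount_rate,
                 baseline = baseline),
            class = "utility_model")
}

.baseline_utility <- function(utility, age, sex) {
  if (!is.null(utility$baseline)) return(utility$baseline(age, sex))
  pmax(utility$floor, utility$u0 - utility$age_slope * age)
}

.first_event_age <- function(sim, type) {
  ev <- sim$events[sim$events$event_type == type, , drop = FALSE]
  first <- tapply(ev$age_at_event, ev$person_id, min)
  out <- rep(NA_real_, nrow(sim$persons))
  m <- match(sim$persons$person_id, as.numeric(names(first)))
  out[!is.na(m)] <- first[m[!is.na(m)]]
  out
}

#' Cohort life expectancy
#'
#' Arithmetic mean of death ages over a completed cohort. For equal-sized
#' female/male sub-cohorts the pooled value equals the mean of the per-sex
#' values exactly.
#'
#' @param sim An `ascvd_sim` from [simulate_cohort()], or a completed persons
#'   data.frame with a `death_age` column.
#' @return Mean age at death, years.
#' @export
life_expectancy <- function(sim) {
  persons <- if (inherits(sim, "ascvd_sim")) sim$persons else sim
  if (!nrow(persons)) stop("empty cohort has no life expectancy", call. = FALSE)
  if (anyNA(persons$death_age))
    stop("cohort is not completed: missing death ages", call. = FALSE)
  mean(persons$death_age)
}

#' Lifetime quality-adjusted life years
#'
#' Per person, the integral over lived years of baseline utility times the
#' product of active condition decrements times the annual discount factor;
#' the cohort value is the person mean. With discount 0 and utilities <= 1,
#' QALYs never exceed life expectancy.
#'
#' @param sim An `ascvd_sim`.
#' @param utility A [utility_model()].
#' @param per_person Return the per-person vector instead of the mean.
#' @return Mean lifetime QALYs (or per-person vector).
#' @export
lifetime_qalys <- function(sim, utility = utility_model(),
                           per_person = FALSE) {
  persons <- sim$persons
  if (!nrow(persons)) stop("empty cohort", call. = FALSE)
  T_death <- persons$death_age
  onset <- list(
    mi = .first_event_age(sim, "MI"),
    ihd = .first_event_age(sim, "IHD"),
    is = .first_event_age(sim, "IS"),
    hf = .first_event_age(sim, "HF"),
    diabetes = if (!is.null(persons$diabetes_onset_age))
      persons$diabetes_onset_age else rep(NA_real_, nrow(persons)))
  # decrements activate at the first integer year boundary >= onset
  onset <- lapply(onset, function(a) ceiling(a))
  disc <- utility$discount_rate
  qaly <- numeric(nrow(persons))
  for (y in 0:(ceiling(max(T_death)) - 1L)) {
    dt_y <- pmin(pmax(T_death - y, 0), 1)
    live <- dt_y > 0
    if (!any(live)) next
    dec <- rep(1, nrow(persons))
    for (cond in names(onset)) {
      fac <- utility$decrements[[cond]]
      if (!is.null(fac)) {
        act <- !is.na(onset[[cond]]) & onset[[cond]] <= y
        dec[act] <- dec[act] * fac
      }
    }
    u <- .baseline_utility(utility, y, persons$sex)
    qaly <- qaly + u * dec * dt_y * (1 + disc)^(-y)
  }
  if (per_person) qaly else mean(qaly)
}

#' Lifetime event table per 100,000 births
#'
#' First occurrences per event type per person: `total` counts persons with
#' at least one event of the type, `fatal` counts persons with a fatal event
#' of the type. Heart failure is counted only when the person's first HF
#' event has no prior IHD event in their history. Other-cause deaths are
#' fatal by construction.
#'
#' @param sim An `ascvd_sim`.
#' @param scale Births to scale to (default 100,000).
#' @return A data.frame with columns `event_type`, `total`, `fatal`.
#' @export
event_table <- function(sim, scale = 1e5) {
  persons <- sim$persons
  n <- nrow(persons)
  ev <- sim$events
  first_ihd <- .first_event_age(sim, "IHD")
  out <- lapply(.event_types, function(type) {
    sel <- ev$event_type == type
    if (type == "HF") {
      first_hf <- .first_event_age(sim, "HF")
      counted <- !is.na(first_hf) &
        (is.na(first_ihd) | first_hf < first_ihd)
      ids <- persons$person_id[counted]
      sel <- sel & ev$person_id %in% ids
    }
    total_ids <- unique(ev$person_id[sel])
    fatal_ids <- unique(ev$person_id[sel & ev$fatal])
    c(total = length(total_ids), fatal = length(fatal_ids))
  })
  out <- do.call(rbind, out)
  data.frame(event_type = .event_types,
             total = out[, "total"] / n * scale,
             fatal = out[, "fatal"] / n * scale,
             stringsAsFactors = FALSE)
}

#' Crude cumulative incidence curve
#'
#' Cumulative first events of a type per person by age: a non-decreasing
#' step curve whose terminal value times the scale equals the event-table
#' total for that type.
#'
#' @param sim An `ascvd_sim`.
#' @param event_type One of `"MI"`, `"IHD"`, `"IS"`, `"HF"`, `"OTHER_DEATH"`.
#' @param ages Age grid, years.
#' @return A data.frame with columns `age` and `incidence` (per person).
#' @export
cumulative_incidence <- function(sim, event_type, ages = 0:110) {
  if (!event_type %in% .event_types)
    stop("unknown event type: ", event_type, call. = FALSE)
  first <- .first_event_age(sim, event_type)
  inc <- vapply(ages, function(a) mean(!is.na(first) & first <= a), numeric(1))
  data.frame(age = ages, incidence = inc)
}

#' Mortality-adjusted (net) cumulative risk curve
#'
#' The cumulative risk that would obtain in the absence of competing death:
#' the product-integral of the cause-specific hazard alone, i.e. one minus
#' the Kaplan-Meier survivor function with first events of the type as
#' events and death from any other cause as censoring. Dominates the crude
#' cumulative incidence at every age.
#'
#' @inheritParams cumulative_incidence
#' @return A data.frame with columns `age` and `risk` (in \[0, 1\]).
#' @export
mortality_adjusted_cum_risk <- function(sim, event_type, ages = 0:110) {
  if (!event_type %in% .event_types)
    stop("unknown event type: ", event_type, call. = FALSE)
  first <- .first_event_age(sim, event_type)
  status <- as.integer(!is.na(first))
  time <- ifelse(status == 1L, first, sim$persons$death_age)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  s <- summary(fit, times = ages, extend = TRUE)$surv
  data.frame(age = ages, risk = 1 - s)
}
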