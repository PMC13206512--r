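# Discrete-event engine: annual competing exponential clocks.
#
# Within each step the five cause-specific rates are held constant at their
# start-of-step values; one candidate event time is sampled per active cause
# from its exponential clock and the earliest candidate inside the step fires
# (at most one clinical event per person-step). Non-fatal events set
# prior-disease flags and the person continues; fatal events (and other-cause
# death) terminate the trajectory at the event time. Survivors at the age cap
# receive a terminal other-cause death at the cap.
#
# All randomness is drawn from counter-based per-person substreams
# (substream_uniform), channels within a step:
#   1..5  candidate clocks for MI, IHD, IS, HF, OTHER_DEATH
#   6     case-fatality draw
#   7..10 comorbidity onsets (smoker, diabetes, hypertension, AF)
# so cohort results are invariant to person ordering and chunking.

#' Simulation configuration
#'
#' @param time_step Step length in years, in (0, 1]. Default 1.
#' @param age_cap Terminal age, years; survivors receive other-cause death at
#'   the cap. Default 110.
#' @param seed Integer root seed for the engine's counter-based substreams.
#' @return A `sim_config` list.
#' @export
sim_config <- function(time_step = 1, age_cap = 110, seed = 1L) {
  stopifnot(time_step > 0, time_step <= 1, age_cap > 0)
  structure(list(time_step = time_step, age_cap = age_cap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.as_state <- function(cohort) {
  s <- as.list(as.data.frame(cohort))
  n <- length(s$person_id)
  if (is.null(s$age)) s$age <- rep(0, n)
  if (is.null(s$cumulative_ldl_exposure)) s$cumulative_ldl_exposure <- rep(0, n)
  if (is.null(s$alive)) s$alive <- rep(TRUE, n)
  for (f in c("prior_mi", "prior_ihd", "prior_is", "prior_hf"))
    if (is.null(s[[f]])) s[[f]] <- rep(FALSE, n)
  s$death_age <- if (is.null(s$death_age)) rep(NA_real_, n) else s$death_age
  if (is.null(s$diabetes_onset_age)) {
    s$diabetes_onset_age <- rep(NA_real_, n)
    if (!is.null(s$diabetes)) s$diabetes_onset_age[s$diabetes] <- 0
  }
  s
}

.subset_state <- function(state, idx) lapply(state, `[`, idx)

# Person-level cardiac frailty (log-normal, mean 1) on the MI/IHD hazards,
# drawn once per person from substream channel 11 at step 0 unless the
# cohort already carries a `frailty` column.
.ensure_frailty <- function(state, model, config) {
  if (!is.null(state$frailty)) return(state)
  sdl <- model$frailty_sd_log
  state$frailty <- if (is.null(sdl) || sdl <= 0) {
    rep(1, length(state$person_id))
  } else {
    stats::qlnorm(substream_uniform(config$seed, state$person_id, 0L, 11L),
                  meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  state
}

# One engine step for the alive subset; mutates and returns
# list(state, events) where events holds this step's records.
.engine_step <- function(state, model, config, population, k) {
  dt_full <- config$time_step
  a0 <- (k - 1) * dt_full
  dt <- min(dt_full, config$age_cap - a0)
  if (dt <= 0) return(list(state = state, events = NULL))
  idx <- which(state$alive)
  if (!length(idx)) return(list(state = state, events = NULL))
  sub <- .subset_state(state, idx)
  id <- sub$person_id
  seed <- config$seed

  if (!is.null(population)) {
    factors <- c("smoker", "diabetes", "hypertension", "af")
    u <- stats::setNames(lapply(seq_along(factors), function(j)
      substream_uniform(seed, id, k, 6L + j)), factors)
    sub$age <- rep(a0, length(idx))
    before_diab <- sub$diabetes
    sub <- attach_comorbidities(sub, population, age = a0 + dt, u = u)
    for (fac in factors) state[[fac]][idx] <- sub[[fac]]
    new_diab <- sub$diabetes & !before_diab
    if (any(new_diab)) state$diabetes_onset_age[idx[new_diab]] <- a0 + dt
  }
  sub$age <- rep(a0, length(idx))

  lam <- cbind(MI = mi_hazard(sub, model),
               IHD = ihd_hazard(sub, model),
               IS = stroke_hazard(sub, model),
               HF = hf_hazard(sub, model),
               OTHER_DEATH = other_mortality_hazard(sub, model))
  tcand <- matrix(Inf, length(idx), 5L)
  for (j in 1:5) {
    uj <- substream_uniform(seed, id, k, j)
    pos <- lam[, j] > 0
    tcand[pos, j] <- -log(uj[pos]) / lam[pos, j]
  }
  tmin <- do.call(pmin, as.data.frame(tcand))
  jmin <- max.col(-tcand, ties.method = "first")
  fires <- tmin < dt
  etype <- .event_types[jmin]

  u_fatal <- substream_uniform(seed, id, k, 6L)
  pfatal <- rep(1, length(idx))
  for (ev in c("MI", "IHD", "IS", "HF")) {
    sel <- fires & etype == ev
    if (any(sel))
      pfatal[sel] <- .case_fatality_prob(ev, sub$sex[sel], sub$stratum[sel],
                                         model, age = a0 + tmin[sel])
  }
  fatal <- fires & (etype == "OTHER_DEATH" | u_fatal < pfatal)

  events <- if (any(fires)) {
    data.frame(person_id = id[fires],
               event_type = etype[fires],
               age_at_event = a0 + tmin[fires],
               fatal = fatal[fires],
               stringsAsFactors = FALSE)
  } else NULL

  # prior-disease flags from non-fatal (and recorded) events
  flag_map <- c(MI = "prior_mi", IHD = "prior_ihd", IS = "prior_is",
                HF = "prior_hf")
  for (ev in names(flag_map)) {
    sel <- fires & etype == ev & !fatal
    if (any(sel)) state[[flag_map[[ev]]]][idx[sel]] <- TRUE
  }

  # exposure and age advance to the event time (fatal) or step end
  lived <- ifelse(fatal, tmin, dt)
  state$cumulative_ldl_exposure[idx] <-
    state$cumulative_ldl_exposure[idx] + sub$ldl_c * mgdl_per_mmol * lived
  state$age[idx] <- a0 + lived
  died <- idx[fatal]
  if (length(died)) {
    state$alive[died] <- FALSE
    state$death_age[died] <- a0 + tmin[fatal]
  }
  list(state = state, events = events)
}

.finalize_sim <- function(state, events_list, config) {
  idx <- which(state$alive)
  if (length(idx)) { # cap rule: forced terminal other-cause death
    events_list[[length(events_list) + 1L]] <-
      data.frame(person_id = state$person_id[idx],
                 event_type = "OTHER_DEATH",
                 age_at_event = config$age_cap,
                 fatal = TRUE, stringsAsFactors = FALSE)
    state$alive[idx] <- FALSE
    state$death_age[idx] <- config$age_cap
    state$age[idx] <- config$age_cap
  }
  events <- do.call(rbind, events_list)
  events <- events[order(events$person_id, events$age_at_event), , drop = FALSE]
  rownames(events) <- NULL
  persons <- as.data.frame(state, stringsAsFactors = FALSE)
  class(persons) <- c("ascvd_cohort", "data.frame")
  structure(list(persons = persons, events = events), class = "ascvd_sim")
}

#' Simulate a cohort to death or the age cap
#'
#' Advances every person through life under the competing hazards of the
#' model, recording every event. Per-person counter-based substreams derived
#' from `(config$seed, person_id)` make the result independent of person
#' ordering and identical across repeat runs.
#'
#' @param cohort An `ascvd_cohort` from [sample_cohort()] (persons at age 0).
#' @param model A [hazard_model()].
#' @param config A [sim_config()].
#' @param population Optional [population_config()]; when supplied,
#'   comorbidity flags progress during the simulation along the configured
#'   age-prevalence curves. `NULL` freezes entry-age comorbidity state.
#' @return An `ascvd_sim` list: `persons` (final states incl. `death_age`)
#'   and `events` (long data.frame: person_id, event_type, age_at_event,
#'   fatal).
#' @export
simulate_cohort <- function(cohort, model, config = sim_config(),
                            population = NULL) {
  if (!length(cohort$person_id) || nrow(as.data.frame(cohort)) == 0L)
    return(structure(list(
      persons = as.data.frame(cohort),
      events = data.frame(person_id = integer(), event_type = character(),
                          age_at_event = numeric(), fatal = logical())),
      class = "ascvd_sim"))
  state <- .ensure_frailty(.as_state(cohort), model, config)
  n_steps <- ceiling(config$age_cap / config$time_step)
  events_list <- vector("list", 0L)
  for (k in seq_len(n_steps)) {
    res <- .engine_step(state, model, config, population, k)
    state <- res$state
    if (!is.null(res$events)) events_list[[length(events_list) + 1L]] <- res$events
    if (!any(state$alive)) break
  }
  .finalize_sim(state, events_list, config)
}

#' Simulate a single person
#'
#' Runs the same engine as [simulate_cohort()] on a one-person cohort; the
#' trajectory is bit-identical to that person's rows within a full cohort run
#' under the same seed (per-person substreams).
#'
#' @param person A one-row `ascvd_cohort`.
#' @inheritParams simulate_cohort
#' @return An `ascvd_sim` with one completed person and their event history
#'   (always non-empty: at least the terminal death record).
#' @export
simulate_person <- function(person, model, config = sim_config(),
                            population = NULL) {
  simulate_cohort(person, model, config, population)
}

#' Advance a person by one simulation step
#'
#' Executes a single competing-clock step at the person's current age: within
#' the step each active event type draws a candidate exponential time and the
#' earliest candidate inside the step fires. Exposure and age advance to the
#' event time (fatal) or the step end.
#'
#' @param person A one-row `ascvd_cohort` (alive).
#' @param model A [hazard_model()].
#' @param config A [sim_config()]; `config$time_step` is the step length.
#' @param population Optional [population_config()] for comorbidity onset.
#' @return A list with `person` (updated one-row state) and `events` (this
#'   step's records, `NULL` if none fired).
#' @export
step_person <- function(person, model, config = sim_config(),
                        population = NULL) {
  state <- .ensure_frailty(.as_state(person), model, config)
  stopifnot(all(state$alive))
  k <- floor(state$age[1] / config$time_step + 1e-9) + 1L
  res <- .engine_step(state, model, config, population, k)
  persons <- as.data.frame(res$state, stringsAsFactors = FALSE)
  class(persons) <- c("ascvd_cohort", "data.frame")
  list(person = persons, events = res$events)
}

#' @export
print.ascvd_sim <- function(x, ...) {
  cat("ascvd_sim:", nrow(x$persons), "persons,",
      nrow(x$events), "events;",
      "mean death age", round(mean(x$persons$death_age), 2), "\n")
  invisible(x)
}
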