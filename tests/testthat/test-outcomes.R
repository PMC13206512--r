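no_events <- function() data.frame(person_id = integer(),
                                   event_type = character(),
                                   age_at_event = numeric(),
                                   fatal = logical())

test_that("life expectancy is the mean death age, pooled exactly", {
  s <- manual_sim(c(60, 80), no_events())
  expect_equal(life_expectancy(s), 70)
  # pooled value equals the mean of equal-sized sex sub-cohorts exactly
  s2 <- manual_sim(c(82.02, 78.45), no_events(), sex = c("female", "male"))
  f <- mean(s2$persons$death_age[s2$persons$sex == "female"])
  m <- mean(s2$persons$death_age[s2$persons$sex == "male"])
  expect_identical(life_expectancy(s2), (f + m) / 2)
  expect_error(life_expectancy(manual_sim(numeric(0), no_events())), "empty")
})

test_that("QALY integration matches closed-form segments", {
  # utility identically 1, death at 10 -> 10 QALYs
  u1 <- utility_model(u0 = 1, age_slope = 0, decrements = list())
  s <- manual_sim(10, no_events())
  expect_equal(lifetime_qalys(s, u1), 10, tolerance = 1e-12)
  # constant utility u -> u * life expectancy
  uc <- utility_model(u0 = 0.7, age_slope = 0, decrements = list())
  s2 <- manual_sim(c(50, 73.25), no_events())
  expect_equal(lifetime_qalys(s2, uc), 0.7 * life_expectancy(s2),
               tolerance = 1e-12)
  # three segments: u = 0.9; MI decrement 0.8 from age 30; death at 50
  um <- utility_model(u0 = 0.9, age_slope = 0,
                      decrements = list(mi = 0.8))
  ev <- data.frame(person_id = 1L, event_type = "MI", age_at_event = 30,
                   fatal = FALSE)
  s3 <- manual_sim(50, ev)
  expect_equal(lifetime_qalys(s3, um), 30 * 0.9 + 20 * 0.9 * 0.8,
               tolerance = 1e-12)
})

test_that("QALYs never exceed life expectancy at zero discount", {
  cfg <- population_config()
  coh <- sample_cohort(cfg, 4, n = 200, seed = 21)
  s <- simulate_cohort(coh, hazard_model(), sim_config(seed = 21),
                       population = cfg)
  q <- lifetime_qalys(s, utility_model(), per_person = TRUE)
  expect_true(all(q <= s$persons$death_age + 1e-9))
  expect_true(all(q > 0))
})

test_that("event tables count first occurrences per person, scaled", {
  ev <- data.frame(person_id = c(1L, 1L),
                   event_type = c("MI", "OTHER_DEATH"),
                   age_at_event = c(55, 70), fatal = c(FALSE, TRUE))
  s <- manual_sim(70, ev)
  et <- event_table(s)
  expect_equal(et$total[et$event_type == "MI"], 100000)
  expect_equal(et$fatal[et$event_type == "MI"], 0)
  expect_equal(et$fatal[et$event_type == "OTHER_DEATH"], 100000)
  # HF with prior IHD history is excluded from the HF column
  ev2 <- data.frame(person_id = c(1L, 1L, 1L, 2L, 2L),
                    event_type = c("IHD", "HF", "OTHER_DEATH",
                                   "HF", "OTHER_DEATH"),
                    age_at_event = c(50, 60, 80, 65, 81),
                    fatal = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  s2 <- manual_sim(c(80, 81), ev2)
  et2 <- event_table(s2)
  expect_equal(et2$total[et2$event_type == "HF"], 50000) # person 2 only
  expect_equal(et2$total[et2$event_type == "IHD"], 50000)
})

test_that("fatal counts never exceed totals on simulated cohorts", {
  cfg <- population_config()
  coh <- sample_cohort(cfg, 2, n = 300, seed = 13)
  s <- simulate_cohort(coh, hazard_model(), sim_config(seed = 13),
                       population = cfg)
  et <- event_table(s)
  expect_true(all(et$fatal <= et$total))
  expect_true(all(et$total >= 0))
})

test_that("cumulative incidence is a consistent non-decreasing step curve", {
  ev <- data.frame(person_id = 1L, event_type = "IS", age_at_event = 50,
                   fatal = FALSE)
  s <- manual_sim(80, ev)
  ci <- cumulative_incidence(s, "IS", ages = c(0, 49, 50, 51, 110))
  expect_equal(ci$incidence, c(0, 0, 1, 1, 1))
  expect_equal(cumulative_incidence(s, "HF")$incidence, rep(0, 111))
  # terminal value times the scale equals the event-table total
  cfg <- population_config()
  coh <- sample_cohort(cfg, 1, n = 300, seed = 17)
  sim <- simulate_cohort(coh, hazard_model(), sim_config(seed = 17),
                         population = cfg)
  et <- event_table(sim)
  for (type in c("MI", "IS")) {
    term <- utils::tail(cumulative_incidence(sim, type)$incidence, 1)
    expect_equal(term * 1e5, et$total[et$event_type == type])
  }
  expect_error(cumulative_incidence(sim, "XX"), "unknown")
})

test_that("net risk equals crude risk when there is no competing death", {
  # non-fatal stroke clock only; everyone survives to the cap
  m <- constant_model(is = 0.01, cf = 0)
  s <- simulate_cohort(flat_cohort(2000), m, sim_config(seed = 6))
  ages <- seq(0, 109, by = 1)
  crude <- cumulative_incidence(s, "IS", ages)$incidence
  adj <- mortality_adjusted_cum_risk(s, "IS", ages)$risk
  expect_equal(adj, crude, tolerance = 1e-12)
})

test_that("net risk matches the two-hazard closed form and dominates crude", {
  lam <- 0.05
  m <- constant_model(is = lam, other = lam, cf = 1)
  s <- simulate_cohort(flat_cohort(10000), m,
                       sim_config(seed = 8, age_cap = 1000))
  horizon <- 60
  crude <- cumulative_incidence(s, "IS", ages = horizon)$incidence
  adj <- mortality_adjusted_cum_risk(s, "IS", ages = horizon)$risk
  crude_expect <- 0.5 * (1 - exp(-2 * lam * horizon))
  adj_expect <- 1 - exp(-lam * horizon)
  expect_lt(abs(crude - crude_expect), 3 * sqrt(0.25 / 10000))
  expect_lt(abs(adj - adj_expect), 0.02)
  # dominance pointwise on a heterogeneous simulated cohort
  cfg <- population_config()
  coh <- sample_cohort(cfg, 3, n = 300, seed = 19)
  sim <- simulate_cohort(coh, hazard_model(), sim_config(seed = 19),
                         population = cfg)
  ages <- 0:110
  expect_true(all(mortality_adjusted_cum_risk(sim, "IS", ages)$risk >=
                    cumulative_incidence(sim, "IS", ages)$incidence - 1e-12))
})
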