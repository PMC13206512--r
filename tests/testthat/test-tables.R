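tabs <- read_printed_tables()

test_that("packaged table fixtures are intact and internally consistent", {
  sums <- tools::md5sum(file.path(system.file("extdata", package = "ascvdsim"),
                                  c("table1.csv", "table2.csv", "table3.csv")))
  expect_identical(unname(sums),
                   c("ee623dbd05bd280991b389e31a93db2a",
                     "6f00c2038d351d6fec217775e66cf257",
                     "d860968de60ea721a6f4c477f5522b06"))
  # pooled life expectancy equals the mean of the sex rows (equal sub-cohorts)
  t1 <- tabs$table1
  for (st in 1:4) {
    pooled <- t1$life_expectancy[t1$sex == "all" & t1$stratum == st]
    bysex <- mean(t1$life_expectancy[t1$sex != "all" & t1$stratum == st])
    expect_lt(abs(pooled - bysex), 0.01)
  }
  # each pooled event cell is the mean of the sex cells to within one count
  t3 <- tabs$table3
  cells <- setdiff(names(t3), c("sex", "stratum"))
  for (st in 1:4) for (cl in cells) {
    pooled <- t3[[cl]][t3$sex == "all" & t3$stratum == st]
    bysex <- mean(t3[[cl]][t3$sex != "all" & t3$stratum == st])
    expect_lt(abs(pooled - bysex), 1 + 1e-9)
  }
  expect_true(all(t3[cells] >= 0))
})

test_that("life-expectancy and QALY gaps reproduce the published figures", {
  expect_equal(le_gap(tabs, 1, 4), 17.21)
  expect_equal(le_gap(tabs, 2, 2), 0)
  expect_equal(le_gap(tabs, 1, 4, decimals = 1, grouping = "ldl"), 13.4)
  expect_equal(qaly_gap(tabs, 1, 4, decimals = 1), 13.7)
  expect_equal(qaly_gap(tabs, 1, 4, decimals = 2), 13.68)
  expect_equal(qaly_gap(tabs, 3, 3), 0)
  expect_error(le_gap(tabs, 1, 9), "no unique row")
})

test_that("lifetime risks and excess fractions match the published table", {
  expect_equal(lifetime_risk_pct(tabs, "MI", 1), 5)
  expect_equal(lifetime_risk_pct(tabs, "MI", 4), 73.09)
  expect_equal(attributable_fraction(tabs, "IHD", 4, 1), 92)
  expect_equal(attributable_fraction(tabs, "MI", 4, 1), 93)
  expect_equal(attributable_fraction(tabs, "MI", 2, 2), 0)
  # an empty cell yields zero risk
  t0 <- tabs
  t0$table3$mi_total[t0$table3$sex == "all" & t0$table3$stratum == 2] <- 0
  expect_equal(lifetime_risk_pct(t0, "MI", 2), 0)
})

test_that("case-fatality ranges span the published sex-by-stratum extremes", {
  expect_equal(unname(case_fatality_range(tabs, "MI")), c(49, 64))
  expect_equal(unname(case_fatality_range(tabs, "IHD")), c(34, 86))
  # degenerate: everything fatal -> (100, 100)
  t1 <- tabs
  for (cl in c("hf", "ihd", "mi", "is"))
    t1$table3[[paste0(cl, "_fatal")]] <- t1$table3[[paste0(cl, "_total")]]
  expect_equal(unname(case_fatality_range(t1, "IHD")), c(100, 100))
  t2 <- tabs
  t2$table3$is_total[t2$table3$sex == "female" & t2$table3$stratum == 2] <- 0
  expect_error(case_fatality_range(t2, "IS"), "zero totals")
})

test_that("cumulative exposure estimates multiply level by lifetime", {
  expect_equal(cumulative_exposure_estimate(2.58, 80.23), 206.9934,
               tolerance = 1e-10)
  expect_lt(abs(cumulative_exposure_estimate(2.58, 80.23) - 207.31) / 207.31,
            0.005)
  expect_equal(cumulative_exposure_estimate(1, 1), 1)
  expect_equal(cumulative_exposure_estimate(3.50, 63.02), 220.57 * 1.0000,
               tolerance = 1e-3)
  expect_error(cumulative_exposure_estimate(-1, 10), "positive")
})

test_that("rounding is half-away-from-zero on decimal-printed values", {
  expect_equal(round_half_away(13.35, 1), 13.4)
  expect_equal(round_half_away(-13.35, 1), -13.4)
  expect_equal(round_half_away(13.68, 1), 13.7)
  expect_equal(round_half_away(79.58 - 66.23, 1), 13.4)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(13.349, 1), 13.3)
})

test_that("simulated summaries satisfy the structural table invariants", {
  cfg <- population_config()
  sims <- lapply(c(1, 4), function(st)
    simulate_cohort(sample_cohort(cfg, st, n = 250, seed = 23),
                    hazard_model(), sim_config(seed = 23), population = cfg))
  comb <- structure(list(
    persons = rbind(sims[[1]]$persons, sims[[2]]$persons),
    events = rbind(sims[[1]]$events, sims[[2]]$events)), class = "ascvd_sim")
  st <- summarize_simulation(comb)
  cells <- setdiff(names(st$table3), c("sex", "stratum"))
  for (cl in c("hf", "ihd", "mi", "is"))
    expect_true(all(st$table3[[paste0(cl, "_fatal")]] <=
                      st$table3[[paste0(cl, "_total")]]))
  for (s4 in unique(st$table3$stratum))
    expect_gte(lifetime_risk_pct(st, "MI", s4), 0)
  expect_true(all(st$table1$qalys <= st$table1$life_expectancy))
  # the same analytics run on simulated summaries
  expect_true(is.numeric(le_gap(st, 1, 4)))
})
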