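test_that("MI hazard is continuous at the exposure threshold and monotone", {
  m <- hazard_model()
  thr <- m$exposure_threshold
  below <- mi_hazard(ref_person(cumulative_ldl_exposure = thr - 1000), m)
  at <- mi_hazard(ref_person(cumulative_ldl_exposure = thr), m)
  just_above <- mi_hazard(ref_person(cumulative_ldl_exposure = thr + 1e-9), m)
  expect_equal(at, below, tolerance = 1e-12)
  expect_equal(just_above, at, tolerance = 1e-9)
  # monotone non-decreasing in exposure on a grid
  h <- vapply(seq(0, 12000, by = 100), function(e)
    mi_hazard(ref_person(cumulative_ldl_exposure = e), m), numeric(1))
  expect_true(all(diff(h) >= 0))
  # degenerate slope: exposure-independent
  m0 <- hazard_model(mi_excess_slope = 0, excess_cap = NULL)
  h0 <- vapply(c(0, 4000, 8000), function(e)
    mi_hazard(ref_person(cumulative_ldl_exposure = e), m0), numeric(1))
  expect_true(all(h0 == h0[1]))
})

test_that("excess risk above threshold is exponential in exposure", {
  m <- hazard_model()
  h1 <- mi_hazard(ref_person(cumulative_ldl_exposure = 6000), m)
  h2 <- mi_hazard(ref_person(cumulative_ldl_exposure = 5500), m)
  expect_equal(h1 / h2, exp(500 * m$mi_excess_slope), tolerance = 1e-12)
})

test_that("exposure threshold is identifiable by grid scan", {
  m <- hazard_model()
  expect_identical(detect_exposure_threshold(m, seq(0, 10000, by = 1)), 5000)
  # departure by >0.1% above plateau happens within one 50 mg-year step
  grid <- seq(0, 10000, by = 50)
  h <- vapply(grid, function(e)
    mi_hazard(ref_person(cumulative_ldl_exposure = e), m), numeric(1))
  first_exceed <- grid[min(which(h > h[1] * 1.001))]
  expect_lte(abs(first_exceed - m$exposure_threshold), 50)
})

test_that("stroke hazard scales as a power law in LDL-C", {
  m <- hazard_model()
  p <- ref_person(age = 70)
  h_ref <- stroke_hazard(utils::modifyList(p, list(ldl_c = m$stroke_ldl_ref)), m)
  base <- m$stroke_baseline$male$rate0 *
    exp(m$stroke_baseline$male$slope * (70 - m$stroke_onset_age))
  expect_equal(h_ref, base, tolerance = 1e-12) # reference point, no comorbidity
  # exact proportionality for arbitrary shifts
  for (d in c(-2, -1, 0.5, 1, 1.7)) {
    h <- stroke_hazard(utils::modifyList(p, list(ldl_c = m$stroke_ldl_ref + d)), m)
    expect_equal(h / h_ref, m$stroke_rr_per_mmol^(-d), tolerance = 1e-12)
  }
  # 1 mmol/L decrease: exactly 16% lower; 2 mmol/L: factor 0.84^2
  h_x <- stroke_hazard(utils::modifyList(p, list(ldl_c = 4)), m)
  h_dn <- stroke_hazard(utils::modifyList(p, list(ldl_c = 3)), m)
  expect_equal(1 - h_dn / h_x, 0.16, tolerance = 1e-12)
  expect_equal(stroke_hazard(utils::modifyList(p, list(ldl_c = 1)), m) /
                 stroke_hazard(utils::modifyList(p, list(ldl_c = 3)), m),
               0.7056, tolerance = 1e-12)
  # zero before onset age
  expect_identical(stroke_hazard(ref_person(age = 59.9), m), 0)
})

test_that("heart-failure hazard carries no lipid term", {
  m <- hazard_model()
  a <- hf_hazard(ref_person(ldl_c = 2, cumulative_ldl_exposure = 1000), m)
  b <- hf_hazard(ref_person(ldl_c = 6, cumulative_ldl_exposure = 12000), m)
  expect_identical(a, b)
})

test_that("Gompertz-Makeham mortality matches its closed form", {
  m <- constant_model()
  m$gompertz <- both_sexes(list(makeham = 0, scale = 2e-4, shape = 0.1))
  expect_equal(other_mortality_hazard(ref_person(age = 0), m), 2e-4)
  # quantile function inverts the survivor function on a parameter grid
  for (a in c(1e-5, 1e-4)) for (b in c(0.08, 0.12)) {
    med <- gm_quantile(0.5, makeham = 0, scale = a, shape = b)
    expect_equal(gm_survival(med, 0, a, b), 0.5, tolerance = 1e-8)
    analytic <- log(1 - b * log(0.5) / a) / b
    expect_equal(med, analytic, tolerance = 1e-6)
  }
})

test_that("all hazards are non-negative over reachable person states", {
  m <- hazard_model()
  set.seed(4)
  for (i in 1:50) {
    p <- ref_person(age = runif(1, 0, 110),
                    sex = sample(c("female", "male"), 1),
                    stratum = sample(4, 1),
                    ldl_c = runif(1, 0.5, 8),
                    cumulative_ldl_exposure = runif(1, 0, 30000),
                    smoker = runif(1) < 0.5, diabetes = runif(1) < 0.5,
                    hypertension = runif(1) < 0.5, af = runif(1) < 0.5,
                    sbp = runif(1, 90, 190),
                    prior_mi = runif(1) < 0.5, prior_ihd = runif(1) < 0.5)
    rates <- c(mi_hazard(p, m), ihd_hazard(p, m), stroke_hazard(p, m),
               hf_hazard(p, m), other_mortality_hazard(p, m))
    expect_true(all(is.finite(rates) & rates >= 0))
  }
})

test_that("case-fatality draws are Bernoulli at the configured probability", {
  m0 <- constant_model(cf = 0)
  m1 <- constant_model(cf = 1)
  mh <- constant_model(cf = 0.5)
  p <- list(sex = rep("female", 10000), stratum = rep(2L, 10000), age = 70)
  set.seed(9)
  expect_false(any(is_fatal("MI", p, m0)))
  expect_true(all(is_fatal("MI", p, m1)))
  frac <- mean(is_fatal("IHD", p, mh))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(is_fatal("BANANA", p, mh), "unknown event type")
})
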