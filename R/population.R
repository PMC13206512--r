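# Seeded synthetic birth cohorts: correlated log-normal lifetime lipid
# set-points rejection-sampled into the requested HDL-C/LDL-C ratio stratum,
# deterministic 50/50 sex split, plus age-parametrised comorbidity prevalence
# and normal laws for HbA1c, systolic blood pressure and BMI.

#' Load or build the population configuration
#'
#' Reads the packaged default population parameter file (YAML) and applies
#' overrides. Latent log-scale lipid means are calibrated so that the
#' post-rejection stratum means reproduce the per-sex target means stored
#' alongside them; comorbidity prevalence curves are logistic in age with
#' per-sex, per-stratum plateaus.
#'
#' @param file Path to a YAML/JSON file; `NULL` uses the packaged default.
#' @param ... Named overrides merged recursively over the file contents.
#' @return A validated `population_config` list.
#' @export
population_config <- function(file = NULL, ...) {
  if (is.null(file))
    file <- system.file("extdata", "default_population.yaml",
                        package = "ascvdsim")
  pars <- yaml::read_yaml(file)
  dots <- list(...)
  if (length(dots)) pars <- utils::modifyList(pars, dots)
  cfg <- structure(pars, class = "population_config")
  .check_population_config(cfg)
  cfg
}

.check_population_config <- function(cfg) {
  stopifnot(cfg$n_per_stratum >= 1,
            cfg$sex_split >= 0, cfg$sex_split <= 1,
            cfg$rejection_floor > 0)
  sd <- cfg$lipids$sd_log
  stopifnot(sd$ldl > 0, sd$hdl > 0, sd$tg > 0)
  if (!all(abs(unlist(cfg$lipids$correlation)) < 1))
    stop("lipid correlations must lie in (-1, 1)", call. = FALSE)
  if (min(eigen(.lipid_cov(cfg), only.values = TRUE)$values) <= 0)
    stop("lipid log-scale covariance is not positive definite", call. = FALSE)
  for (fac in names(cfg$comorbidities)) {
    pl <- cfg$comorbidities[[fac]]$plateau
    if (any(unlist(pl) < 0 | unlist(pl) > 1))
      stop("prevalence plateaus must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

.lipid_cov <- function(cfg) {
  sd <- cfg$lipids$sd_log
  rho <- cfg$lipids$correlation
  s <- c(sd$ldl, sd$hdl, sd$tg)
  R <- matrix(c(1, rho$ldl_hdl, rho$ldl_tg,
                rho$ldl_hdl, 1, rho$hdl_tg,
                rho$ldl_tg, rho$hdl_tg, 1), 3, 3)
  diag(s) %*% R %*% diag(s)
}

# Logistic prevalence curve for one comorbidity factor, vectorised over age.
.prevalence <- function(factor_cfg, age, sex, stratum) {
  plateau <- ifelse(sex == "female",
                    unlist(factor_cfg$plateau$female)[stratum],
                    unlist(factor_cfg$plateau$male)[stratum])
  plateau / (1 + exp(-(age - factor_cfg$midpoint) / factor_cfg$width))
}

#' Comorbidity prevalence at a given age
#'
#' Evaluates the configured logistic prevalence curve for one factor.
#'
#' @param config A [population_config()].
#' @param factor One of `"smoker"`, `"diabetes"`, `"hypertension"`, `"af"`.
#' @param age Age(s), years.
#' @param sex `"female"` or `"male"` (vectorised).
#' @param stratum Risk-group index 1..4 (vectorised).
#' @return Prevalence in \[0, 1\].
#' @export
comorbidity_prevalence <- function(config, factor, age, sex, stratum) {
  fc <- config$comorbidities[[factor]]
  if (is.null(fc)) stop("unknown comorbidity factor: ", factor, call. = FALSE)
  .prevalence(fc, age, sex, stratum)
}

# Rejection-sample `n` lipid set-points of one sex into a ratio stratum.
.sample_lipids_stratum <- function(cfg, sex, stratum, n, spec) {
  mu <- c(unlist(cfg$lipids$mu_log[[sex]]$ldl)[stratum],
          unlist(cfg$lipids$mu_log[[sex]]$hdl)[stratum],
          log(unlist(cfg$lipids$tg_mean[[sex]])[stratum]))
  Sigma <- .lipid_cov(cfg)
  bounds <- list(c(spec$ratio_cutoffs[1], Inf),
                 c(spec$ratio_cutoffs[2], spec$ratio_cutoffs[1]),
                 c(spec$ratio_cutoffs[3], spec$ratio_cutoffs[2]),
                 c(0, spec$ratio_cutoffs[3]))[[stratum]]
  out <- matrix(numeric(0), 0, 3)
  drawn <- 0L
  max_draws <- max(1e4, ceiling(n / cfg$rejection_floor))
  while (nrow(out) < n) {
    m <- max(1000L, 4L * (n - nrow(out)))
    if (drawn + m > max_draws)
      stop("stratum ", stratum, " is infeasible under the configured lipid ",
           "distributions (rejection acceptance below ",
           cfg$rejection_floor, ")", call. = FALSE)
    z <- exp(MASS::mvrnorm(m, mu, Sigma))
    drawn <- drawn + m
    ratio <- z[, 2] / z[, 1]
    keep <- ratio >= bounds[1] & ratio < bounds[2]
    out <- rbind(out, z[keep, , drop = FALSE])
    if (drawn >= 1e4 && nrow(out) / drawn < cfg$rejection_floor)
      stop("stratum ", stratum, " is infeasible under the configured lipid ",
           "distributions (rejection acceptance below ",
           cfg$rejection_floor, ")", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a seeded birth cohort for one ratio stratum
#'
#' Returns `n_per_stratum` persons at age 0 with lifetime lipid set-points
#' whose HDL-C/LDL-C ratio lies in the requested stratum (rejection
#' sampling), a deterministic female/male split, and entry-age comorbidity
#' state drawn by [attach_comorbidities()]. Identical `config` + `seed` give
#' a field-for-field identical cohort.
#'
#' @param config A [population_config()].
#' @param stratum Ratio risk-group index in 1..4.
#' @param n Cohort size; defaults to `config$n_per_stratum`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param spec A [risk_group_spec()].
#' @return An `ascvd_cohort` data.frame, one row per person.
#' @examples
#' coh <- sample_cohort(population_config(), stratum = 1, n = 10, seed = 7)
#' table(coh$sex)
#' @export
sample_cohort <- function(config, stratum, n = config$n_per_stratum,
                          seed = config$seed, spec = risk_group_spec()) {
  stopifnot(stratum %in% 1:4, n >= 1)
  n_f <- round(n * config$sex_split)
  n_m <- n - n_f
  with_local_seed((seed * 131 + stratum) %% 2147483647, {
    lip <- rbind(
      if (n_f) .sample_lipids_stratum(config, "female", stratum, n_f, spec),
      if (n_m) .sample_lipids_stratum(config, "male", stratum, n_m, spec))
    cohort <- data.frame(
      person_id = stratum * 10000000L + seq_len(n),
      sex = rep(c("female", "male"), c(n_f, n_m)),
      age = 0,
      ldl_c = lip[, 1], hdl_c = lip[, 2], tg = lip[, 3],
      stratum = as.integer(stratum),
      cumulative_ldl_exposure = 0,
      alive = TRUE,
      prior_mi = FALSE, prior_ihd = FALSE, prior_is = FALSE, prior_hf = FALSE,
      stringsAsFactors = FALSE)
    cohort <- attach_comorbidities(cohort, config)
    class(cohort) <- c("ascvd_cohort", "data.frame")
    cohort
  })
}

#' Attach or update comorbidity state
#'
#' Draws the boolean comorbidity flags from the configured age/sex/stratum
#' prevalence curves and, on first invocation, HbA1c, systolic blood pressure
#' and BMI from their normal laws. When re-invoked at an older `age`, flags
#' already set stay set and unset flags switch on with the incremental onset
#' probability `(p(age) - p(a0)) / (1 - p(a0))`, so repeated application
#' reproduces the prevalence curve while flags never switch off.
#'
#' @param person An `ascvd_cohort` data.frame (or one row of it).
#' @param config A [population_config()].
#' @param age Target age(s); defaults to the person's current age.
#' @param u Optional named list of uniforms (one vector per factor) replacing
#'   R's RNG — used by the engine's counter-based substreams.
#' @return The updated person/cohort.
#' @export
attach_comorbidities <- function(person, config, age = NULL, u = NULL) {
  n <- length(person$person_id)
  if (is.null(age)) age <- person$age
  a0 <- person$age
  factors <- c("smoker", "diabetes", "hypertension", "af")
  for (j in seq_along(factors)) {
    fac <- factors[j]
    existing <- person[[fac]]
    fresh <- is.null(existing)
    if (fresh) existing <- rep(FALSE, n)
    p0 <- if (fresh) 0 else .prevalence(config$comorbidities[[fac]], a0,
                                        person$sex, person$stratum)
    p1 <- .prevalence(config$comorbidities[[fac]], age,
                      person$sex, person$stratum)
    p_on <- pmax(0, pmin(1, (p1 - p0) / pmax(1 - p0, .Machine$double.eps)))
    uu <- if (is.null(u)) stats::runif(n) else u[[fac]]
    person[[fac]] <- existing | (!existing & uu < p_on)
  }
  bio <- config$biometrics
  for (v in c("hba1c", "sbp", "bmi")) {
    if (is.null(person[[v]])) {
      mn <- ifelse(person$sex == "female",
                   unlist(bio[[v]]$mean$female)[person$stratum],
                   unlist(bio[[v]]$mean$male)[person$stratum])
      person[[v]] <- pmax(bio[[v]]$floor, stats::rnorm(n, mn, bio[[v]]$sd))
    }
  }
  person
}

#' Write / read a cohort as CSV
#'
#' One row per person with the serialisation columns
#' (person_id, sex, ldl_c, hdl_c, tg, smoker, diabetes, hba1c, sbp,
#' hypertension, af, bmi, stratum).
#'
#' @param cohort An `ascvd_cohort`.
#' @param path Output file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `ascvd_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("person_id", "sex", "ldl_c", "hdl_c", "tg", "smoker", "diabetes",
            "hba1c", "sbp", "hypertension", "af", "bmi", "stratum")
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$age <- 0
  cohort$cumulative_ldl_exposure <- 0
  cohort$alive <- TRUE
  cohort$prior_mi <- cohort$prior_ihd <- cohort$prior_is <- cohort$prior_hf <- FALSE
  class(cohort) <- c("ascvd_cohort", "data.frame")
  cohort
}
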