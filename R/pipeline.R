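# End-to-end pipeline: generate -> simulate -> summarise -> report, plus
# configuration validation and a reproducibility manifest.

#' Validate the configuration objects
#'
#' Checks every declared invariant on the population, hazard, simulation and
#' utility configurations and returns a report, one row per rule.
#'
#' @param population A [population_config()] or path to its YAML/JSON file.
#' @param hazards A [hazard_model()] or path to its YAML/JSON file.
#' @param sim A [sim_config()].
#' @param utility A [utility_model()].
#' @return A data.frame with columns `rule`, `pass`, `message`; attribute
#'   `valid` is `TRUE` when every rule passes.
#' @export
validate_config <- function(population = population_config(),
                            hazards = hazard_model(),
                            sim = sim_config(),
                            utility = utility_model()) {
  if (is.character(population)) population <- population_config(population)
  if (is.character(hazards)) hazards <- hazard_model(hazards)
  rules <- list(
    n_per_stratum_positive = function()
      population$n_per_stratum >= 1,
    sex_split_fraction = function()
      population$sex_split >= 0 && population$sex_split <= 1,
    prevalences_in_unit_interval = function()
      all(unlist(lapply(population$comorbidities,
                        function(f) unlist(f$plateau))) >= 0 &
          unlist(lapply(population$comorbidities,
                        function(f) unlist(f$plateau))) <= 1),
    lipid_covariance_positive_definite = function()
      min(eigen(.lipid_cov(population), only.values = TRUE)$values) > 0,
    rejection_floor_positive = function()
      population$rejection_floor > 0,
    exposure_threshold_positive = function()
      hazards$exposure_threshold > 0,
    stroke_rr_in_unit_interval = function()
      hazards$stroke_rr_per_mmol > 0 && hazards$stroke_rr_per_mmol < 1,
    rates_non_negative = function()
      all(vapply(c("mi_baseline", "ihd_baseline", "stroke_baseline",
                   "hf_baseline"),
                 function(b) hazards[[b]]$female$rate0 >= 0 &&
                   hazards[[b]]$male$rate0 >= 0, logical(1))) &&
      all(hazards$ratio_multiplier >= 0),
    case_fatality_probabilities = function()
      all(unlist(hazards$case_fatality) >= 0 &
          unlist(hazards$case_fatality) <= 1),
    gompertz_parameters = function()
      all(vapply(c("female", "male"), function(sx) {
        g <- hazards$gompertz[[sx]]
        g$makeham >= 0 && g$scale >= 0 && g$shape > 0
      }, logical(1))),
    time_step_in_unit_interval = function()
      sim$time_step > 0 && sim$time_step <= 1,
    age_cap_positive = function() sim$age_cap > 0,
    utilities_in_unit_interval = function()
      utility$u0 >= 0 && utility$u0 <= 1 && utility$floor >= 0 &&
      utility$floor <= 1,
    utility_decrements = function()
      all(unlist(utility$decrements) > 0 & unlist(utility$decrements) <= 1))
  res <- lapply(names(rules), function(nm) {
    ok <- tryCatch(isTRUE(rules[[nm]]()), error = function(e) FALSE)
    data.frame(rule = nm, pass = ok,
               message = if (ok) "ok" else "invariant violated",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, res)
  attr(report, "valid") <- all(report$pass)
  report
}

#' Run the full generation/simulation/summary pipeline
#'
#' Generates one birth cohort per ratio stratum, simulates all of them to
#' death or the age cap, and writes the cohort CSV, long-format event
#' history, the three summary tables, crude and mortality-adjusted incidence
#' curves, the derived-statistics JSON and a manifest with configuration
#' snapshot, seed and output checksums. A completed run is regenerable from
#' its manifest via [rerun_manifest()].
#'
#' @param out_dir Output directory (created if absent).
#' @param n_per_stratum Persons per ratio stratum.
#' @param seed Root seed for generation and simulation substreams.
#' @param population,hazards,sim,utility Configuration objects (defaults:
#'   packaged defaults).
#' @param spec A [risk_group_spec()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, n_per_stratum = 1000, seed = 42,
                         population = population_config(),
                         hazards = hazard_model(),
                         sim = sim_config(seed = seed),
                         utility = utility_model(),
                         spec = risk_group_spec()) {
  if (n_per_stratum < 1)
    stop("n_per_stratum must be at least 1", call. = FALSE)
  report <- validate_config(population, hazards, sim, utility)
  if (!attr(report, "valid"))
    stop("configuration validation failed: ",
         paste(report$rule[!report$pass], collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sims <- lapply(1:4, function(st) {
    coh <- sample_cohort(population, st, n = n_per_stratum, seed = seed,
                         spec = spec)
    simulate_cohort(coh, hazards, sim, population = population)
  })
  combined <- structure(
    list(persons = do.call(rbind, lapply(sims, `[[`, "persons")),
         events = do.call(rbind, lapply(sims, `[[`, "events"))),
    class = "ascvd_sim")

  write_cohort_csv(combined$persons, file.path(out_dir, "cohort.csv"))
  utils::write.csv(combined$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  tables <- summarize_simulation(combined, utility, spec)
  for (tn in names(tables))
    utils::write.csv(tables[[tn]], file.path(out_dir, paste0(tn, ".csv")),
                     row.names = FALSE)

  curves <- do.call(rbind, lapply(1:4, function(st) {
    s <- sims[[st]]
    do.call(rbind, lapply(c("MI", "IHD", "IS", "HF"), function(ev) {
      ci <- cumulative_incidence(s, ev)
      cbind(stratum = st, event_type = ev, ci)
    }))
  }))
  utils::write.csv(curves, file.path(out_dir, "cumulative_incidence.csv"),
                   row.names = FALSE)
  ldl_grp <- assign_ldl_group(combined$persons$ldl_c, spec)
  adj <- do.call(rbind, lapply(sort(unique(ldl_grp)), function(g) {
    keep <- ldl_grp == g
    ids <- combined$persons$person_id[keep]
    sub <- structure(list(
      persons = combined$persons[keep, , drop = FALSE],
      events = combined$events[combined$events$person_id %in% ids, ,
                               drop = FALSE]), class = "ascvd_sim")
    cbind(ldl_group = g, mortality_adjusted_cum_risk(sub, "IS"))
  }))
  utils::write.csv(adj, file.path(out_dir, "adjusted_stroke_risk.csv"),
                   row.names = FALSE)

  stats_json <- derived_statistics(tables)
  jsonlite::write_json(stats_json, file.path(out_dir, "derived_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- c("cohort.csv", "events.csv", "table1.csv", "table2.csv",
             "table3.csv", "cumulative_incidence.csv",
             "adjusted_stroke_risk.csv", "derived_stats.json")
  manifest <- list(
    package = "ascvdsim",
    version = as.character(utils::packageVersion("ascvdsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    n_per_stratum = n_per_stratum,
    config = list(population = unclass(population),
                  hazards = unclass(hazards),
                  sim = unclass(sim),
                  utility = unclass(utility)[c("u0", "age_slope", "floor",
                                               "decrements", "discount_rate")],
    spec = unclass(spec)),
    outputs = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' Rebuilds all outputs from the configuration snapshot and seed recorded in
#' a manifest; summary outputs are byte-identical to the original run.
#'
#' @param manifest_path Path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir Output directory for the regenerated run.
#' @return The new manifest, invisibly.
#' @export
rerun_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  population <- structure(cfg$population, class = "population_config")
  hazards <- structure(cfg$hazards, class = "hazard_model")
  sim <- structure(cfg$sim, class = "sim_config")
  utility <- do.call(utility_model, cfg$utility)
  spec <- do.call(risk_group_spec, cfg$spec)
  run_pipeline(out_dir, n_per_stratum = man$n_per_stratum, seed = man$seed,
               population = population, hazards = hazards, sim = sim,
               utility = utility, spec = spec)
}

#' Verify the output checksums recorded in a manifest
#'
#' @param manifest_path Path to `manifest.json`.
#' @param out_dir Directory holding the outputs (defaults to the manifest's
#'   directory).
#' @return Logical: `TRUE` if every recorded checksum matches.
#' @export
verify_manifest <- function(manifest_path, out_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  all(vapply(names(man$outputs), function(f) {
    identical(unname(tools::md5sum(file.path(out_dir, f))),
              unname(unlist(man$outputs[[f]]$md5)))
  }, logical(1)))
}
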