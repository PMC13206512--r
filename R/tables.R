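# Summary tables (life expectancy/QALYs by ratio stratum and by LDL group,
# lifetime events per 100,000 births) and the deterministic derived
# statistics computed from them. The same operations run on the packaged
# published-table fixtures and on simulated cohort summaries.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (13.35 -> 13.4 at one
#' decimal), guarded against binary floating-point representation of decimal
#' table values (79.58 - 66.23 is 13.3499... in doubles but rounds as the
#' exact decimal 13.35).
#'
#' @param x Numeric vector.
#' @param decimals Number of decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, decimals = 0) {
  sign(x) * floor(abs(x) * 10^decimals + 0.5 + sqrt(.Machine$double.eps)) /
    10^decimals
}

#' Read the packaged published summary tables
#'
#' Loads the three fixture CSVs shipped with the package: life expectancy and
#' QALYs by HDL-C/LDL-C ratio stratum (`table1`), by LDL-C group (`table2`),
#' and lifetime events per 100,000 births (`table3`).
#'
#' @param dir Directory holding `table1.csv`, `table2.csv`, `table3.csv`;
#'   defaults to the packaged fixtures.
#' @return An `ascvd_tables` list of three data.frames.
#' @export
read_printed_tables <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "ascvdsim")
  tabs <- lapply(c(table1 = "table1.csv", table2 = "table2.csv",
                   table3 = "table3.csv"),
                 function(f) utils::read.csv(file.path(dir, f),
                                             stringsAsFactors = FALSE))
  structure(tabs, class = "ascvd_tables")
}

.tab_row <- function(tab, sex, key_col, key) {
  r <- tab[tab$sex == sex & tab[[key_col]] == key, , drop = FALSE]
  if (nrow(r) != 1L)
    stop("no unique row for sex='", sex, "', ", key_col, "='", key, "'",
         call. = FALSE)
  r
}

#' Life-expectancy gap between two strata
#'
#' `LE(stratum_a) - LE(stratum_b)` on the pooled (`sex = "all"`) rows,
#' rounded half away from zero.
#'
#' @param tables An `ascvd_tables` (fixtures or simulated summary).
#' @param stratum_a,stratum_b Group labels (1..4; `grouping = "ldl"` also
#'   accepts `"gt4"`).
#' @param decimals Decimal places for rounding (default 2).
#' @param grouping `"ratio"` (table1) or `"ldl"` (table2).
#' @param sex Row set to compare within (default `"all"`).
#' @return The gap in years.
#' @examples
#' le_gap(read_printed_tables(), 1, 4) # 17.21
#' @export
le_gap <- function(tables, stratum_a, stratum_b, decimals = 2,
                   grouping = c("ratio", "ldl"), sex = "all") {
  grouping <- match.arg(grouping)
  tab <- if (grouping == "ratio") tables$table1 else tables$table2
  key <- if (grouping == "ratio") "stratum" else "ldl_group"
  a <- .tab_row(tab, sex, key, stratum_a)$life_expectancy
  b <- .tab_row(tab, sex, key, stratum_b)$life_expectancy
  round_half_away(a - b, decimals)
}

#' QALY gap between two strata
#'
#' As [le_gap()] on the lifetime-QALY column.
#' @inheritParams le_gap
#' @return The gap in QALYs.
#' @examples
#' qaly_gap(read_printed_tables(), 1, 4, decimals = 1) # 13.7
#' @export
qaly_gap <- function(tables, stratum_a, stratum_b, decimals = 2,
                     grouping = c("ratio", "ldl"), sex = "all") {
  grouping <- match.arg(grouping)
  tab <- if (grouping == "ratio") tables$table1 else tables$table2
  key <- if (grouping == "ratio") "stratum" else "ldl_group"
  a <- .tab_row(tab, sex, key, stratum_a)$qalys
  b <- .tab_row(tab, sex, key, stratum_b)$qalys
  round_half_away(a - b, decimals)
}

.event_cols <- c(HF = "hf", IHD = "ihd", MI = "mi", IS = "is",
                 OTHER_DEATH = "other")

#' Lifetime risk of an event type, percent
#'
#' Total events per 100,000 births divided by 1,000 (i.e. expressed as a
#' percentage of births).
#'
#' @inheritParams le_gap
#' @param event_type `"MI"`, `"IHD"`, `"IS"` or `"HF"`.
#' @param stratum Ratio-stratum label 1..4.
#' @return Lifetime risk, percent.
#' @examples
#' lifetime_risk_pct(read_printed_tables(), "MI", 1) # 5
#' @export
lifetime_risk_pct <- function(tables, event_type, stratum, sex = "all") {
  col <- paste0(.event_cols[[event_type]], "_total")
  r <- .tab_row(tables$table3, sex, "stratum", stratum)
  r[[col]] / 100000 * 100
}

#' Case-fatality range across sex-by-stratum cells, percent
#'
#' Fatal/total per cell over the eight sex-specific stratum cells (pooled
#' rows excluded), min and max rounded half away from zero to whole percent.
#'
#' @inheritParams lifetime_risk_pct
#' @return Named numeric `c(min, max)` in percent.
#' @examples
#' case_fatality_range(read_printed_tables(), "MI") # c(49, 64)
#' @export
case_fatality_range <- function(tables, event_type) {
  stub <- .event_cols[[event_type]]
  tab <- tables$table3[tables$table3$sex %in% c("female", "male"), ,
                       drop = FALSE]
  total <- tab[[paste0(stub, "_total")]]
  fatal <- tab[[paste0(stub, "_fatal")]]
  if (any(total <= 0))
    stop("case fatality undefined: zero totals in some cells", call. = FALSE)
  pct <- round_half_away(100 * fatal / total, 0)
  c(min = min(pct), max = max(pct))
}

#' Excess (attributable) fraction of events relative to a reference stratum
#'
#' `(1 - total_reference / total_index) * 100`, floored at zero and rounded
#' to whole percent: the share of the index stratum's lifetime events in
#' excess of the low-risk reference.
#'
#' @inheritParams lifetime_risk_pct
#' @param index_stratum,reference_stratum Ratio-stratum labels.
#' @return Percentage (whole percent).
#' @examples
#' attributable_fraction(read_printed_tables(), "IHD", 4, 1) # 92
#' @export
attributable_fraction <- function(tables, event_type, index_stratum,
                                  reference_stratum, sex = "all") {
  col <- paste0(.event_cols[[event_type]], "_total")
  idx <- .tab_row(tables$table3, sex, "stratum", index_stratum)[[col]]
  ref <- .tab_row(tables$table3, sex, "stratum", reference_stratum)[[col]]
  if (idx <= 0) stop("index stratum has no events", call. = FALSE)
  round_half_away(max(0, (1 - ref / idx) * 100), 0)
}

#' Cumulative LDL-C exposure from mean level and life expectancy
#'
#' The product `mean_ldl * life_expectancy` in mmol-years — the back-of-table
#' plausibility estimate of lifetime exposure.
#'
#' @param mean_ldl Mean LDL-C, mmol/L (positive).
#' @param life_expectancy Years (positive).
#' @return Exposure in mmol-years.
#' @examples
#' cumulative_exposure_estimate(2.58, 80.23) # ~207
#' @export
cumulative_exposure_estimate <- function(mean_ldl, life_expectancy) {
  if (!(mean_ldl > 0 && life_expectancy > 0))
    stop("mean LDL-C and life expectancy must be positive", call. = FALSE)
  mean_ldl * life_expectancy
}

# ---- simulated summaries in the same table shape -------------------------

.summarize_subset <- function(sim, keep, utility, scale) {
  ids <- sim$persons$person_id[keep]
  sub <- list(persons = sim$persons[keep, , drop = FALSE],
              events = sim$events[sim$events$person_id %in% ids, ,
                                  drop = FALSE])
  class(sub) <- "ascvd_sim"
  et <- event_table(sub, scale)
  lk <- function(type, col) et[et$event_type == type, col]
  data.frame(
    life_expectancy = life_expectancy(sub),
    qalys = lifetime_qalys(sub, utility),
    mean_ldl = mean(sub$persons$ldl_c),
    mean_hdl = mean(sub$persons$hdl_c),
    hf_total = lk("HF", "total"), hf_fatal = lk("HF", "fatal"),
    ihd_total = lk("IHD", "total"), ihd_fatal = lk("IHD", "fatal"),
    mi_total = lk("MI", "total"), mi_fatal = lk("MI", "fatal"),
    other_fatal = lk("OTHER_DEATH", "fatal"),
    is_total = lk("IS", "total"), is_fatal = lk("IS", "fatal"))
}

#' Summarise a simulated cohort into the published-table shape
#'
#' Builds the three summary tables (life expectancy/QALYs by ratio stratum,
#' by LDL-C group, and lifetime events per 100,000 births) from a completed
#' simulation, so every table-analytics operation runs interchangeably on
#' simulated output and on the packaged fixtures. Pooled (`"all"`) rows are
#' computed from the union of persons, not by averaging sex summaries.
#'
#' @param sim An `ascvd_sim` whose persons carry `stratum` and lipid columns
#'   (strata may be mixed, e.g. four concatenated stratum cohorts).
#' @param utility A [utility_model()].
#' @param spec A [risk_group_spec()] for the LDL-C grouping.
#' @param scale Births to scale event counts to (default 100,000).
#' @return An `ascvd_tables` list (`table1`, `table2`, `table3`).
#' @export
summarize_simulation <- function(sim, utility = utility_model(),
                                 spec = risk_group_spec(), scale = 1e5) {
  persons <- sim$persons
  sexes <- list(all = c("female", "male"), female = "female", male = "male")
  t1 <- t2 <- t3 <- NULL
  ldl_grp <- assign_ldl_group(persons$ldl_c, spec)
  for (sx in names(sexes)) {
    in_sex <- persons$sex %in% sexes[[sx]]
    for (st in sort(unique(persons$stratum))) {
      keep <- in_sex & persons$stratum == st
      if (!any(keep)) next
      s <- .summarize_subset(sim, keep, utility, scale)
      t1 <- rbind(t1, cbind(sex = sx, stratum = st,
                            s[c("life_expectancy", "qalys",
                                "mean_ldl", "mean_hdl")]))
      t3 <- rbind(t3, cbind(sex = sx, stratum = st,
                            s[!names(s) %in% c("mean_ldl", "mean_hdl",
                                               "life_expectancy", "qalys")]))
    }
    groups <- list(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L)
    if (sx == "all") groups$gt4 <- c(3L, 4L)
    for (g in names(groups)) {
      keep <- in_sex & ldl_grp %in% groups[[g]]
      if (!any(keep)) next
      s <- .summarize_subset(sim, keep, utility, scale)
      t2 <- rbind(t2, cbind(sex = sx, ldl_group = g,
                            s[c("life_expectancy", "qalys")]))
    }
  }
  rownames(t1) <- rownames(t2) <- rownames(t3) <- NULL
  structure(list(table1 = t1, table2 = t2, table3 = t3),
            class = "ascvd_tables")
}

#' All derived statistics as a named list
#'
#' Computes every table-derived headline statistic from an `ascvd_tables`
#' object: stratum 1-vs-4 life-expectancy and QALY gaps, the LDL-group 1-vs-4
#' life-expectancy gap, the stratum-1 and stratum-4 lifetime MI risks, MI and
#' IHD case-fatality ranges, the IHD and MI excess fractions, and the
#' stratum-1 cumulative-exposure estimate.
#'
#' @param tables An `ascvd_tables`.
#' @return Named list of numbers, serialisable to JSON.
#' @export
derived_statistics <- function(tables) {
  t1s1 <- .tab_row(tables$table1, "all", "stratum", 1)
  cf <- function(type, which) # NA when a sparse simulated cell is empty
    tryCatch(unname(case_fatality_range(tables, type)[which]),
             error = function(e) NA_real_)
  list(
    le_gap_ratio_1_4 = le_gap(tables, 1, 4, 2),
    qaly_gap_ratio_1_4_1dp = qaly_gap(tables, 1, 4, 1),
    qaly_gap_ratio_1_4_2dp = qaly_gap(tables, 1, 4, 2),
    le_gap_ldl_1_4_1dp = le_gap(tables, 1, 4, 1, grouping = "ldl"),
    lifetime_mi_risk_pct_stratum1 = lifetime_risk_pct(tables, "MI", 1),
    lifetime_mi_risk_pct_stratum4 = lifetime_risk_pct(tables, "MI", 4),
    mi_case_fatality_min = cf("MI", "min"),
    mi_case_fatality_max = cf("MI", "max"),
    ihd_case_fatality_min = cf("IHD", "min"),
    ihd_case_fatality_max = cf("IHD", "max"),
    ihd_excess_fraction_4_vs_1 = attributable_fraction(tables, "IHD", 4, 1),
    mi_excess_fraction_4_vs_1 = attributable_fraction(tables, "MI", 4, 1),
    cumulative_exposure_stratum1_mmol_years =
      cumulative_exposure_estimate(t1s1$mean_ldl, t1s1$life_expectancy))
}
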