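# Lipid profiles, risk-group stratification and cumulative LDL-C exposure.

#' Conversion factor between mmol/L and mg/dL for LDL-C
#'
#' Cumulative LDL-C exposure is booked internally in mg-years; concentrations
#' are carried in mmol/L. One mmol/L of LDL-C equals 38.67 mg/dL.
#' @export
mgdl_per_mmol <- 38.67

#' Construct a lipid profile
#'
#' @param ldl_c LDL cholesterol, mmol/L (strictly positive).
#' @param hdl_c HDL cholesterol, mmol/L (strictly positive).
#' @param triglycerides Triglycerides, mmol/L (strictly positive).
#' @return A `lipid_profile` list with the three concentrations and the
#'   HDL-C/LDL-C `ratio`.
#' @examples
#' lipid_profile(2.58, 1.59, 1.2)$ratio
#' @export
lipid_profile <- function(ldl_c, hdl_c, triglycerides = 1.3) {
  if (!all(is.finite(ldl_c) & ldl_c > 0) ||
      !all(is.finite(hdl_c) & hdl_c > 0) ||
      !all(is.finite(triglycerides) & triglycerides > 0)) {
    stop("lipid concentrations must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(ldl_c = ldl_c, hdl_c = hdl_c,
                 triglycerides = triglycerides,
                 ratio = hdl_c / ldl_c),
            class = "lipid_profile")
}

#' Risk-group stratification cutoffs
#'
#' Cutoffs for the two stratifications used throughout: the HDL-C/LDL-C ratio
#' strata (low to very-high risk) and the LDL-C concentration strata.
#' Intervals are lower-closed: a ratio exactly at a cutoff belongs to the
#' lower-risk side (ratio 0.45 is group 1), and an LDL-C exactly at a cutoff
#' belongs to the higher group (3.1 mmol/L is group 2).
#'
#' @param ratio_cutoffs Strictly decreasing ratio cutoffs separating groups
#'   1|2, 2|3, 3|4. Default `c(0.45, 0.35, 0.25)`.
#' @param ldl_cutoffs Strictly increasing LDL-C cutoffs (mmol/L) separating
#'   groups 1|2, 2|3, 3|4. Default `c(3.1, 4.0, 5.0)`.
#' @return A `risk_group_spec` list.
#' @export
risk_group_spec <- function(ratio_cutoffs = c(0.45, 0.35, 0.25),
                            ldl_cutoffs = c(3.1, 4.0, 5.0)) {
  stopifnot(length(ratio_cutoffs) == 3L, length(ldl_cutoffs) == 3L)
  if (any(diff(ratio_cutoffs) >= 0))
    stop("ratio cutoffs must be strictly decreasing", call. = FALSE)
  if (any(diff(ldl_cutoffs) <= 0))
    stop("LDL cutoffs must be strictly increasing", call. = FALSE)
  structure(list(ratio_cutoffs = as.numeric(ratio_cutoffs),
                 ldl_cutoffs = as.numeric(ldl_cutoffs)),
            class = "risk_group_spec")
}

#' Assign the HDL-C/LDL-C ratio risk group
#'
#' Group 1 (low risk): ratio >= 0.45; group 2: 0.35 <= ratio < 0.45;
#' group 3: 0.25 <= ratio < 0.35; group 4 (very high risk): ratio < 0.25.
#'
#' @param profile A [lipid_profile()], or a numeric vector of ratios.
#' @param spec A [risk_group_spec()].
#' @return Integer group index in 1..4 (vectorised).
#' @examples
#' assign_risk_group(lipid_profile(2.58, 1.59)) # 1
#' assign_risk_group(lipid_profile(3.50, 0.76)) # 4
#' @export
assign_risk_group <- function(profile, spec = risk_group_spec()) {
  ratio <- if (inherits(profile, "lipid_profile")) profile$ratio else profile
  if (!all(is.finite(ratio) & ratio > 0))
    stop("HDL-C/LDL-C ratio must be finite and positive", call. = FALSE)
  cut <- spec$ratio_cutoffs
  ifelse(ratio >= cut[1], 1L,
    ifelse(ratio >= cut[2], 2L,
      ifelse(ratio >= cut[3], 3L, 4L)))
}

#' Assign the LDL-C concentration group
#'
#' Group 1: LDL-C < 3.1 mmol/L; group 2: 3.1 <= LDL-C < 4.0;
#' group 3: 4.0 <= LDL-C < 5.0; group 4: LDL-C >= 5.0.
#'
#' @inheritParams assign_risk_group
#' @return Integer group index in 1..4 (vectorised).
#' @examples
#' assign_ldl_group(lipid_profile(2.58, 1.59)) # 1
#' @export
assign_ldl_group <- function(profile, spec = risk_group_spec()) {
  ldl <- if (inherits(profile, "lipid_profile")) profile$ldl_c else profile
  if (!all(is.finite(ldl) & ldl > 0))
    stop("LDL-C must be finite and positive", call. = FALSE)
  cut <- spec$ldl_cutoffs
  ifelse(ldl < cut[1], 1L,
    ifelse(ldl < cut[2], 2L,
      ifelse(ldl < cut[3], 3L, 4L)))
}

#' Accrue cumulative LDL-C exposure
#'
#' Cumulative exposure is the time-integral of the LDL-C concentration,
#' booked in mg-years: `exposure + ldl_c * 38.67 * dt`. Exposure accrues from
#' birth; with stable lifetime lipid set-points this is linear in age.
#'
#' @param exposure Current cumulative exposure, mg-years (non-negative).
#' @param ldl_c LDL-C concentration, mmol/L.
#' @param dt Elapsed time, years (`dt = 0` is the identity).
#' @return Updated exposure in mg-years.
#' @examples
#' accumulate_exposure(0, 135 / mgdl_per_mmol, 37.037) # ~5000 mg-years
#' @export
accumulate_exposure <- function(exposure, ldl_c, dt) {
  if (any(dt < 0)) stop("dt must be non-negative", call. = FALSE)
  exposure + ldl_c * mgdl_per_mmol * dt
}

#' Convert cumulative exposure between mg-years and mmol-years
#'
#' @param exposure_mg Exposure in mg-years.
#' @return Exposure in mmol-years.
#' @export
exposure_as_mmol_years <- function(exposure_mg) exposure_mg / mgdl_per_mmol
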