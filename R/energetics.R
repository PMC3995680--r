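# Indirect-calorimetry reference values: Weir energy expenditure from gas
# exchange and METs relative to each subject's measured seated resting rate.

#' Energy expenditure by the abbreviated Weir equation
#'
#' EE (kcal/min) = 3.941 x VO2 + 1.106 x VCO2, with gas volumes in L/min.
#' The coefficients are the classical abbreviated-equation constants and can
#' be overridden.
#'
#' @param vo2_l_min,vco2_l_min Oxygen consumption and carbon dioxide
#'   production in L/min (non-negative; vectorized).
#' @param coef_vo2,coef_vco2 Weir coefficients in kcal/L.
#' @return Energy expenditure in kcal/min.
#' @export
weir_energy_expenditure <- function(vo2_l_min, vco2_l_min,
                                    coef_vo2 = 3.941, coef_vco2 = 1.106) {
  if (any(vo2_l_min < 0) || any(vco2_l_min < 0))
    stop("gas volumes must be non-negative")
  coef_vo2 * vo2_l_min + coef_vco2 * vco2_l_min
}

#' METs relative to measured seated resting metabolic rate
#'
#' The activity energy expenditure divided by the subject's measured seated
#' resting expenditure — the study definition of METs, not the 3.5 mL/kg/min
#' convention (see [mets_conventional()] for that).
#'
#' @param activity_kcal_min Activity energy expenditure, kcal/min
#'   (vectorized).
#' @param rest_kcal_min Seated resting energy expenditure, kcal/min
#'   (positive).
#' @return METs.
#' @export
mets_from_calorimetry <- function(activity_kcal_min, rest_kcal_min) {
  if (any(rest_kcal_min <= 0))
    stop("resting energy expenditure must be positive")
  mets <- activity_kcal_min / rest_kcal_min
  if (any(mets > 20)) warning("METs above 20; check inputs")
  mets
}

#' Conventional METs from VO2 and body weight
#'
#' The 3.5 mL/kg/min convention; provided for sensitivity analysis only — the
#' package default is RMR-relative METs ([mets_from_calorimetry()]).
#'
#' @param vo2_l_min Oxygen consumption, L/min.
#' @param weight_kg Body weight, kg.
#' @return METs under the conventional definition.
#' @export
mets_conventional <- function(vo2_l_min, weight_kg) {
  if (any(weight_kg <= 0)) stop("weight must be positive")
  (vo2_l_min * 1000 / weight_kg) / 3.5
}

#' Measured METs per subject x activity
#'
#' Joins a calorimetry table with a subject table and computes Weir energy
#' expenditure and RMR-relative METs.
#'
#' @param calorimetry Data.frame from [read_calorimetry()].
#' @param subjects Data.frame from [read_subjects()].
#' @return A data.frame `subject_id, activity, measured_mets`.
#' @export
measured_mets_table <- function(calorimetry, subjects) {
  miss <- setdiff(unique(calorimetry$subject_id), subjects$subject_id)
  if (length(miss))
    stop("calorimetry rows with no subject record: ",
         paste(miss, collapse = ", "))
  rmr <- subjects$rmr_kcal_min[match(calorimetry$subject_id,
                                     subjects$subject_id)]
  ee <- weir_energy_expenditure(calorimetry$vo2_l_min, calorimetry$vco2_l_min)
  data.frame(subject_id = calorimetry$subject_id,
             activity = calorimetry$activity,
             measured_mets = mets_from_calorimetry(ee, rmr),
             stringsAsFactors = FALSE)
}
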