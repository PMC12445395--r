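#' Mean arterial pressure
#'
#' `MAP = DBP + (SBP - DBP) / 3`, mmHg.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg; must not exceed `sbp`.
#' @return MAP in mmHg (vectorized).
#' @examples
#' mean_arterial_pressure(127, 76)  # 93
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(sbp < dbp, na.rm = TRUE))
    stop_invalid("systolic pressure must be >= diastolic pressure")
  dbp + (sbp - dbp) / 3
}

#' Rate-pressure product
#'
#' `RPP = HR x SBP`, a proxy for myocardial oxygen demand (mmHg * bpm).
#'
#' @param hr heart rate, beats/min.
#' @param sbp systolic blood pressure, mmHg.
#' @return RPP (vectorized).
#' @export
rate_pressure_product <- function(hr, sbp) hr * sbp

#' Myocardial perfusion reserve
#'
#' Ratio of hyperemic (stress) to resting MBF. A missing or zero rest MBF
#' yields `NA` (the patient is excluded from reserve analyses, not dropped).
#'
#' @param stress_mbf,rest_mbf MBF in mL/min/g (vectorized).
#' @return MPR, dimensionless; `NA` where the rest value is missing or zero.
#' @export
perfusion_reserve <- function(stress_mbf, rest_mbf) {
  out <- stress_mbf / rest_mbf
  out[is.na(rest_mbf) | rest_mbf == 0] <- NA_real_
  out
}

#' Coronary vascular resistance
#'
#' MAP at stress or rest divided by the corresponding MBF,
#' mmHg / (mL/min/g).
#'
#' @param map_mmHg mean arterial pressure, mmHg.
#' @param mbf corresponding MBF, mL/min/g (> 0).
#' @return CVR (vectorized).
#' @export
coronary_vascular_resistance <- function(map_mmHg, mbf) {
  if (any(mbf <= 0, na.rm = TRUE)) stop_invalid("MBF must be > 0 for CVR")
  map_mmHg / mbf
}

#' Adequacy of the hyperemic response
#'
#' The vasodilator response is adequate if the heart rate increased by at
#' least 10 beats/min, or if splenic switch-off was identified (adenosine
#' only; pass `NA` when the sign was not assessable).
#'
#' @param rest_hr,stress_hr heart rates, beats/min.
#' @param splenic_switch_off logical or `NA` (absent).
#' @return Logical (vectorized).
#' @export
hyperemia_adequate <- function(rest_hr, stress_hr, splenic_switch_off = NA) {
  if (any(c(rest_hr, stress_hr) <= 0, na.rm = TRUE))
    stop_invalid("heart rates must be positive")
  (stress_hr - rest_hr >= 10) |
    (!is.na(splenic_switch_off) & splenic_switch_off)
}

#' Age category
#'
#' `< 55` young adult; `55-74` middle-aged; `>= 75` elderly.
#'
#' @param age years.
#' @return Factor with levels `young_adult`, `middle_aged`, `elderly`.
#' @export
age_category <- function(age) {
  cut(age, breaks = c(-Inf, 55, 75, Inf), right = FALSE,
      labels = c("young_adult", "middle_aged", "elderly"))
}

#' Apply eligibility and subgroup rules to a cohort table
#'
#' Removes rows violating the recruitment and analysis rules — resting heart
#' rate above 100 bpm, rhythm other than sinus or AF (history of paroxysmal or
#' treated AF), and inadequate vasodilator response
#' ([hyperemia_adequate()]) — and appends the subgroup flags used downstream:
#' `lge_free`, `lvef_preserved` (LVEF at or above `lvef_threshold`),
#' `age_category`, `mpr_analyzable` (adenosine with rest MBF available) and
#' the derived `mpr` column.
#'
#' @param cohort data frame with at least `rhythm`, `rest_hr`, `stress_hr`,
#'   `splenic_switch_off`, `lvef`, `lge`, `age`, `agent`, `stress_mbf`,
#'   `rest_mbf`.
#' @param lvef_threshold preserved-LVEF cut, percent (default 55).
#' @return List with `analyzed` (the retained, flagged cohort) and
#'   `exclusions` (data frame of reason / n); the reason counts plus the
#'   analyzed count equal the input row count.
#' @export
apply_eligibility <- function(cohort, lvef_threshold = 55) {
  req <- c("rhythm", "rest_hr", "stress_hr", "splenic_switch_off",
           "lvef", "lge", "age", "agent", "stress_mbf", "rest_mbf")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop_invalid("cohort is missing required columns: %s",
                 paste(missing_cols, collapse = ", "))
  reasons <- rep(NA_character_, nrow(cohort))
  bad_rhythm <- !(as.character(cohort$rhythm) %in% c("sinus", "af"))
  reasons[bad_rhythm] <- "excluded rhythm history"
  hi_hr <- is.na(reasons) & cohort$rest_hr > 100
  reasons[hi_hr] <- "resting HR > 100"
  ok <- is.na(reasons)
  inad <- ok & !hyperemia_adequate(cohort$rest_hr, cohort$stress_hr,
                                   cohort$splenic_switch_off)
  reasons[inad] <- "poor vasodilator response"
  keep <- is.na(reasons)
  analyzed <- cohort[keep, , drop = FALSE]
  analyzed$lge_free <- as.character(analyzed$lge) == "none"
  analyzed$lvef_preserved <- analyzed$lvef >= lvef_threshold
  analyzed$age_category <- age_category(analyzed$age)
  analyzed$mpr_analyzable <- as.character(analyzed$agent) == "adenosine" &
    !is.na(analyzed$rest_mbf)
  analyzed$mpr <- ifelse(analyzed$mpr_analyzable,
                         perfusion_reserve(analyzed$stress_mbf, analyzed$rest_mbf),
                         NA_real_)
  tab <- table(factor(reasons[!keep]))
  exclusions <- data.frame(reason = names(tab), n = as.integer(tab),
                           row.names = NULL)
  list(analyzed = analyzed, exclusions = exclusions)
}

#' Optional rate-pressure-product correction of rest MBF
#'
#' Normalizes rest MBF by the resting rate-pressure product relative to a
#' reference value. Off by default throughout the package: the standard
#' analysis reports uncorrected rest MBF.
#'
#' @param rest_mbf rest MBF, mL/min/g.
#' @param rest_rpp resting RPP, mmHg * bpm.
#' @param reference_rpp reference RPP (default 10000).
#' @return Corrected rest MBF.
#' @export
rpp_correct_rest_mbf <- function(rest_mbf, rest_rpp, reference_rpp = 10000) {
  rest_mbf * reference_rpp / rest_rpp
}
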