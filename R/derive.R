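#' Estimate right atrial pressure from the inferior vena cava
#'
#' Categorical right atrial pressure (RAP) following the American Society of
#' Echocardiography rule: an IVC diameter of at most 21 mm that collapses by
#' more than 50% on a sniff test indicates normal RAP (3 mmHg); a diameter
#' over 21 mm with less than 50% collapse indicates elevated RAP (15 mmHg);
#' every other combination, including exact boundary values, is assigned the
#' intermediate 8 mmHg.
#'
#' @param ivc_diameter IVC end-expiratory diameter in mm.
#' @param ivc_collapse Fractional inspiratory collapse in `[0, 1]`.
#' @return Numeric vector with values in `{3, 8, 15}` mmHg; `NA` where either
#'   input is missing (downstream classification then falls back on the
#'   tricuspid gradient).
#' @examples
#' estimate_rap(c(18, 25, 25, 21), c(0.7, 0.3, 0.7, 0.5))
#' @export
estimate_rap <- function(ivc_diameter, ivc_collapse) {
  chk_range(ivc_diameter, lo = 1e-9, name = "ivc_diameter")
  chk_range(ivc_collapse, 0, 1, name = "ivc_collapse")
  out <- rep(8, length(ivc_diameter))
  out[ivc_diameter <= 21 & ivc_collapse > 0.5] <- 3
  out[ivc_diameter > 21 & ivc_collapse < 0.5] <- 15
  out[is.na(ivc_diameter) | is.na(ivc_collapse)] <- NA_real_
  out
}

#' Tricuspid pressure gradient by the simplified Bernoulli equation
#'
#' @param trv Tricuspid regurgitation peak velocity in m/s.
#' @return Gradient in mmHg, `4 * trv^2`; `NA` propagates.
#' @examples
#' tricuspid_gradient(3.0)  # 36 mmHg
#' @export
tricuspid_gradient <- function(trv) {
  chk_range(trv, lo = 0, name = "trv")
  4 * trv^2
}

#' Pulmonary artery systolic pressure
#'
#' Sum of the tricuspid gradient and the estimated right atrial pressure;
#' missing if either component is missing.
#'
#' @param gradient Tricuspid pressure gradient, mmHg.
#' @param rap Right atrial pressure, mmHg.
#' @return ePASP in mmHg or `NA`.
#' @export
compute_epasp <- function(gradient, rap) {
  gradient + rap
}

#' Left ventricular fractional shortening
#'
#' `(LVEDD - LVESD) / LVEDD * 100`. Records where the end-systolic diameter
#' exceeds the end-diastolic diameter are physically inconsistent and raise
#' an error naming the offending rows rather than being silently dropped.
#'
#' @param lvedd LV end-diastolic diameter, mm (> 0).
#' @param lvesd LV end-systolic diameter, mm (>= 0).
#' @return Fractional shortening in percent.
#' @examples
#' fractional_shortening(50, 30)  # 40
#' @export
fractional_shortening <- function(lvedd, lvesd) {
  chk_range(lvedd, lo = 1e-9, name = "lvedd")
  chk_range(lvesd, lo = 0, name = "lvesd")
  bad <- which(!is.na(lvedd) & !is.na(lvesd) & lvesd > lvedd)
  if (length(bad)) {
    stop_ephcohort(sprintf(
      "lvesd > lvedd (physically inconsistent) at rows: %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  (lvedd - lvesd) / lvedd * 100
}

#' Classify LV systolic dysfunction
#'
#' @param fs Fractional shortening, percent.
#' @return Logical: `TRUE` iff `fs < 29` (strict).
#' @export
classify_lv_systolic <- function(fs) {
  fs < 29
}

#' Classify right ventricular dilation
#'
#' @param rvedd Basal RV end-diastolic diameter, mm.
#' @return Logical: `TRUE` iff `rvedd > 42` (strict).
#' @export
classify_rv_dilated <- function(rvedd) {
  rvedd > 42
}

#' Default diastolic staging thresholds
#'
#' Named cutoffs for the three-stage LV diastolic function table, following
#' the staging literature for elderly cohorts. All are configurable; the
#' decision table itself is fixed (see [stage_diastolic()]).
#'
#' @param ea_low Lower E/A bound: below it, inflow shows the relaxation
#'   abnormality grouped with normal (stage 1).
#' @param ea_high Upper E/A bound: above it, inflow is restrictive
#'   (stages 3-4).
#' @param e_over_eprime E/E' bound separating pseudonormal (stage 2) filling
#'   from normal within the normal-appearing E/A range.
#' @param eprime_low E' bound (cm/s): a lower septal annular velocity also
#'   marks pseudonormal filling.
#' @param dt_low,dt_high Deceleration-time bounds (ms) replacing the E/A
#'   bounds in atrial fibrillation: below `dt_low` restrictive, above
#'   `dt_high` normal/relaxation-abnormality.
#' @return Named list of thresholds.
#' @export
diastolic_thresholds <- function(ea_low = 0.75, ea_high = 2.0,
                                 e_over_eprime = 10, eprime_low = 8,
                                 dt_low = 140, dt_high = 220) {
  stopifnot(ea_low < ea_high, dt_low < dt_high,
            e_over_eprime > 0, eprime_low > 0)
  list(ea_low = ea_low, ea_high = ea_high, e_over_eprime = e_over_eprime,
       eprime_low = eprime_low, dt_low = dt_low, dt_high = dt_high)
}

#' Stage LV diastolic function
#'
#' Three ordered categories from mitral inflow and tissue Doppler:
#' `normal_or_stage1` (normal filling or relaxation abnormality),
#' `stage2` (pseudonormal) and `stage3_4` (restrictive). In sinus rhythm the
#' table reads the E/A ratio first: above `ea_high` is restrictive, below
#' `ea_low` is a relaxation abnormality (grouped with normal), and in the
#' normal-appearing range the stage is pseudonormal when filling pressure
#' looks elevated (E/E' above `e_over_eprime` or E' below `eprime_low`),
#' normal otherwise. In atrial fibrillation the A wave is unusable, so the
#' deceleration time replaces the E/A ratio (`dt_low`/`dt_high` bounds) and
#' `a_peak` is never read.
#'
#' @param e_peak,a_peak Mitral inflow peak E and A velocities, m/s.
#' @param e_prime Septal annular early diastolic velocity, cm/s.
#' @param dec_time E-wave deceleration time, ms.
#' @param af Logical atrial fibrillation flag.
#' @param thresholds Output of [diastolic_thresholds()].
#' @return Factor with levels `normal_or_stage1`, `stage2`, `stage3_4`;
#'   `NA` where the required inputs for the participant's rhythm branch are
#'   missing.
#' @export
stage_diastolic <- function(e_peak, a_peak, e_prime, dec_time, af,
                            thresholds = diastolic_thresholds()) {
  n <- length(e_peak)
  af <- rep_len(as.logical(af), n)
  ratio <- 100 * e_peak / e_prime  # e_peak m/s vs e_prime cm/s
  ea <- e_peak / a_peak
  elevated <- ratio > thresholds$e_over_eprime | e_prime < thresholds$eprime_low

  stage <- rep(NA_character_, n)
  # sinus rhythm branch: E/A first, then filling-pressure indices
  sr <- !af & !is.na(ea)
  stage[sr & ea > thresholds$ea_high] <- "stage3_4"
  stage[sr & ea < thresholds$ea_low] <- "normal_or_stage1"
  mid <- sr & ea >= thresholds$ea_low & ea <= thresholds$ea_high
  stage[mid & !is.na(elevated) & elevated] <- "stage2"
  stage[mid & !is.na(elevated) & !elevated] <- "normal_or_stage1"
  # AF branch: deceleration time replaces E/A; a_peak never read
  afb <- af & !is.na(dec_time)
  stage[afb & dec_time < thresholds$dt_low] <- "stage3_4"
  stage[afb & dec_time > thresholds$dt_high] <- "normal_or_stage1"
  afm <- afb & dec_time >= thresholds$dt_low & dec_time <= thresholds$dt_high
  stage[afm & !is.na(elevated) & elevated] <- "stage2"
  stage[afm & !is.na(elevated) & !elevated] <- "normal_or_stage1"

  factor(stage, levels = c("normal_or_stage1", "stage2", "stage3_4"))
}

#' Derive all echocardiographic measures for a cohort
#'
#' Runs the per-participant derivations over a cohort table: RAP from the
#' IVC, tricuspid gradient, ePASP, fractional shortening with the systolic
#' dysfunction flag, diastolic staging and RV dilation. Missing inputs give
#' missing outputs; they are never coded as sentinel numbers.
#'
#' @param cohort Data frame in the layout of [cohort_dictionary()] (one row
#'   per participant).
#' @param thresholds Diastolic staging thresholds, see
#'   [diastolic_thresholds()].
#' @return Data frame keyed by `id` with columns `rap`, `gradient`, `epasp`,
#'   `fs`, `lv_sys_dysfunction`, `diastolic_stage`, `rv_dilated`, plus the
#'   carried-through `trv`, `trv_reason` and `rvedd` needed by the case
#'   definitions.
#' @export
derive_measures <- function(cohort, thresholds = diastolic_thresholds()) {
  stopifnot(is.data.frame(cohort))
  req <- c("id", "trv", "trv_reason", "ivc_diameter", "ivc_collapse",
           "lvedd", "lvesd", "rvedd", "e_peak", "a_peak", "e_prime",
           "dec_time", "af")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop_ephcohort("cohort is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(cohort$trv) &
                 !cohort$trv_reason %in% c("jet_absent", "jet_too_small",
                                           "not_recorded"))
  if (length(bad)) {
    stop_ephcohort(sprintf(
      "missing trv without a valid reason at rows: %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  rap <- estimate_rap(cohort$ivc_diameter, cohort$ivc_collapse)
  gradient <- tricuspid_gradient(cohort$trv)
  fs <- fractional_shortening(cohort$lvedd, cohort$lvesd)
  data.frame(
    id = cohort$id,
    rap = rap,
    gradient = gradient,
    epasp = compute_epasp(gradient, rap),
    fs = fs,
    lv_sys_dysfunction = classify_lv_systolic(fs),
    diastolic_stage = stage_diastolic(cohort$e_peak, cohort$a_peak,
                                      cohort$e_prime, cohort$dec_time,
                                      cohort$af, thresholds),
    rv_dilated = classify_rv_dilated(cohort$rvedd),
    trv = cohort$trv,
    trv_reason = cohort$trv_reason,
    rvedd = cohort$rvedd,
    stringsAsFactors = FALSE
  )
}
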