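#' Primary echocardiographic pulmonary hypertension definition
#'
#' Case ascertainment hierarchy for the primary definition (ePASP threshold
#' 40 mmHg): (1) when ePASP could be estimated, a participant is a case iff
#' ePASP exceeds the threshold; (2) when RAP is missing but TRV was
#' measured, the tricuspid-gradient fallback applies (gradient above
#' `4 * trv_fallback^2`); (3) when the regurgitation jet was absent or too
#' small to measure, the participant is assumed a non-case, since an
#' unmeasurable jet most likely reflects normal pulmonary pressures;
#' (4) participants with no tricuspid regurgitation data recorded at all are
#' excluded from the denominator.
#'
#' @param derived Output of [derive_measures()].
#' @param epasp_cut ePASP case threshold, mmHg.
#' @param trv_fallback TRV fallback threshold, m/s (gradient cut is
#'   `4 * trv_fallback^2` mmHg).
#' @return Data frame with `status` (factor case/noncase/excluded) and
#'   `path` (factor epasp_measured/trv_fallback/assumed_noncase/no_tr_data)
#'   recording how each row was ascertained.
#' @export
classify_primary <- function(derived, epasp_cut = 40, trv_fallback = 3.0) {
  n <- nrow(derived)
  status <- rep(NA_character_, n)
  path <- rep(NA_character_, n)
  grad_cut <- 4 * trv_fallback^2

  has_epasp <- !is.na(derived$epasp)
  status[has_epasp] <- ifelse(derived$epasp[has_epasp] > epasp_cut,
                              "case", "noncase")
  path[has_epasp] <- "epasp_measured"

  fb <- !has_epasp & !is.na(derived$gradient)
  status[fb] <- ifelse(derived$gradient[fb] > grad_cut, "case", "noncase")
  path[fb] <- "trv_fallback"

  an <- !has_epasp & is.na(derived$gradient) &
    derived$trv_reason %in% c("jet_absent", "jet_too_small")
  status[an] <- "noncase"
  path[an] <- "assumed_noncase"

  ex <- is.na(status)
  status[ex] <- "excluded"
  path[ex] <- "no_tr_data"

  data.frame(
    status = factor(status, levels = c("case", "noncase", "excluded")),
    path = factor(path, levels = c("epasp_measured", "trv_fallback",
                                   "assumed_noncase", "no_tr_data"))
  )
}

#' Right-ventricle-augmented definition
#'
#' Adds a dilated right ventricle (RVEDD > 42 mm) as a sufficient criterion
#' on top of the primary ePASP definition. Participants without any
#' tricuspid regurgitation data but with a dilated right ventricle become
#' classifiable cases, so this denominator can exceed the primary one;
#' no-TR-data participants with a normal-size or unmeasured right ventricle
#' remain excluded (their pressure status is unknowable under either
#' criterion).
#'
#' @param primary_status Factor from [classify_primary()] (`status` column).
#' @param rv_dilated Logical RV-dilation flag (may be `NA`).
#' @return Factor with levels case/noncase/excluded.
#' @export
classify_rv_augmented <- function(primary_status, rv_dilated) {
  status <- as.character(primary_status)
  dil <- !is.na(rv_dilated) & rv_dilated
  status[dil] <- "case"
  factor(status, levels = c("case", "noncase", "excluded"))
}

#' Stringent definition
#'
#' Same hierarchy as [classify_primary()] with the 50 mmHg ePASP threshold
#' and the TRV > 3.4 m/s fallback, and no right-ventricle criterion.
#'
#' @inheritParams classify_primary
#' @return Data frame with `status` and `path` as in [classify_primary()].
#' @export
classify_stringent <- function(derived, epasp_cut = 50, trv_fallback = 3.4) {
  classify_primary(derived, epasp_cut = epasp_cut, trv_fallback = trv_fallback)
}

#' Classify a cohort under all three case definitions
#'
#' @param derived Output of [derive_measures()].
#' @return Data frame keyed by `id` with `primary_def`, `rv_augmented_def`,
#'   `stringent_def` status factors and the primary ascertainment `path`.
#' @examples
#' cohort <- simulate_cohort(500, seed = 1)
#' status <- classify_eph(derive_measures(cohort$data))
#' table(status$primary_def)
#' @export
classify_eph <- function(derived) {
  prim <- classify_primary(derived)
  str <- classify_stringent(derived)
  data.frame(
    id = derived$id,
    primary_def = prim$status,
    rv_augmented_def = classify_rv_augmented(prim$status, derived$rv_dilated),
    stringent_def = str$status,
    path = prim$path,
    stringsAsFactors = FALSE
  )
}
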