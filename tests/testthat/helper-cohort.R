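# Shared fixtures, all generated in code.

# a derived-measures table built directly (bypassing the generator) so the
# classifiers can be exercised on hand-chosen and adversarial inputs
make_derived <- function(epasp, gradient = epasp - 3, rap = 3,
                         trv_reason = "", rvedd = 33) {
  n <- max(lengths(list(epasp, gradient, trv_reason)))
  data.frame(
    id = seq_len(n),
    rap = rep_len(rap, n),
    gradient = rep_len(gradient, n),
    epasp = rep_len(epasp, n),
    fs = 40, lv_sys_dysfunction = FALSE,
    diastolic_stage = factor("normal_or_stage1",
                             levels = c("normal_or_stage1", "stage2",
                                        "stage3_4")),
    rv_dilated = rep_len(classify_rv_dilated(rvedd), n),
    trv = rep_len(ifelse(is.na(gradient), NA_real_, sqrt(gradient / 4)), n),
    trv_reason = rep_len(trv_reason, n),
    rvedd = rep_len(rvedd, n),
    stringsAsFactors = FALSE
  )
}

# a random derived table covering the full missingness/threshold space
random_derived <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trv <- runif(n, 0, 4.5)
  reason <- sample(c("", "jet_absent", "jet_too_small", "not_recorded"),
                   n, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.2))
  trv[reason != ""] <- NA
  rap <- sample(c(3, 8, 15, NA), n, replace = TRUE)
  gradient <- tricuspid_gradient(trv)
  rvedd <- ifelse(runif(n) < 0.1, NA, runif(n, 25, 50))
  data.frame(
    id = seq_len(n), rap = rap, gradient = gradient,
    epasp = compute_epasp(gradient, rap),
    fs = 40, lv_sys_dysfunction = FALSE,
    diastolic_stage = factor("normal_or_stage1",
                             levels = c("normal_or_stage1", "stage2",
                                        "stage3_4")),
    rv_dilated = classify_rv_dilated(rvedd),
    trv = trv, trv_reason = reason, rvedd = rvedd,
    stringsAsFactors = FALSE
  )
}

# small fully-observed analysis table (no masking applied)
complete_analysis_table <- function(n, seed = 1) {
  ch <- simulate_cohort(n, seed = seed)
  build_analysis_table(ch$data, derive_measures(ch$data))
}

case_ids <- function(status) status$id[status$primary_def == "case"]
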