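#' Age bands and BMI split used in the subgroup tables
#' @param age Numeric age in years.
#' @return Factor with 5-year bands from 65 (open-ended above 85).
#' @export
age_bands <- function(age) {
  cut(age, breaks = c(65, 70, 75, 80, 85, Inf), right = FALSE,
      labels = c("65 to 70", "70 to 75", "75 to 80", "80 to 85",
                 "85 or older"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> mask -> derive -> classify -> prevalence ->
#' regression and collects the four result tables: (1) included-versus-
#' excluded participant characteristics, (2) prevalence of echocardiographic
#' pulmonary hypertension overall and by subgroup under the primary
#' definition, (3) overall and by-sex prevalence under all three
#' definitions, (4) pooled model A / model B associations with ePASP. A
#' reproducibility manifest records the seeds, a configuration hash, stage
#' row counts and output-file checksums.
#'
#' @param n Cohort size to generate.
#' @param seed Integer master seed; the masking, imputation and any later
#'   draws use seeds derived from it.
#' @param config Generator configuration, see [eph_config()].
#' @param m Number of imputations for the regression stage.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as CSV alongside `manifest.json` and a plain-text report.
#' @param subgroup_covariates Use `"imputed"` covariates (first completed
#'   copy; the default, matching covariate imputation before analysis) or
#'   `"complete_case"` grouping in the subgroup table.
#' @return Object of class `eph_report`: list with `tables` (named list
#'   `characteristics`, `prevalence_subgroups`, `prevalence_definitions`,
#'   `associations`), `fit` (the [epasp_models()] object), `manifest`,
#'   `cohort`, `status`.
#' @examples
#' \donttest{
#' rep <- run_eph_pipeline(n = 2000, seed = 11, m = 3)
#' rep$manifest$counts
#' }
#' @export
run_eph_pipeline <- function(n = 3381, seed = 1, config = eph_config(),
                             m = 5L, out_dir = NULL,
                             subgroup_covariates = c("imputed",
                                                     "complete_case")) {
  subgroup_covariates <- match.arg(subgroup_covariates)
  cohort <- simulate_cohort(n, seed = seed, config = config)
  masked <- apply_missingness(cohort, seed = seed + 1L)
  derived <- derive_measures(masked$data)
  status <- classify_eph(derived)
  analysis <- build_analysis_table(masked$data, derived)

  fit <- epasp_models(analysis, m = m, seed = seed + 2L)
  grouping <- if (subgroup_covariates == "imputed") {
    fit$imputed$imputations[[1]]
  } else {
    analysis
  }

  included <- status$primary_def != "excluded"
  characteristics <- compare_populations(
    cbind(analysis[included, c("age", "bmi", "smoking", "copd", "diabetes",
                               "hypertension", "fs", "rap", "rvedd")],
          sex = analysis$sex[included],
          diastolic_stage = analysis$diastolic_stage[included]),
    cbind(analysis[!included, c("age", "bmi", "smoking", "copd", "diabetes",
                                "hypertension", "fs", "rap", "rvedd")],
          sex = analysis$sex[!included],
          diastolic_stage = analysis$diastolic_stage[!included])
  )

  groups <- list(
    overall = factor(rep("overall", nrow(grouping))),
    sex = grouping$sex,
    age = age_bands(grouping$age),
    smoking = grouping$smoking,
    bmi = factor(ifelse(grouping$bmi < 25, "< 25 kg/m2", ">= 25 kg/m2"),
                 levels = c("< 25 kg/m2", ">= 25 kg/m2")),
    copd = factor(ifelse(grouping$copd, "yes", "no"), c("yes", "no")),
    hypertension = factor(ifelse(grouping$hypertension, "yes", "no"),
                          c("yes", "no")),
    diabetes = factor(ifelse(grouping$diabetes, "yes", "no"), c("yes", "no")),
    lv_systolic_dysfunction = factor(ifelse(grouping$fs < 29, "yes", "no"),
                                     c("yes", "no")),
    lv_diastolic_dysfunction = grouping$diastolic_stage
  )
  prevalence_subgroups <- do.call(rbind, lapply(names(groups), function(g) {
    tab <- subgroup_prevalence(status$primary_def, groups[[g]])
    cbind(grouping = g, as.data.frame(tab))
  }))

  prevalence_definitions <- do.call(rbind, lapply(
    c("primary_def", "rv_augmented_def", "stringent_def"),
    function(def) {
      overall <- as.data.frame(wald_ci(sum(status[[def]] == "case"),
                                       sum(status[[def]] != "excluded")))
      overall$p_value <- NA_real_
      by_sex <- as.data.frame(subgroup_prevalence(status[[def]],
                                                  grouping$sex))
      rbind(
        cbind(definition = def, group = "overall", overall),
        cbind(definition = def, group = as.character(by_sex$level),
              subset(by_sex, select = -level))
      )
    }
  ))

  associations <- .association_table(fit)

  counts <- list(
    generated = n,
    excluded_no_tr_data = sum(status$path == "no_tr_data"),
    analysis_set = sum(included),
    epasp_estimable = sum(status$path == "epasp_measured"),
    trv_fallback = sum(status$path == "trv_fallback"),
    assumed_noncase = sum(status$path == "assumed_noncase")
  )
  manifest <- list(
    seed = seed,
    derived_seeds = c(masking = seed + 1L, imputation = seed + 2L),
    m = m,
    counts = counts,
    config_hash = .config_hash(config),
    created = "run_eph_pipeline",
    package_version = as.character(utils::packageVersion("ephcohort"))
  )

  tables <- list(
    characteristics = characteristics,
    prevalence_subgroups = prevalence_subgroups,
    prevalence_definitions = prevalence_definitions,
    associations = associations
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      cohort = "cohort.csv", truth = "truth.csv", derived = "derived.csv",
      status = "status.csv", table1 = "table1.csv", table2 = "table2.csv",
      table3 = "table3.csv", table4 = "table4.csv"
    )
    write_cohort(masked$data, file.path(out_dir, files["cohort"]))
    write_cohort(masked$truth, file.path(out_dir, files["truth"]))
    write_cohort(derived, file.path(out_dir, files["derived"]))
    write_cohort(status, file.path(out_dir, files["status"]))
    write_cohort(characteristics, file.path(out_dir, files["table1"]))
    write_cohort(prevalence_subgroups, file.path(out_dir, files["table2"]))
    write_cohort(prevalence_definitions, file.path(out_dir, files["table3"]))
    write_cohort(associations, file.path(out_dir, files["table4"]))
    manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(.render_report(tables, counts),
               file.path(out_dir, "report.txt"))
  }

  structure(list(tables = tables, fit = fit, manifest = manifest,
                 cohort = masked, derived = derived, status = status),
            class = "eph_report")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.association_table <- function(fit) {
  a <- do.call(rbind, lapply(fit$model_a, function(f) f$table))
  a$model <- "A"
  b <- fit$model_b$table
  b$model <- "B"
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}

.render_report <- function(tables, counts) {
  c(
    "Echocardiographic pulmonary hypertension: synthetic-cohort analysis",
    "",
    sprintf("Generated: %d; excluded (no TR data): %d; analysis set: %d",
            counts$generated, counts$excluded_no_tr_data,
            counts$analysis_set),
    sprintf("  ePASP estimable: %d; TRV fallback: %d; assumed non-case: %d",
            counts$epasp_estimable, counts$trv_fallback,
            counts$assumed_noncase),
    "",
    "Prevalence by definition (overall):",
    vapply(unique(tables$prevalence_definitions$definition), function(def) {
      r <- tables$prevalence_definitions
      r <- r[r$definition == def & r$group == "overall", ][1, ]
      sprintf("  %-18s %s%% (%s; %s)  [%d/%d]", def, fmt_pct1(r$p),
              fmt_pct1(r$ci_low), fmt_pct1(r$ci_high), r$k, r$n)
    }, ""),
    "",
    "Model B associations with ePASP (mmHg):",
    {
      b <- tables$associations
      b <- b[b$model == "B", ]
      sprintf("  %-28s %6.2f (%.2f; %.2f)  p=%s", b$term, b$estimate,
              b$ci_low, b$ci_high, format(signif(b$p_value, 2)))
    }
  )
}

#' @export
print.eph_report <- function(x, ...) {
  writeLines(.render_report(x$tables, x$manifest$counts))
  invisible(x)
}
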