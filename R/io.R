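#' Cohort column dictionary
#'
#' The shipped dictionary of cohort columns: name, type, unit, allowed
#' range and (for categoricals) allowed levels. [read_cohort()] validates
#' incoming files against it and refuses silently ambiguous columns.
#'
#' @return Data frame, one row per column.
#' @export
cohort_dictionary <- function() {
  path <- system.file("extdata", "column_dictionary.csv",
                      package = "ephcohort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a cohort CSV
#'
#' One row per participant. Every required dictionary column must be
#' present under its exact name; unknown columns are an error (a renamed or
#' re-unit-ed column must not pass silently). Numeric columns are range-
#' checked against the dictionary and categorical columns against the
#' allowed levels; violations name the column and offending rows. Empty
#' cells are missing values; missing TRV must carry a `trv_reason`.
#'
#' @param file Path to a CSV in the [cohort_dictionary()] layout.
#' @param strict Error on unknown columns (default `TRUE`).
#' @return Validated data frame with categorical columns as factors.
#' @export
read_cohort <- function(file, strict = TRUE) {
  dict <- cohort_dictionary()
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  missing_cols <- setdiff(dict$column[dict$required], names(raw))
  if (length(missing_cols)) {
    stop_ephcohort("cohort file lacks required columns: ",
                   paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), dict$column)
  if (length(extra) && strict) {
    stop_ephcohort("unknown columns (units cannot be validated): ",
                   paste(extra, collapse = ", "))
  }
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (!col %in% names(raw)) next
    x <- raw[[col]]
    type <- dict$type[i]
    if (type %in% c("numeric", "integer")) {
      if (!is.numeric(x)) {
        stop_ephcohort(sprintf("column %s must be numeric (%s)", col,
                               dict$unit[i]))
      }
      if (!is.na(dict$min[i])) chk_range(x, dict$min[i], dict$max[i], col)
    } else if (type == "logical") {
      if (is.numeric(x)) x <- x != 0
      if (is.character(x)) x <- toupper(x) %in% c("TRUE", "T", "1", "YES")
      raw[[col]] <- as.logical(x)
    } else if (type == "categorical") {
      levs <- strsplit(dict$levels[i], "|", fixed = TRUE)[[1]]
      x_chr <- as.character(x)
      if (col == "trv_reason") x_chr[is.na(x_chr)] <- ""
      bad <- which(!is.na(x_chr) & !x_chr %in% levs)
      if (length(bad)) {
        stop_ephcohort(sprintf(
          "column %s has values outside {%s} at rows: %s", col,
          paste(levs, collapse = ", "),
          paste(utils::head(bad, 5L), collapse = ", ")
        ))
      }
      raw[[col]] <- if (col == "trv_reason") x_chr
                    else factor(x_chr, levels = levs)
    }
  }
  raw
}

#' Write a cohort (or any pipeline table) to CSV
#'
#' @param x Data frame.
#' @param file Output path.
#' @export
write_cohort <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Assemble the analysis table from covariates and derived measures
#'
#' Joins the participant covariates to the derived echo measures by `id`
#' and applies last observation carried forward to smoking and COPD from
#' the prior-visit columns. The result is the input of [impute_cohort()]
#' and the regression models.
#'
#' @param cohort Participant table (covariates, prior-visit columns).
#' @param derived Output of [derive_measures()].
#' @return Data frame with covariates, `fs`, `diastolic_stage`, `epasp`
#'   and the never-imputed predictors `trv`, `rap`, `rvedd`.
#' @export
build_analysis_table <- function(cohort, derived) {
  stopifnot(all(cohort$id == derived$id))
  out <- data.frame(
    id = cohort$id,
    age = cohort$age,
    sex = cohort$sex,
    bmi = cohort$bmi,
    smoking = locf(cohort$smoking, cohort$prior_smoking),
    copd = locf(cohort$copd, cohort$prior_copd),
    diabetes = cohort$diabetes,
    hypertension = cohort$hypertension,
    fs = derived$fs,
    diastolic_stage = derived$diastolic_stage,
    epasp = derived$epasp,
    gradient = derived$gradient,
    trv = derived$trv,
    rap = derived$rap,
    rvedd = derived$rvedd,
    stringsAsFactors = FALSE
  )
  out
}
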