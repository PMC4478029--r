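#' Reporting scales for ePASP regression covariates
#'
#' Effects are reported on conventional clinical scales: age per 10 years,
#' BMI per 5 kg/m2 and fractional shortening per 10 percentage points; all
#' other covariates per unit or per level. Fits run on raw scales and the
#' multiplier is applied deterministically to estimates and standard errors
#' afterwards, so the scale never affects fitting.
#'
#' @return Data frame with `covariate`, `multiplier`, `label`.
#' @export
covariate_scales <- function() {
  data.frame(
    covariate = c("age", "bmi", "fs"),
    multiplier = c(10, 5, 10),
    label = c("Age, per 10 years", "Body mass index, per 5 kg/m2",
              "LV fractional shortening, per 10%"),
    stringsAsFactors = FALSE
  )
}

.scale_for <- function(covariate) {
  sc <- covariate_scales()
  i <- match(covariate, sc$covariate)
  if (is.na(i)) 1 else sc$multiplier[i]
}

.fit_one <- function(dat, rhs) {
  stats::lm(stats::reformulate(rhs, response = "epasp"), data = dat)
}

# coefficient indices of the columns belonging to one model term
.term_cols <- function(fit, covariate) {
  labs <- attr(stats::terms(fit), "term.labels")
  idx <- which(labs == covariate)
  if (!length(idx)) stop_ephcohort("term not in model: ", covariate)
  which(attr(stats::model.matrix(fit), "assign") == idx)
}

# pool one covariate's coefficient block across a list of lm fits
.pool_block <- function(fits, covariate, level = 0.95) {
  cols <- .term_cols(fits[[1]], covariate)
  mult <- .scale_for(covariate)
  grab <- function(fun) {
    v <- vapply(fits, fun, numeric(length(cols)))
    if (length(cols) == 1L) matrix(v, ncol = 1L) else t(v)
  }
  est <- grab(function(f) stats::coef(f)[cols])
  vars <- grab(function(f) diag(stats::vcov(f))[cols, drop = FALSE])
  df_com <- fits[[1]]$df.residual
  pooled <- rubin_pool(est * mult, vars * mult^2, df_com = df_com)
  alpha <- 1 - level
  tq <- stats::qt(1 - alpha / 2, df = pooled$df)
  pooled$ci_low <- pooled$estimate - tq * pooled$se
  pooled$ci_high <- pooled$estimate + tq * pooled$se
  pooled$term <- names(stats::coef(fits[[1]]))[cols]
  pooled$covariate <- covariate
  # omnibus p for the whole block (equals the t-test p when 1 df)
  if (length(cols) > 1L) {
    ob <- pool_wald_test(
      lapply(fits, function(f) stats::coef(f)[cols]),
      lapply(fits, function(f) stats::vcov(f)[cols, cols, drop = FALSE]),
      df_com = df_com
    )
    pooled$p_block <- ob$p_value
  } else {
    pooled$p_block <- pooled$p_value
  }
  rownames(pooled) <- NULL
  pooled[, c("covariate", "term", "estimate", "se", "df",
             "ci_low", "ci_high", "p_value", "p_block", "riv")]
}

# restrict each completed copy to rows with an estimable outcome and fit
.fit_per_imputation <- function(imputed, rhs) {
  lapply(imputed$imputations, function(dat) {
    .fit_one(dat[!is.na(dat$epasp), , drop = FALSE], rhs)
  })
}

#' Age/sex-adjusted association of one factor with ePASP (model A)
#'
#' Linear regression of ePASP on the covariate plus age and sex, fitted on
#' each completed copy of the analysis set restricted to participants with
#' an estimable ePASP (the outcome is never imputed), then pooled with
#' Rubin's rules. When the covariate is age or sex itself, the adjustment
#' set degenerates to the other of the two (no duplicated term).
#'
#' @param imputed An [impute_cohort()] result.
#' @param covariate Covariate name in the analysis table.
#' @param level Confidence level.
#' @return Object of class `eph_mifit` (see [fit_model_b()]); for a factor
#'   covariate one row per non-reference level plus a block-level omnibus
#'   p-value.
#' @export
fit_model_a <- function(imputed, covariate, level = 0.95) {
  stopifnot(inherits(imputed, "eph_imputed"))
  dat1 <- imputed$imputations[[1]]
  x1 <- dat1[[covariate]]
  if (is.null(x1)) stop_ephcohort("unknown covariate: ", covariate)
  if (length(unique(x1[!is.na(x1)])) < 2L) {
    stop_ephcohort("constant covariate: ", covariate)
  }
  rhs <- unique(c(covariate, "age", "sex"))
  fits <- .fit_per_imputation(imputed, rhs)
  tab <- .pool_block(fits, covariate, level = level)
  structure(
    list(table = tab, model = "A", covariates = covariate,
         adjusted_for = setdiff(rhs, covariate),
         m = imputed$m, n = sum(!is.na(dat1$epasp)), level = level),
    class = "eph_mifit"
  )
}

#' Multivariable ePASP model from the model-A screen (model B)
#'
#' Fits the single multivariable model containing exactly the covariates
#' whose model-A (block) p-value is below the selection threshold, entered
#' simultaneously, pooled over imputations. Selection uses unrounded pooled
#' p-values with a strict `<` comparison.
#'
#' @param imputed An [impute_cohort()] result.
#' @param model_a_results Named list of model-A `eph_mifit` objects (e.g.
#'   from [epasp_models()]), or a named numeric vector of selection
#'   p-values.
#' @param p_select Selection threshold (default 0.05, strict).
#' @param level Confidence level.
#' @return Object of class `eph_mifit`: list with the pooled coefficient
#'   `table` (columns `covariate`, `term`, `estimate`, `se`, `df`,
#'   `ci_low`, `ci_high`, `p_value`, `p_block`, `riv`), the selected
#'   `covariates`, `m` and the analysis `n`. Reference levels of factors
#'   carry no row.
#' @export
fit_model_b <- function(imputed, model_a_results, p_select = 0.05,
                        level = 0.95) {
  stopifnot(inherits(imputed, "eph_imputed"))
  pvals <- if (is.numeric(model_a_results)) {
    model_a_results
  } else {
    vapply(model_a_results, function(f) f$table$p_block[1L], numeric(1L))
  }
  if (is.null(names(pvals)) || any(!nzchar(names(pvals)))) {
    stop_ephcohort("model_a_results must be named by covariate")
  }
  selected <- names(pvals)[!is.na(pvals) & pvals < p_select]
  if (!length(selected)) {
    stop_ephcohort("no covariate passed the model-A screen (p < ",
                   p_select, ")")
  }
  fits <- .fit_per_imputation(imputed, selected)
  tab <- do.call(rbind, lapply(selected, function(v) {
    .pool_block(fits, v, level = level)
  }))
  structure(
    list(table = tab, model = "B", covariates = selected,
         selection_p = pvals, p_select = p_select,
         m = imputed$m, n = sum(!is.na(imputed$imputations[[1]]$epasp)),
         level = level),
    class = "eph_mifit"
  )
}

#' @export
coef.eph_mifit <- function(object, ...) {
  stats::setNames(object$table$estimate, object$table$term)
}

#' @export
confint.eph_mifit <- function(object, parm, level = 0.95, ...) {
  tab <- object$table
  tq <- stats::qt(1 - (1 - level) / 2, df = tab$df)
  out <- cbind(tab$estimate - tq * tab$se, tab$estimate + tq * tab$se)
  dimnames(out) <- list(tab$term,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.eph_mifit <- function(x, digits = 2, ...) {
  cat(sprintf("Pooled linear model %s for ePASP (mmHg), n = %d, m = %d\n",
              x$model, x$n, x$m))
  if (x$model == "A") {
    cat("Adjusted for:", paste(x$adjusted_for, collapse = " + "), "\n")
  } else {
    cat("Covariates (model-A screen, p <", format(x$p_select), "):",
        paste(x$covariates, collapse = ", "), "\n")
  }
  tab <- x$table
  show <- data.frame(
    term = tab$term,
    estimate = round(tab$estimate, digits),
    ci = sprintf("(%s; %s)", round(tab$ci_low, digits),
                 round(tab$ci_high, digits)),
    p = signif(tab$p_value, 2)
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.eph_mifit <- function(object, ...) object$table

#' Age/sex-screened and multivariable ePASP models, pooled over imputations
#'
#' The full association analysis in one call: model A (each candidate factor
#' adjusted for age and sex) for every candidate, then model B containing
#' the factors that passed the screen, entered simultaneously. Expects the
#' analysis table of [build_analysis_table()] or an existing
#' [impute_cohort()] result.
#'
#' @param data Analysis table (or an `eph_imputed` object, in which case
#'   `m` and `seed` are ignored).
#' @param candidates Candidate covariates for the screen.
#' @param m,seed Passed to [impute_cohort()].
#' @param p_select Model-A selection threshold, strict.
#' @param level Confidence level.
#' @return Object of class `epasp_models`: list with `model_a` (named list
#'   of `eph_mifit`), `model_b` (`eph_mifit`), `selected`, `imputed`.
#' @examples
#' cohort <- simulate_cohort(1500, seed = 7)
#' masked <- apply_missingness(cohort, seed = 8)
#' tab <- build_analysis_table(masked$data, derive_measures(masked$data))
#' fit <- epasp_models(tab, m = 5, seed = 9)
#' coef(fit$model_b)
#' @export
epasp_models <- function(data,
                         candidates = c("age", "sex", "bmi", "smoking",
                                        "fs", "diastolic_stage", "copd",
                                        "diabetes", "hypertension"),
                         m = 5L, seed = NULL, p_select = 0.05,
                         level = 0.95) {
  imputed <- if (inherits(data, "eph_imputed")) {
    data
  } else {
    impute_cohort(data, m = m, seed = seed)
  }
  model_a <- lapply(candidates, function(v) {
    fit_model_a(imputed, v, level = level)
  })
  names(model_a) <- candidates
  model_b <- fit_model_b(imputed, model_a, p_select = p_select,
                         level = level)
  structure(
    list(model_a = model_a, model_b = model_b,
         selected = model_b$covariates, imputed = imputed),
    class = "epasp_models"
  )
}

#' @export
print.epasp_models <- function(x, ...) {
  cat("ePASP association analysis (pooled over", x$model_b$m,
      "imputations)\n\nModel A screen (age/sex-adjusted):\n")
  pa <- vapply(x$model_a, function(f) f$table$p_block[1L], numeric(1L))
  for (v in names(pa)) {
    cat(sprintf("  %-16s p = %-8s%s\n", v, format(signif(pa[v], 2)),
                if (v %in% x$selected) " *" else ""))
  }
  cat("\n")
  print(x$model_b)
  invisible(x)
}
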