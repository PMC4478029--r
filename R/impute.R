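#' Last observation carried forward
#'
#' Replaces missing current values with the participant's prior-visit value
#' (used for smoking status and COPD). Observed current values are never
#' overwritten; rows missing at both visits stay missing and enter the
#' multiple-imputation step.
#'
#' @param current Vector of current-visit values (any type; `NA` = missing).
#' @param prior Vector of prior-visit values, same length and type.
#' @return Completed vector of the same type.
#' @examples
#' locf(c("never", NA, NA), c("former", "former", NA))
#' @export
locf <- function(current, prior) {
  if (length(current) != length(prior)) {
    stop_ephcohort("current and prior must have equal length")
  }
  take <- is.na(current) & !is.na(prior)
  if (is.factor(current)) {
    out <- as.character(current)
    out[take] <- as.character(prior)[take]
    factor(out, levels = levels(current))
  } else {
    current[take] <- prior[take]
    current
  }
}

# ---- chained-equations imputation with predictive mean matching ----------

# numeric working copy of a column for use on the predictor side
.num_code <- function(x) {
  if (is.numeric(x)) x
  else if (is.logical(x)) as.numeric(x)
  else as.numeric(as.integer(factor(x)))
}

# design matrix from the currently-completed predictors plus auxiliary
# variables; auxiliaries may themselves be missing and are entered as
# zero-filled values with a missingness indicator, so they inform the
# imputation model without ever being imputed
.imp_design <- function(data, predictors, aux) {
  cols <- lapply(predictors, function(v) .num_code(data[[v]]))
  names(cols) <- predictors
  X <- do.call(cbind, cols)
  for (v in aux) {
    a <- .num_code(data[[v]])
    ind <- as.numeric(is.na(a))
    a[is.na(a)] <- 0
    X <- cbind(X, a, ind)
    colnames(X)[ncol(X) - 1:0] <- c(v, paste0(v, "_missing"))
  }
  X <- cbind(`(Intercept)` = 1, X)
  # drop constant / collinear columns via a pivoted QR
  qrX <- qr(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

# one predictive-mean-matching draw for a single target variable
.pmm_draw <- function(y, X, miss, donors = 5L) {
  obs <- which(!miss)
  mis <- which(miss)
  yn <- .num_code(y)
  Xo <- X[obs, , drop = FALSE]
  fit <- stats::lm.fit(Xo, yn[obs])
  keep <- !is.na(fit$coefficients)
  Xo <- Xo[, keep, drop = FALSE]
  beta_hat <- fit$coefficients[keep]
  res <- fit$residuals
  df <- max(length(obs) - length(beta_hat), 1L)
  sigma2 <- sum(res^2) / df
  # Bayesian parameter draw (proper imputation): sigma2* then beta*
  sigma2_star <- sigma2 * df / stats::rchisq(1L, df)
  XtX <- crossprod(Xo)
  R <- tryCatch(chol(XtX), error = function(e) chol(XtX + diag(1e-8, ncol(XtX))))
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(length(beta_hat))) * sqrt(sigma2_star)
  # type-1 matching: beta_hat predictions for donors, beta_star for targets
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(X[mis, keep, drop = FALSE] %*% beta_star)
  k <- min(donors, length(obs))
  picks <- vapply(yhat_mis, function(t) {
    d <- abs(yhat_obs - t)
    cand <- order(d)[seq_len(k)]
    obs[cand[sample.int(k, 1L)]]
  }, integer(1L))
  out <- y
  out[mis] <- y[picks]  # donor values, so factors keep their levels
  out
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Produces `m` completed copies of the analysis table. Each incomplete
#' covariate is imputed in turn from all other covariates, cycling until the
#' chains settle; draws use predictive mean matching (nearest observed
#' donors on the Bayesian-drawn linear predictor), so imputed values are
#' always observed values, which works uniformly for continuous, binary and
#' ordered categorical covariates. The haemodynamic measurements (`trv`,
#' `rap`, `rvedd` by default) enter every imputation model as predictors but
#' are never imputed themselves; the outcome `epasp` is their deterministic
#' sum and is likewise never imputed.
#'
#' @param data Analysis table (see [build_analysis_table()]).
#' @param m Number of imputations (default 5).
#' @param seed Integer seed; identical seed and data give byte-identical
#'   output.
#' @param max_missing Per-covariate missingness cap as a proportion; a
#'   covariate above the cap aborts with an error naming it (default 0.06).
#' @param cycles Chained-equation cycles per imputation (default 5).
#' @param donors Donor pool size for predictive mean matching (default 5).
#' @param aux Names of predictor-only (never imputed) variables.
#' @param exclude Columns never imputed and never used as predictors
#'   (identifiers, outcome-side quantities).
#' @return Object of class `eph_imputed`: list with `imputations` (list of
#'   `m` completed data frames), `methods`, `m`, `seed`.
#' @export
impute_cohort <- function(data, m = 5L, seed = NULL, max_missing = 0.06,
                          cycles = 5L, donors = 5L,
                          aux = c("trv", "rap", "rvedd"),
                          exclude = c("id", "epasp", "gradient")) {
  stopifnot(is.data.frame(data), m >= 1L)
  if (!is.null(seed)) set.seed(seed)
  aux <- intersect(aux, names(data))
  exclude <- intersect(exclude, names(data))
  candidates <- setdiff(names(data), c(aux, exclude))
  frac <- vapply(data[candidates], function(x) mean(is.na(x)), numeric(1))
  over <- names(frac)[frac > max_missing]
  if (length(over)) {
    stop_ephcohort(sprintf(
      "missingness above the %.0f%% cap for: %s",
      100 * max_missing,
      paste(sprintf("%s (%.1f%%)", over, 100 * frac[over]), collapse = ", ")
    ))
  }
  targets <- names(frac)[frac > 0]
  miss_idx <- lapply(data[targets], is.na)

  one_imputation <- function() {
    filled <- data
    # initialise by random draws from the observed margin
    for (v in targets) {
      mi <- miss_idx[[v]]
      pool <- filled[[v]][!mi]
      filled[[v]][mi] <- pool[sample.int(length(pool), sum(mi),
                                         replace = TRUE)]
    }
    if (length(targets)) {
      for (cyc in seq_len(cycles)) {
        for (v in targets) {
          preds <- setdiff(candidates, v)
          X <- .imp_design(filled, preds, aux)
          filled[[v]] <- .pmm_draw(data[[v]], X, miss_idx[[v]],
                                   donors = donors)
        }
      }
    }
    filled
  }

  out <- list(
    imputations = lapply(seq_len(m), function(i) one_imputation()),
    methods = stats::setNames(rep("pmm", length(targets)), targets),
    m = as.integer(m),
    seed = seed,
    aux = aux
  )
  class(out) <- "eph_imputed"
  out
}

#' @export
print.eph_imputed <- function(x, ...) {
  cat(sprintf("Multiply-imputed analysis set: m = %d, %d row(s)\n",
              x$m, nrow(x$imputations[[1]])))
  if (length(x$methods)) {
    cat("Imputed (pmm):", paste(names(x$methods), collapse = ", "), "\n")
  } else {
    cat("No missing values; copies are identical.\n")
  }
  cat("Predictor-only:", paste(x$aux, collapse = ", "), "\n")
  invisible(x)
}
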