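#' Binomial prevalence with a Wald confidence interval
#'
#' Normal-approximation (Wald) interval, `p +/- z * sqrt(p (1 - p) / n)`,
#' with no continuity correction, truncated to `[0, 1]` and reported in
#' percent. Printed values use half-up rounding to one decimal so tabulated
#' triples are bit-reproducible.
#'
#' @param k Case count.
#' @param n Denominator (> 0).
#' @param level Confidence level, default 0.95.
#' @return A one-row data frame of class `eph_prevalence` with columns `k`,
#'   `n`, `p`, `ci_low`, `ci_high` (all percentages on the 0-100 scale,
#'   unrounded).
#' @examples
#' wald_ci(73, 2823)  # prints 2.6% (2.0; 3.2)
#' @export
wald_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop_ephcohort("k and n must be scalar and non-missing")
  }
  if (n <= 0) stop_ephcohort("denominator n must be positive")
  if (k < 0 || k > n) stop_ephcohort("k must lie in [0, n]")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  out <- data.frame(
    k = k, n = n,
    p = 100 * p,
    ci_low = 100 * max(0, p - half),
    ci_high = 100 * min(1, p + half)
  )
  class(out) <- c("eph_prevalence", "data.frame")
  out
}

#' @export
print.eph_prevalence <- function(x, ...) {
  cat(sprintf("%s%% (%s; %s)  [%d/%d]\n",
              fmt_pct1(x$p), fmt_pct1(x$ci_low), fmt_pct1(x$ci_high),
              x$k, x$n))
  invisible(x)
}

#' Prevalence by subgroup with a between-level test
#'
#' One Wald prevalence estimate per level of a grouping variable plus a
#' single Pearson chi-square p-value (no continuity correction) for the
#' difference across levels. Rows whose status is `excluded` or whose
#' grouping value is missing do not contribute; empty levels are dropped
#' with a warning.
#'
#' @param status Factor with levels case/noncase/excluded (one of the
#'   definition columns of [classify_eph()]).
#' @param group Grouping vector (factor or coercible); its level order is
#'   kept.
#' @param level Confidence level for the Wald intervals.
#' @return Data frame of class `eph_subgroup` with one row per non-empty
#'   level (`level`, `k`, `n`, `p`, `ci_low`, `ci_high`) and the omnibus
#'   `p_value` as an attribute (also a column, repeated).
#' @export
subgroup_prevalence <- function(status, group, level = 0.95) {
  if (length(status) != length(group)) {
    stop_ephcohort("status and group must have equal length")
  }
  g <- if (is.factor(group)) group else factor(group)
  keep <- status %in% c("case", "noncase") & !is.na(g)
  g <- droplevels(g[keep], exclude = NULL)
  case <- status[keep] == "case"

  empty <- setdiff(levels(if (is.factor(group)) group else factor(group)),
                   levels(g))
  if (length(empty)) {
    warning("empty subgroup level(s) omitted: ", paste(empty, collapse = ", "))
  }

  rows <- do.call(rbind, lapply(levels(g), function(lv) {
    sel <- g == lv
    est <- wald_ci(sum(case[sel]), sum(sel), level = level)
    cbind(level = lv, as.data.frame(est))
  }))
  tab <- table(g, factor(case, levels = c(FALSE, TRUE)))
  p_value <- if (nrow(tab) >= 2L && all(rowSums(tab) > 0)) {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    NA_real_
  }
  rows$p_value <- p_value
  attr(rows, "p_value") <- p_value
  class(rows) <- c("eph_subgroup", "data.frame")
  rows
}

#' Compare two populations characteristic by characteristic
#'
#' The inclusion/exclusion comparison table: per characteristic, mean (SD)
#' or level percentages in each group plus a p-value — Welch's two-sample
#' t-test for continuous variables, a Pearson chi-square omnibus test over
#' levels for categorical ones (a multi-level variable gets one p-value).
#' Characteristics that are all-missing in either group are omitted with a
#' warning.
#'
#' @param included,excluded Data frames sharing the compared columns.
#' @param vars Character vector of columns to compare; defaults to the
#'   intersection of the two tables (minus `id`).
#' @return Data frame with `variable`, `type`, group summaries and
#'   `p_value`.
#' @export
compare_populations <- function(included, excluded,
                                vars = setdiff(intersect(names(included),
                                                         names(excluded)),
                                               "id")) {
  one <- function(v) {
    x <- included[[v]]
    y <- excluded[[v]]
    if (all(is.na(x)) || all(is.na(y))) {
      warning("variable all-missing in a group, omitted: ", v)
      return(NULL)
    }
    if (is.numeric(x) && !is.logical(x)) {
      p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      data.frame(
        variable = v, type = "continuous",
        included = sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                           stats::sd(x, na.rm = TRUE)),
        excluded = sprintf("%.1f (%.1f)", mean(y, na.rm = TRUE),
                           stats::sd(y, na.rm = TRUE)),
        p_value = p, stringsAsFactors = FALSE
      )
    } else {
      xf <- factor(x)
      yf <- factor(y, levels = levels(xf))
      tab <- rbind(table(xf), table(yf))
      p <- if (ncol(tab) >= 2L) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else {
        NA_real_
      }
      pct <- function(t) paste(sprintf("%s %s%%", colnames(tab),
                                       fmt_pct1(100 * t / sum(t))),
                               collapse = ", ")
      data.frame(
        variable = v, type = "categorical",
        included = pct(tab[1, ]), excluded = pct(tab[2, ]),
        p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(vars, one)))
  rownames(out) <- NULL
  out
}
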