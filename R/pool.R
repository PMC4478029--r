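#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: the pooled
#' estimate is the mean of the estimates and the pooled variance is
#' `W + (1 + 1/m) B`, with `W` the mean within-imputation variance and `B`
#' the between-imputation variance. Degrees of freedom follow the
#' Barnard-Rubin small-sample adjustment; when the between component is
#' exactly zero (no missing data) the complete-data degrees of freedom are
#' used, so the pooled fit reproduces a single ordinary fit exactly.
#'
#' @param estimates Numeric matrix, one row per imputation, one column per
#'   parameter (a vector is taken as a one-parameter matrix).
#' @param variances Matrix of squared standard errors, same shape.
#' @param df_com Complete-data residual degrees of freedom (`Inf` allowed).
#' @return Data frame with `estimate`, `se`, `df`, `statistic`, `p_value`,
#'   `riv` (relative increase in variance) per parameter.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1L)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1L)
  stopifnot(all(dim(estimates) == dim(variances)))
  m <- nrow(estimates)
  if (m < 2L) stop_ephcohort("pooling requires m >= 2 fits")
  qbar <- colMeans(estimates)
  w <- colMeans(variances)
  b <- apply(estimates, 2L, stats::var)
  t_var <- w + (1 + 1 / m) * b
  se <- sqrt(t_var)
  riv <- (1 + 1 / m) * b / w
  lambda <- (1 + 1 / m) * b / t_var
  df <- vapply(seq_along(qbar), function(j) {
    if (b[j] <= .Machine$double.eps * max(w[j], 1)) return(df_com)
    nu_old <- (m - 1) / lambda[j]^2
    if (!is.finite(df_com)) return(nu_old)
    nu_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda[j])
    nu_old * nu_obs / (nu_old + nu_obs)
  }, numeric(1L))
  stat <- qbar / se
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  out <- data.frame(estimate = qbar, se = se, df = df,
                    statistic = stat, p_value = p, riv = riv)
  rownames(out) <- colnames(estimates)
  out
}

#' Pooled multi-parameter Wald test (D1)
#'
#' Omnibus test that a block of coefficients (e.g. all dummies of a factor)
#' is jointly zero, pooled over imputations with the Li-Raghunathan-Rubin
#' D1 statistic: the between-imputation variance enters through the average
#' relative increase in variance rather than a full pooled covariance.
#'
#' @param est_list List of length `m`; each element a numeric vector of the
#'   block's estimates for one imputation.
#' @param vcov_list List of the corresponding covariance blocks.
#' @param df_com Complete-data residual degrees of freedom.
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
pool_wald_test <- function(est_list, vcov_list, df_com = Inf) {
  m <- length(est_list)
  if (m < 2L) stop_ephcohort("pooling requires m >= 2 fits")
  k <- length(est_list[[1]])
  if (!all(vapply(est_list, length, 1L) == k)) {
    stop_ephcohort("mismatched model structures across imputations")
  }
  qbar <- Reduce(`+`, est_list) / m
  wbar <- Reduce(`+`, vcov_list) / m
  dev <- lapply(est_list, function(q) tcrossprod(q - qbar))
  b <- Reduce(`+`, dev) / (m - 1)
  winv <- solve(wbar)
  r <- (1 + 1 / m) * sum(diag(b %*% winv)) / k
  d1 <- drop(t(qbar) %*% winv %*% qbar) / (k * (1 + r))
  nu <- k * (m - 1)
  df2 <- if (r <= .Machine$double.eps) {
    df_com
  } else if (nu > 4) {
    4 + (nu - 4) * (1 + (1 - 2 / nu) / r)^2
  } else {
    nu * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  }
  if (is.finite(df_com)) df2 <- min(df2, df_com)
  p <- stats::pf(d1, k, df2, lower.tail = FALSE)
  list(statistic = d1, df1 = k, df2 = df2, p_value = p)
}
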