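test_that("carry-forward fills only what is missing", {
  cur <- factor(c(NA, "current", NA), levels = c("never", "former", "current"))
  pri <- factor(c("former", "never", NA), levels = levels(cur))
  got <- locf(cur, pri)
  expect_equal(as.character(got), c("former", "current", NA))
  expect_equal(locf(c(NA, TRUE, NA), c(FALSE, FALSE, NA)),
               c(FALSE, TRUE, NA))
})

test_that("a table with no missing values yields identical copies", {
  tab <- complete_analysis_table(300, seed = 41)
  imp <- impute_cohort(tab, m = 3, seed = 42)
  expect_length(imp$imputations, 3)
  for (k in 1:3) expect_identical(imp$imputations[[k]], tab)
})

test_that("imputation is reproducible and never touches observed cells", {
  tab <- complete_analysis_table(400, seed = 43)
  set.seed(44)
  tab$bmi[sample(400, 20)] <- NA
  tab$diabetes[sample(400, 15)] <- NA
  a <- impute_cohort(tab, m = 4, seed = 45)
  b <- impute_cohort(tab, m = 4, seed = 45)
  expect_identical(a$imputations, b$imputations)
  obs <- !is.na(tab$bmi)
  for (k in 1:4) {
    expect_identical(a$imputations[[k]]$bmi[obs], tab$bmi[obs])
    expect_false(anyNA(a$imputations[[k]]$bmi))
    expect_false(anyNA(a$imputations[[k]]$diabetes))
  }
  # copies differ between imputations where values were drawn
  expect_false(identical(a$imputations[[1]]$bmi, a$imputations[[2]]$bmi))
})

test_that("predictor-only haemodynamic variables are never imputed", {
  tab <- complete_analysis_table(300, seed = 46)
  tab$trv[1:40] <- NA
  tab$rap[1:30] <- NA
  tab$rvedd[1:25] <- NA
  tab$bmi[1:10] <- NA
  imp <- impute_cohort(tab, m = 2, seed = 47)
  for (k in 1:2) {
    expect_identical(is.na(imp$imputations[[k]]$trv), is.na(tab$trv))
    expect_identical(is.na(imp$imputations[[k]]$rap), is.na(tab$rap))
    expect_identical(is.na(imp$imputations[[k]]$rvedd), is.na(tab$rvedd))
  }
  expect_false("trv" %in% names(imp$methods))
})

test_that("the missingness cap rejects over-missing covariates by name", {
  tab <- complete_analysis_table(300, seed = 48)
  tab$bmi[1:40] <- NA  # > 6%
  expect_error(impute_cohort(tab, m = 2, seed = 49), "bmi")
})

test_that("MCAR-masked means are recovered within sampling error", {
  tab <- complete_analysis_table(3000, seed = 50)
  truth_mean <- mean(tab$bmi)
  set.seed(51)
  mask <- sample(3000, round(0.06 * 3000))
  masked <- tab
  masked$bmi[mask] <- NA
  imp <- impute_cohort(masked, m = 5, seed = 52)
  means <- vapply(imp$imputations, function(d) mean(d$bmi), numeric(1))
  se <- sd(tab$bmi) / sqrt(nrow(tab))
  expect_lt(abs(mean(means) - truth_mean), 2 * se)
})

test_that("Rubin pooling reproduces the worked arithmetic", {
  # identical fits: pooled equals the single fit, zero between-variance
  est <- matrix(rep(2.5, 4), ncol = 1)
  va <- matrix(rep(0.09, 4), ncol = 1)
  pooled <- rubin_pool(est, va, df_com = 100)
  expect_equal(pooled$estimate, 2.5)
  expect_equal(pooled$se, 0.3)
  expect_equal(pooled$df, 100)
  # m = 2, estimates {1, 3}, zero within: T = (1 + 1/2) * B = 1.5 * 2 = 3
  pooled <- rubin_pool(c(1, 3), c(0, 0))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$se^2, 3)
  # pooled variance never falls below the mean within-imputation variance
  set.seed(53)
  for (i in 1:20) {
    e <- rnorm(5)
    v <- runif(5, 0.5, 2)
    expect_gte(rubin_pool(e, v)$se^2, mean(v))
  }
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("pooled multi-parameter Wald test collapses when fits agree", {
  q <- c(0.5, -0.2)
  V <- diag(c(0.04, 0.09))
  res <- pool_wald_test(list(q, q, q), list(V, V, V), df_com = 200)
  expect_equal(res$df1, 2)
  expect_equal(res$statistic, drop(t(q) %*% solve(V) %*% q) / 2)
  expect_equal(res$df2, 200)
  expect_error(pool_wald_test(list(q, c(1, 2, 3)), list(V, V)),
               "mismatched")
})
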