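test_that("effects are reported on clinical scales", {
  tab <- complete_analysis_table(1200, seed = 61)
  imp <- impute_cohort(tab, m = 2, seed = 62)
  fit <- fit_model_a(imp, "age")
  raw <- lm(epasp ~ age + sex, data = tab[!is.na(tab$epasp), ])
  expect_equal(fit$table$estimate, 10 * unname(coef(raw)["age"]))
  expect_equal(fit$table$se, 10 * unname(sqrt(diag(vcov(raw))["age"])))
})

test_that("age and sex adjustment never duplicates the covariate", {
  tab <- complete_analysis_table(800, seed = 63)
  imp <- impute_cohort(tab, m = 2, seed = 64)
  fit <- fit_model_a(imp, "sex")
  expect_equal(fit$adjusted_for, "age")
  expect_equal(nrow(fit$table), 1)
  expect_error(fit_model_a(imp, "nope"), "unknown covariate")
  tab2 <- tab
  tab2$copd <- FALSE
  imp2 <- impute_cohort(tab2, m = 2, seed = 65)
  expect_error(fit_model_a(imp2, "copd"), "constant")
})

test_that("factor covariates get one row per level and an omnibus p", {
  tab <- complete_analysis_table(1000, seed = 66)
  imp <- impute_cohort(tab, m = 2, seed = 67)
  fit <- fit_model_a(imp, "diastolic_stage")
  expect_equal(nrow(fit$table), 2)  # reference level carries no row
  expect_equal(length(unique(fit$table$p_block)), 1)
  expect_true(all(fit$table$ci_low < fit$table$estimate))
  expect_true(all(fit$table$ci_high > fit$table$estimate))
})

test_that("model-B selection is strict on unrounded p-values", {
  tab <- complete_analysis_table(1500, seed = 68)
  imp <- impute_cohort(tab, m = 2, seed = 69)
  pv <- c(age = 0.001, smoking = 0.67, copd = 0.05, bmi = 0.0499999)
  fit <- fit_model_b(imp, pv)
  expect_setequal(fit$covariates, c("age", "bmi"))  # 0.05 itself is out
  expect_error(fit_model_b(imp, c(smoking = 0.67)), "screen")
})

test_that("null covariates are screened out and CIs cover zero", {
  set.seed(70)
  reps <- 500
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    n <- 250
    dat <- data.frame(
      epasp = rnorm(n, 26, 7),
      age = rnorm(n, 76, 6),
      sex = factor(sample(c("male", "female"), n, TRUE),
                   c("male", "female")),
      noise = rnorm(n)
    )
    imp <- structure(list(imputations = list(dat, dat), m = 2L,
                          methods = character(0), aux = character(0)),
                     class = "eph_imputed")
    fit <- fit_model_a(imp, "noise")
    covered[i] <- fit$table$ci_low <= 0 && fit$table$ci_high >= 0
  }
  expect_gte(mean(covered), 0.93)
})

test_that("full model fit recovers generating coefficients at modest n", {
  ch <- simulate_cohort(6000, seed = 71)
  masked <- apply_missingness(ch, seed = 72)
  tab <- build_analysis_table(masked$data, derive_measures(masked$data))
  fit <- epasp_models(tab, m = 5, seed = 73)
  b <- fit$model_b$table
  truth <- c(age = 2.2, diastolic_stagestage3_4 = 7.1, copdTRUE = 2.4)
  for (term in names(truth)) {
    row <- b[b$term == term, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$se)
  }
  expect_false("smoking" %in% fit$selected)  # generated with zero effect
})

test_that("pooled model-B estimates are unbiased over replicates", {
  # mean deviation from the generating coefficients over independent
  # cohorts, against its own Monte-Carlo standard error
  reps <- 200
  dev_age <- numeric(reps)
  dev_dd34 <- numeric(reps)
  se_age <- numeric(reps)
  se_dd34 <- numeric(reps)
  for (i in seq_len(reps)) {
    ch <- simulate_cohort(2000, seed = 8000 + i)
    masked <- apply_missingness(ch, seed = 9000 + i)
    tab <- build_analysis_table(masked$data, derive_measures(masked$data))
    imp <- impute_cohort(tab, m = 5, seed = 10000 + i)
    fit <- fit_model_b(imp, c(age = 0.001, sex = 0.001, bmi = 0.001,
                              fs = 0.001, diastolic_stage = 0.001,
                              copd = 0.001, diabetes = 0.001,
                              hypertension = 0.001))
    tb <- fit$table
    dev_age[i] <- tb$estimate[tb$term == "age"] - 2.2
    se_age[i] <- tb$se[tb$term == "age"]
    dev_dd34[i] <- tb$estimate[tb$term == "diastolic_stagestage3_4"] - 7.1
    se_dd34[i] <- tb$se[tb$term == "diastolic_stagestage3_4"]
  }
  expect_lt(abs(mean(dev_age)), 3 * sd(dev_age) / sqrt(reps))
  expect_lt(abs(mean(dev_dd34)), 3 * sd(dev_dd34) / sqrt(reps))
  # pooled SEs are on the Monte-Carlo scale of the estimator
  expect_lt(abs(mean(se_age) / sd(dev_age) - 1), 0.35)
  expect_lt(abs(mean(se_dd34) / sd(dev_dd34) - 1), 0.35)
})
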