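test_that("generation is deterministic given the seed", {
  a <- simulate_cohort(500, seed = 81)
  b <- simulate_cohort(500, seed = 81)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(500, seed = 82)
  expect_false(identical(a$data, c2$data))
  am <- apply_missingness(a, seed = 83)
  bm <- apply_missingness(b, seed = 83)
  expect_identical(am$data, bm$data)
})

test_that("visible data carry no ground-truth columns", {
  ch <- simulate_cohort(100, seed = 84)
  expect_false(any(c("epasp_true", "lp_true", "case_true") %in%
                     names(ch$data)))
  expect_identical(ch$truth$id, ch$data$id)
})

test_that("marginals match the configured population", {
  ch <- simulate_cohort(1e5, seed = 85)
  d <- ch$data
  expect_lt(abs(mean(d$age) - 76.4), 0.1)
  expect_lt(abs(sd(d$age) - 6.2), 0.1)
  expect_gte(min(d$age), 65)
  expect_lt(abs(mean(d$sex == "female") - 0.59), 0.01)
  expect_lt(abs(mean(d$bmi) - 27.2), 0.1)
  expect_lt(abs(mean(d$copd) - 0.104), 0.005)
  # three-point RAP distribution: mean 3.89, sd 2.31 in closed form
  rap <- ch$truth$rap_true
  expect_lt(abs(mean(rap) - (0.85 * 3 + 0.13 * 8 + 0.02 * 15)), 0.05)
  expect_lt(abs(sd(rap) - 2.3096), 0.05)
  expect_setequal(unique(rap), c(3, 8, 15))
})

test_that("degenerate generator collapses to the intercept", {
  cfg <- eph_config(
    effects = list(age = 0, women = 0, bmi = 0, fs = 0, dd_stage2 = 0,
                   dd_stage34 = 0, copd = 0, diabetes = 0,
                   hypertension = 0, intercept = 30),
    residual = list(sd = 0, skew = FALSE)
  )
  ch <- simulate_cohort(200, seed = 86, config = cfg)
  expect_true(all(ch$truth$epasp_true == 30))
})

test_that("derivation round-trips the generated truth exactly", {
  ch <- simulate_cohort(2000, seed = 87)
  d <- derive_measures(ch$data)
  expect_equal(d$epasp, ch$truth$epasp_true, tolerance = 1e-12)
  expect_equal(d$rap, ch$truth$rap_true)
  # the emitted mitral pattern reproduces the assigned diastolic stage
  expect_equal(as.character(d$diastolic_stage),
               as.character(ch$truth$dd_true))
})

test_that("masking reproduces the observed missingness rates", {
  n <- 3381 * 8  # several cohorts' worth to tighten binomial noise
  ch <- simulate_cohort(n, seed = 88)
  m <- apply_missingness(ch, seed = 89)
  no_tr <- m$data$trv_reason == "not_recorded"
  expect_lt(abs(mean(no_tr) - 558 / 3381), 4 * sqrt(0.165 * 0.835 / n))
  jet <- m$data$trv_reason %in% c("jet_absent", "jet_too_small")
  rate_jet <- sum(jet) / sum(!no_tr)
  expect_lt(abs(rate_jet - 670 / 2823),
            4 * sqrt(0.237 * 0.763 / sum(!no_tr)))
  # TRV measured but RAP unavailable, as a share of the analysis set
  fallback <- !is.na(m$data$trv) & is.na(m$data$ivc_diameter)
  expect_lt(abs(sum(fallback) / sum(!no_tr) - 208 / 2823),
            4 * sqrt(0.074 * 0.926 / sum(!no_tr)))
})

test_that("jet unmeasurability is informative about true pressure", {
  ch <- simulate_cohort(30000, seed = 90)
  m <- apply_missingness(ch, seed = 91)
  jet <- m$data$trv_reason %in% c("jet_absent", "jet_too_small")
  measured <- !is.na(m$data$trv)
  expect_lt(mean(ch$truth$epasp_true[jet]),
            mean(ch$truth$epasp_true[measured]) - 0.5)
  # with zero steepness the masking is carried completely at random
  cfg0 <- eph_config(missingness = list(trv_mask_steepness = 0))
  ch0 <- simulate_cohort(30000, seed = 92, config = cfg0)
  m0 <- apply_missingness(ch0, seed = 93)
  jet0 <- m0$data$trv_reason %in% c("jet_absent", "jet_too_small")
  measured0 <- !is.na(m0$data$trv)
  expect_lt(abs(mean(ch0$truth$epasp_true[jet0]) -
                  mean(ch0$truth$epasp_true[measured0])), 0.3)
})

test_that("age gradient in prevalence emerges from the effect structure", {
  ch <- simulate_cohort(80000, seed = 94)
  m <- apply_missingness(ch, seed = 95)
  st <- classify_eph(derive_measures(m$data))
  tab <- subgroup_prevalence(st$primary_def, age_bands(m$data$age))
  expect_equal(nrow(tab), 5)
  # oldest band clearly above youngest; profile close to monotone
  expect_gt(tab$p[5], 2 * tab$p[1])
  expect_true(all(diff(tab$p) > -0.4))
  expect_lt(tab$p_value[1], 0.001)
})

test_that("invalid configurations are rejected", {
  expect_error(eph_config(rap_p = c(`3` = 0.5, `8` = 0.5, `15` = 0.2)),
               "sum to 1")
  expect_error(eph_config(marginals = list(p_women = 1.2)), "\\[0, 1\\]")
  expect_error(eph_config(bogus = 1), "unknown config")
})
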