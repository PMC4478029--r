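test_that("RAP follows the guideline IVC rule including boundaries", {
  expect_equal(estimate_rap(18, 0.70), 3)
  expect_equal(estimate_rap(25, 0.30), 15)
  expect_equal(estimate_rap(25, 0.70), 8)
  # both strict inequalities fail at the exact boundary -> intermediate
  expect_equal(estimate_rap(21, 0.50), 8)
  expect_equal(estimate_rap(21, 0.51), 3)
  expect_equal(estimate_rap(21.01, 0.49), 15)
  expect_true(is.na(estimate_rap(NA, 0.7)))
  expect_true(is.na(estimate_rap(20, NA)))
  expect_error(estimate_rap(20, 1.2), "ivc_collapse")
})

test_that("RAP rule is total on its decision grid with values {3, 8, 15}", {
  grid <- expand.grid(d = seq(5, 35, by = 0.25), c = seq(0, 1, by = 0.025))
  rap <- estimate_rap(grid$d, grid$c)
  expect_false(anyNA(rap))
  expect_setequal(unique(rap), c(3, 8, 15))
  # each cell maps to exactly one value: re-evaluation is identical
  expect_identical(rap, estimate_rap(grid$d, grid$c))
})

test_that("tricuspid gradient is the simplified Bernoulli equation", {
  expect_equal(tricuspid_gradient(3.0), 36)
  expect_equal(tricuspid_gradient(3.4), 46.24)
  expect_equal(round_half_up(tricuspid_gradient(3.4)), 46)
  expect_equal(tricuspid_gradient(0), 0)
  expect_true(is.na(tricuspid_gradient(NA)))
  v <- seq(0.1, 6, by = 0.1)
  expect_true(all(diff(tricuspid_gradient(v)) > 0))
})

test_that("ePASP is gradient plus RAP and reproduces 4 t^2 + r exactly", {
  expect_equal(compute_epasp(36, 3), 39)
  expect_true(is.na(compute_epasp(36, NA)))
  expect_equal(compute_epasp(46.24, 8), 54.24)
  for (r in c(3, 8, 15)) {
    t <- seq(0, 6, by = 0.05)
    expect_identical(compute_epasp(tricuspid_gradient(t), r), 4 * t^2 + r)
  }
})

test_that("fractional shortening formula and consistency guard", {
  expect_equal(fractional_shortening(50, 30), 40)
  expect_equal(fractional_shortening(50, 50), 0)
  expect_equal(fractional_shortening(40, 28.4), 29)
  expect_error(fractional_shortening(40, 41), "inconsistent")
  expect_true(is.na(fractional_shortening(c(50, NA), c(30, 20))[2]))
})

test_that("LV systolic dysfunction cut is strict at 29%", {
  expect_true(classify_lv_systolic(28.9))
  expect_false(classify_lv_systolic(29.0))
  expect_false(classify_lv_systolic(41.1))
  expect_true(is.na(classify_lv_systolic(NA)))
})

test_that("RV dilation cut is strict at 42 mm", {
  expect_true(classify_rv_dilated(43))
  expect_false(classify_rv_dilated(42))
  expect_false(classify_rv_dilated(33.0))
  expect_true(is.na(classify_rv_dilated(NA)))
})

# independent re-statement of the default staging decision table, coded as
# plain nested conditionals; the vectorised implementation must agree on a
# grid that covers every branch
oracle_stage <- function(e, a, ep, dt, af, th = diastolic_thresholds()) {
  elevated <- (100 * e / ep > th$e_over_eprime) || (ep < th$eprime_low)
  if (!af) {
    ea <- e / a
    if (ea > th$ea_high) return("stage3_4")
    if (ea < th$ea_low) return("normal_or_stage1")
    if (elevated) "stage2" else "normal_or_stage1"
  } else {
    if (dt < th$dt_low) return("stage3_4")
    if (dt > th$dt_high) return("normal_or_stage1")
    if (elevated) "stage2" else "normal_or_stage1"
  }
}

test_that("diastolic staging matches the decision table on a full grid", {
  grid <- expand.grid(
    e = c(0.4, 0.8, 1.2), a = c(0.3, 0.8, 1.2, 1.6),
    ep = c(5, 7.9, 8, 10, 14), dt = c(100, 140, 180, 220, 260),
    af = c(FALSE, TRUE)
  )
  got <- stage_diastolic(grid$e, grid$a, grid$ep, grid$dt, grid$af)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    oracle_stage(grid$e[i], grid$a[i], grid$ep[i], grid$dt[i], grid$af[i])
  }, "")
  expect_false(anyNA(got))  # complete inputs always stage (partition)
  expect_equal(as.character(got), want)
})

test_that("staging handles the AF branch without the A wave", {
  # missing a_peak with a deceleration time present is a valid AF stage
  expect_equal(as.character(stage_diastolic(1.0, NA, 9, 250, TRUE)),
               "normal_or_stage1")
  # the AF branch never reads a_peak: absurd A gives the same answer
  expect_equal(stage_diastolic(1.0, 999, 9, 120, TRUE),
               stage_diastolic(1.0, NA, 9, 120, TRUE))
  # non-AF without an E/A ratio cannot be staged
  expect_true(is.na(stage_diastolic(1.0, NA, 9, 250, FALSE)))
  # AF without a deceleration time cannot be staged
  expect_true(is.na(stage_diastolic(1.0, NA, 9, NA, TRUE)))
})

test_that("staging in normal ranges is normal under any threshold set", {
  th <- diastolic_thresholds(ea_low = 0.9, ea_high = 1.8,
                             e_over_eprime = 12, eprime_low = 7)
  expect_equal(as.character(stage_diastolic(1.0, 1.0, 10, 200, FALSE, th)),
               "normal_or_stage1")
})

test_that("derive_measures carries missingness and validates reasons", {
  ch <- simulate_cohort(200, seed = 21)
  d <- derive_measures(ch$data)
  expect_equal(nrow(d), 200)
  expect_false(anyNA(d$epasp))
  bad <- ch$data
  bad$trv[1] <- NA  # no reason given
  expect_error(derive_measures(bad), "reason")
  ok <- ch$data
  ok$trv[1] <- NA
  ok$trv_reason[1] <- "jet_too_small"
  d2 <- derive_measures(ok)
  expect_true(is.na(d2$epasp[1]) && is.na(d2$gradient[1]))
  expect_false(is.na(d2$rap[1]))
})
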