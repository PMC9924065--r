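# Cohort generation, eligibility rules, error models, assay censoring.

test_that("eligibility rules match the selection table", {
  e <- eligible_for_cpg2(60, 22)
  expect_true(e$eligible)
  expect_match(e$rule, "50 umol/L")
  e2 <- eligible_for_cpg2(1.5, 40, arf = TRUE)
  expect_true(e2$eligible)
  expect_match(e2$rule, ">=1 umol/L")
  # below every applicable threshold
  expect_false(eligible_for_cpg2(0.05, 70, arf = FALSE,
                                 mtx_dose_g_per_m2 = 2)$eligible)
  # 70-h rules are stratified by dose intensity
  expect_true(eligible_for_cpg2(0.2, 72, mtx_dose_g_per_m2 = 2)$eligible)
  expect_false(eligible_for_cpg2(0.2, 72, mtx_dose_g_per_m2 = 5)$eligible)
  expect_true(eligible_for_cpg2(0.35, 72, mtx_dose_g_per_m2 = 5)$eligible)
  # concentration alone is not enough before the stated hour
  expect_false(eligible_for_cpg2(60, 10)$eligible)
})

test_that("acute renal failure criteria follow the footnote definition", {
  expect_true(acute_renal_failure(ccr_or_gfr = 60))
  expect_false(acute_renal_failure(ccr_or_gfr = 120, scr_now = 0.8,
                                   scr_baseline = 0.8))
  expect_true(acute_renal_failure(scr_now = 1.6, scr_baseline = 0.8))
  expect_true(acute_renal_failure(scr_now = 1.0, scr_baseline = 1.0,
                                  scr_uln = 0.9))
  # 1.5-fold for two consecutive, increasing measurements
  expect_true(acute_renal_failure(scr_now = 1.0, scr_baseline = 0.6,
                                  scr_series = c(0.95, 1.0)))
  expect_false(acute_renal_failure(scr_now = 1.0, scr_baseline = 0.6,
                                   scr_series = c(1.0, 0.95)))
  expect_error(acute_renal_failure(), "evaluable")
})

test_that("phase-1 cohorts have the study layout", {
  co <- generate_cohort(study_design(1), cpg2_final_model(1), seed = 42)
  expect_length(co, 16)
  arms <- vapply(co, function(s) s$arm, numeric(1))
  expect_equal(sum(arms == 20), 8)
  expect_equal(sum(arms == 50), 8)
  for (s in co) {
    expect_equal(nrow(s$obs), 12)       # 192 samples over 16 subjects
    expect_equal(nrow(s$doses), 2)      # second dose at exactly 48 h
    expect_equal(s$doses$time, c(0, 48))
    expect_equal(s$doses$amount[1], s$arm * s$covariates$weight)
    expect_true(all(s$obs$analyte == "CPG2"))
  }
})

test_that("identical seeds reproduce cohorts exactly; seeds differ otherwise", {
  a <- generate_cohort(study_design(1, n_subjects = 4),
                       cpg2_final_model(1), seed = 9)
  b <- generate_cohort(study_design(1, n_subjects = 4),
                       cpg2_final_model(1), seed = 9)
  c3 <- generate_cohort(study_design(1, n_subjects = 4),
                        cpg2_final_model(1), seed = 10)
  expect_identical(lapply(a, function(s) s$obs),
                   lapply(b, function(s) s$obs))
  expect_false(identical(a[[1]]$obs$dv, c3[[1]]$obs$dv))
})

test_that("with all variability at zero the data equal the typical curve", {
  pop <- cpg2_final_model(1)
  pop$omega2_cl <- 0; pop$omega2_v <- 0; pop$sigma_add <- 0
  co <- generate_cohort(study_design(1, n_subjects = 3), pop, seed = 1)
  for (s in co) {
    ind <- cpg2_individual(pop, s$covariates)
    expect_equal(s$obs$dv, cpg2_conc(s$obs$time, s$doses, ind))
    expect_equal(s$obs$dv, s$obs$tdv)
  }
})

test_that("residual error models are additive (CPG2) / proportional (MTX)", {
  expect_equal(apply_residual_error(c(1, 2), "CPG2", 0)$value, c(1, 2))
  expect_equal(apply_residual_error(10, "MTX", 0)$value, 10)
  # a fixed seed draws the same eps under either error model
  a <- apply_residual_error(10, "MTX", 0.1, seed = 4)$value
  eps <- apply_residual_error(100, "CPG2", 1, seed = 4)$value - 100
  expect_equal(a, 10 * (1 + 0.1 * eps))
  # Monte-Carlo: empirical SD of (obs - pred) approaches sigma (additive)
  set.seed(77)
  draws <- apply_residual_error(rep(5, 1e5), "CPG2", 0.25)
  expect_equal(sd(draws$value - 5), 0.25, tolerance = 0.02)
  # proportional: MTX pred 10 with eps 0.1 gives 11
  expect_equal(10 * (1 + 0.1), 11)
  set.seed(78)
  mtx <- apply_residual_error(rep(10, 1e5), "MTX", 0.2)
  expect_equal(sd(mtx$value / 10 - 1), 0.2, tolerance = 0.02)
  # negative draws are floored and flagged
  set.seed(79)
  low <- apply_residual_error(rep(0.01, 1000), "CPG2", 1)
  expect_true(any(low$floored))
  expect_true(all(low$value >= 0))
})

test_that("assay censoring applies the quantification limits", {
  # 0.5 ng/ml MTX is ~0.0011 umol/L via the molar mass 454.44 g/mol
  expect_true(censor_assay(0.0005, "MTX")$below_lloq)
  expect_false(censor_assay(0.002, "MTX")$below_lloq)
  expect_false(censor_assay(50, "MTX")$below_lloq)
  # CPG2 LLOQ 1 ng/ml = 0.001 mg/L
  expect_true(censor_assay(0.0005, "CPG2")$below_lloq)
  expect_false(censor_assay(0.5, "CPG2")$below_lloq)
  # no upper censoring: values far above the ULOQ pass through
  expect_false(censor_assay(700, "MTX")$below_lloq)
})

test_that("phase-2 cohorts are eligible at CPG2 start and follow the rules", {
  co <- cached_phase2_cohort()
  for (s in co) {
    tr <- s$truth
    expect_true(eligible_for_cpg2(tr$c0, tr$hours_post_mtx, tr$arf,
                                  tr$mtx_dose_g_per_m2)$eligible)
    # the dosing history reproduces the drawn baseline concentration
    p <- tr$mtx
    prof <- solve_mtx(s$doses[s$doses$analyte == "MTX", , drop = FALSE],
                      p, times = c(-tr$hours_post_mtx, 0))
    expect_equal(prof$conc[2], tr$c0, tolerance = 1e-6)
    # second dose appended iff the true 46-h concentration exceeds 1 umol/L
    n_cpg2 <- sum(s$doses$analyte == "CPG2")
    expect_equal(n_cpg2, if (tr$conc46 > 1) 2L else 1L)
    if (tr$second_dose) {
      expect_true(48 %in% s$doses$time[s$doses$analyte == "CPG2"])
      expect_true(all(c("72h", "96h") %in%
                        s$obs$nominal[s$obs$analyte == "MTX"]))
    }
    # window samples landed inside their windows
    w <- s$obs[s$obs$nominal == "5-8h" & s$obs$analyte == "MTX", ]
    expect_true(w$time >= 5 && w$time <= 8)
    w2 <- s$obs[s$obs$nominal == "12-20h", ]
    expect_true(all(w2$time >= 12 & w2$time <= 20))
  }
})

test_that("per-point missingness thins the observation schedule", {
  d <- study_design(2, n_subjects = 3, missing_prob = 0.35)
  co <- generate_cohort(d, cpg2_final_model(2), mtx_final_model(),
                        seed = 15)
  full <- generate_cohort(study_design(2, n_subjects = 3),
                          cpg2_final_model(2), mtx_final_model(),
                          seed = 15)
  expect_lt(sum(vapply(co, function(s) nrow(s$obs), integer(1))),
            sum(vapply(full, function(s) nrow(s$obs), integer(1))))
})

test_that("impossible designs are rejected", {
  expect_error(study_design(2, n_subjects = 0), "positive")
  expect_error(study_design(3), "phase")
  expect_error(generate_cohort(study_design(2, n_subjects = 2),
                               cpg2_final_model(2)), "pop_mtx")
})
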