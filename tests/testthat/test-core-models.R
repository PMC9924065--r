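# Structural models: BSA, covariate models, CPG2 closed form, MTX ODE.

test_that("DuBois BSA evaluates, errors on bad input, and scales correctly", {
  expect_equal(bsa_dubois(169.6, 60.9), 1.7028, tolerance = 1e-4)
  expect_error(bsa_dubois(100, 0), "positive")
  expect_error(bsa_dubois(-1, 60), "positive")
  # doubling both height and weight multiplies BSA by 2^(0.725+0.425)
  expect_equal(bsa_dubois(320, 140) / bsa_dubois(160, 70), 2^1.15)
  expect_equal(bsa_mosteller(180, 80), sqrt(180 * 80 / 3600))
})

test_that("covariates() derives BSA and rejects non-positive values", {
  cv <- covariates(weight = 60.9, height = 169.6)
  expect_equal(cv$bsa, bsa_dubois(169.6, 60.9))
  cv2 <- covariates(weight = 60.9, height = 169.6, bsa_formula = "mosteller")
  expect_equal(cv2$bsa, bsa_mosteller(169.6, 60.9))
  expect_error(covariates(weight = -5, height = 170), "positive")
  expect_error(covariates(weight = 60), "bsa")
})

test_that("CPG2 covariate model reproduces the fitted typical values", {
  cov1 <- covariates(weight = 60, bsa = 1)
  # typical clearance at BSA 1 equals the typical value itself
  p2 <- cpg2_individual(cpg2_final_model(2), cov1)
  expect_equal(p2$cl, 0.238)
  expect_equal(p2$v, 1.200)
  # phase-1 model at the healthy-volunteer mean BSA
  bsa <- bsa_dubois(169.6, 60.9)
  p1 <- cpg2_individual(cpg2_final_model(1), covariates(weight = 60.9,
                                                        bsa = bsa))
  expect_equal(p1$cl, 0.0590 * bsa^3.227)
  expect_equal(p1$cl, 0.329, tolerance = 0.01)
  # random effects act multiplicatively on the log scale
  pe <- cpg2_individual(cpg2_final_model(2), cov1, eta = c(0.3, -0.2))
  expect_equal(pe$cl, 0.238 * exp(0.3))
  expect_equal(pe$v, 1.200 * exp(-0.2))
})

test_that("MTX covariate model reproduces the final-model formulas", {
  pop <- mtx_final_model()
  cov <- covariates(weight = 60, bsa = 1.703, scr = 1)
  p <- mtx_individual(pop, cov)
  expect_equal(p$clr, 3.248)                 # 3.248 * 60/1/60
  expect_equal(p$vp, 3.052)                  # 3.052 * 60/60
  expect_equal(p$vc, 0.386 * 60 / 1.703)     # ~13.60 L
  expect_equal(p$vc, 13.60, tolerance = 1e-3)
  expect_equal(p$kr, p$clr / p$vc)
  expect_equal(p$kr, 0.2389, tolerance = 1e-3)
  expect_equal(p$alpha, 6.545e5)
  expect_error(covariates(weight = 60, bsa = 1.7, scr = 0), "positive")
})

test_that("micro-constant identities hold for sampled individuals", {
  pop <- mtx_final_model()
  set.seed(5)
  for (i in 1:25) {
    cov <- covariates(weight = runif(1, 11, 78), height = runif(1, 80, 178),
                      scr = runif(1, 0.3, 3.4))
    p <- mtx_individual(pop, cov, eta = rnorm(4, 0, 0.5))
    expect_equal(p$kr * p$vc, p$clr, tolerance = 1e-12)
    expect_equal(p$k12 * p$vc, pop$q_fixed, tolerance = 1e-12)
    expect_equal(p$k21 * p$vp, pop$q_fixed, tolerance = 1e-12)
  }
})

test_that("cpg2_conc: pre-dose zero, no-elimination limit, superposition", {
  doses <- dose_event(1, 3000, 1 / 12, "CPG2")
  p <- list(cl = 0.3, v = 3)
  expect_equal(cpg2_conc(c(0, 0.5, 1), doses, p), c(0, 0, 0))
  # cl = 0: concentration at end of infusion equals total mass / V
  p0 <- list(cl = 0, v = 3)
  expect_equal(cpg2_conc(1 + 1 / 12, doses, p0), (3000 / 1000) / 3)
  # superposition of two doses equals the sum of single-dose curves
  d2 <- rbind(doses, dose_event(48, 3000, 1 / 12, "CPG2"))
  t <- c(2, 47, 50, 96)
  expect_equal(cpg2_conc(t, d2, p),
               cpg2_conc(t, doses, p) +
                 cpg2_conc(t, dose_event(48, 3000, 1 / 12, "CPG2"), p))
  expect_error(cpg2_conc(c(1, NA), doses, p))
})

test_that("cpg2_conc closed form matches a numeric ODE of the same model", {
  p <- list(cl = 0.35, v = 2.8)
  doses <- rbind(dose_event(0, 2500, 1 / 12, "CPG2"),
                 dose_event(48, 2500, 1 / 12, "CPG2"))
  rate <- 2500 / 1000 / (1 / 12)
  rhs <- function(t, y, parms) {
    inr <- if ((t >= 0 && t < 1 / 12) || (t >= 48 && t < 48 + 1 / 12))
      rate else 0
    list(inr - p$cl / p$v * y)
  }
  times <- sort(c(seq(0, 96, by = 0.5), 1 / 12, 48 + 1 / 12))
  # small hmax so the adaptive stepper cannot overstep the 5-min infusions
  ode <- deSolve::lsoda(0, times, rhs, NULL, rtol = 1e-11, atol = 1e-13,
                        hmax = 0.02)
  conc_ode <- ode[, 2] / p$v
  conc_cf <- cpg2_conc(times, doses, p)
  expect_equal(conc_cf, conc_ode, tolerance = 1e-8)
})

test_that("mtx_rhs: zero state, half-saturation, and linear limit", {
  pop <- mtx_final_model()
  p <- mtx_individual(pop, covariates(weight = 60, bsa = 1.7, scr = 1))
  z <- mtx_rhs(0, mtx_state(), p, cpg2 = 5)
  expect_equal(unname(z[[1]]), rep(0, 4))
  # at [Xc] = Km the MM elimination runs at Vmax/2, Vmax = alpha * [CPG2]
  cc <- 2.5
  st <- mtx_state(xc = pop$km_fixed * p$vc)
  d <- mtx_rhs(0, st, p, cpg2 = cc)
  expect_equal(d[[1]][["cum_degraded"]], p$alpha * cc / 2)
  # no catalyst: exact linear two-compartment derivatives
  st2 <- mtx_state(xc = 100, xp = 40)
  d2 <- mtx_rhs(0, st2, p, cpg2 = 0)
  expect_equal(d2[[1]][["xc"]], -(p$kr + p$k12) * 100 + p$k21 * 40)
  expect_equal(d2[[1]][["xp"]], p$k12 * 100 - p$k21 * 40)
  expect_equal(d2[[1]][["cum_degraded"]], 0)
})

test_that("solve_mtx with alpha = 0 matches the biexponential closed form", {
  pop <- mtx_pop_params(tv_clr = 3.248, tv_vc = 0.386, tv_vp = 3.052,
                        tv_alpha = 1e-300 + 1, covariate_model = "final")
  p <- mtx_individual(pop, covariates(weight = 47, bsa = 1.4, scr = 0.8))
  p$alpha <- 0
  amt <- 30000
  doses <- dose_event(0, amt, 6, "MTX")
  times <- seq(0, 96, length.out = 100)
  out <- solve_mtx(doses, p, times = times)
  oracle <- lin2cpt_amounts(times, data.frame(t0 = 0, t1 = 6,
                                              rate = amt / 6),
                            k10 = p$kr, k12 = p$k12, k21 = p$k21)
  expect_equal(out$xc[-1], oracle$xc[-1], tolerance = 1e-6)
  expect_equal(out$xp[-1], oracle$xp[-1], tolerance = 1e-6)
})

test_that("the compiled and pure-R engines agree", {
  co <- cached_phase2_cohort()
  s <- co[[1]]
  p <- s$truth$mtx
  times <- c(-2, 0, 0.5, 2, 24, 48)
  a <- solve_mtx(s$doses, p, s$truth$cpg2, times = times)
  b <- solve_mtx(s$doses, p, s$truth$cpg2, times = times, engine = "R")
  expect_equal(a$conc, b$conc, tolerance = 1e-6)
  expect_equal(a$cum_degraded, b$cum_degraded, tolerance = 1e-6)
})

test_that("mass is conserved for every simulated subject at all times", {
  co <- cached_phase2_cohort()
  for (s in co) {
    p <- s$truth$mtx
    times <- sort(unique(c(seq(-1, 96, by = 7), 0.1, 0.4, 46)))
    out <- solve_mtx(s$doses, p, s$truth$cpg2, times = times)
    total <- out$xc + out$xp + out$cum_renal + out$cum_degraded
    expect_equal(total, out$dosed, tolerance = 1e-6)
  }
})

test_that("increasing the CPG2 dose never increases the MTX exposure", {
  co <- cached_phase2_cohort()
  s <- co[[2]]
  p <- s$truth$mtx
  times <- seq(0, 48, by = 0.5)
  auc <- function(scale) {
    doses <- s$doses
    is_c <- doses$analyte == "CPG2"
    doses$amount[is_c] <- doses$amount[is_c] * scale
    out <- solve_mtx(doses, p, s$truth$cpg2, times = times)
    sum(diff(times) * (head(out$conc, -1) + tail(out$conc, -1)) / 2)
  }
  aucs <- vapply(c(0.25, 0.5, 1, 2, 4), auc, numeric(1))
  expect_true(all(diff(aucs) <= 1e-8))
})

test_that("a rescue-scale CPG2 dose collapses plasma MTX within 15 min", {
  # typical adult, delayed excretion, 50 U/kg CPG2
  pop <- mtx_final_model()
  cov <- covariates(weight = 60, height = 170, scr = 1.5)
  p <- mtx_individual(pop, cov)
  pc <- cpg2_individual(cpg2_final_model(2), cov)
  doses <- rbind(dose_event(-40, 3e5, 6, "MTX"),
                 dose_event(0, 50 * 60, 1 / 12, "CPG2"))
  out <- solve_mtx(doses, p, pc, times = c(0, 0.25))
  drop_frac <- 1 - out$conc[2] / out$conc[1]
  expect_gt(drop_frac, 0.95)
})

test_that("the worked-example summary reproduces the headline values", {
  sm <- final_model_summary()
  val <- function(pat) sm$value[grep(pat, sm$quantity)]
  expect_equal(val("renal clearance"), 3.248)
  expect_equal(val("central volume"), 0.386)
  expect_equal(val("peripheral volume"), 3.052)
  expect_equal(val("Vmax per unit"), 6.545e5)
  expect_equal(val("clearance at mean BSA"), 0.329, tolerance = 0.01)
  expect_equal(val("weight-normalized"), 0.0896, tolerance = 0.01)
})

test_that("init_from_conc puts the system at the distribution steady ratio", {
  p <- mtx_individual(mtx_final_model(),
                      covariates(weight = 60, bsa = 1.7, scr = 1))
  st <- init_from_conc(50, p)
  expect_equal(st[["xc"]], 50 * p$vc)
  expect_equal(st[["xp"]] / st[["xc"]], p$k12 / p$k21)
  expect_error(init_from_conc(-1, p))
})
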