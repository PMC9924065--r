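# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results through different routes than the
# package (quadrature instead of Laplace, biexponential partial fractions
# instead of the ODE integrator).

# ---- Gauss-Hermite marginal likelihood (one free random effect) -------------

# -2 log of the exact marginal likelihood for a single subject with additive
# residual error and a single normal random effect, by Gauss-Hermite
# quadrature (change of variable eta = sqrt(2) * omega * x).
gh_neg2ll_1eta <- function(y, f_of_eta, omega2, sigma, n_nodes = 80) {
  gh <- pracma::gaussHermite(n_nodes)
  eta <- sqrt(2 * omega2) * gh$x
  ll <- vapply(eta, function(e) {
    f <- f_of_eta(e)
    sum(dnorm(y, f, sigma, log = TRUE))
  }, numeric(1))
  m <- max(ll)
  -2 * (m + log(sum(gh$w * exp(ll - m))) - 0.5 * log(pi))
}

# ---- biexponential two-compartment solution ---------------------------------

# Closed-form central/peripheral amounts for the linear two-compartment
# model (elimination k10 from central) under piecewise-constant infusion
# into the central compartment, via partial fractions of the transfer
# function -- no matrix exponentials, no ODE solver.
lin2cpt_amounts <- function(t, infusions, k10, k12, k21) {
  S <- k10 + k12 + k21
  P <- k10 * k21
  alpha <- (S + sqrt(S^2 - 4 * P)) / 2
  beta <- (S - sqrt(S^2 - 4 * P)) / 2
  # unit-bolus impulse responses
  cc <- c((k21 - alpha) / (beta - alpha), (k21 - beta) / (alpha - beta))
  cp <- c(k12 / (beta - alpha), -k12 / (beta - alpha))
  lam <- c(alpha, beta)
  xc <- numeric(length(t)); xp <- numeric(length(t))
  for (i in seq_len(nrow(infusions))) {
    t0 <- infusions$t0[i]; t1 <- infusions$t1[i]; r <- infusions$rate[i]
    for (j in 1:2) {
      te <- pmax(pmin(t, t1) - t0, 0)      # infused duration so far
      post <- pmax(t - t1, 0)
      g <- r / lam[j] * (1 - exp(-lam[j] * te)) * exp(-lam[j] * post)
      xc <- xc + cc[j] * g
      xp <- xp + cp[j] * g
    }
  }
  list(xc = xc, xp = xp)
}

# ---- fixture builders -------------------------------------------------------

make_subject <- function(id = 1, cov, doses, obs, truth = NULL) {
  structure(list(id = id, arm = NA, covariates = cov, doses = doses,
                 obs = obs, truth = truth),
            class = "pk_subject")
}

make_obs <- function(time, analyte, dv, nominal = as.character(time),
                     blq = FALSE, tdv = dv) {
  data.frame(time = time, nominal = nominal, analyte = analyte,
             dv = dv, blq = blq, tdv = tdv, stringsAsFactors = FALSE)
}

as_cohort <- function(subjects) structure(subjects, class = "pk_cohort")

# A single-subject CPG2 "toy": short infusion approximating a bolus, a few
# samples, additive error; random effect on CL only (omega2_v = 0).
toy_cpg2_subject <- function(eta = c(0, 0), sigma = 0, seed = NULL,
                             pop = toy_cpg2_pop()) {
  cov <- covariates(weight = 60, bsa = 1.7)
  doses <- dose_event(0, 3000, 1 / 12, "CPG2")
  ind <- cpg2_individual(pop, cov, eta)
  times <- c(0.25, 2, 8, 24)
  pred <- cpg2_conc(times, doses, ind)
  if (!is.null(seed)) set.seed(seed)
  dv <- pred + rnorm(length(pred), 0, sigma)
  make_subject(1, cov, doses, make_obs(times, "CPG2", dv))
}

toy_cpg2_pop <- function(omega2_cl = 0.04, omega2_v = 0, sigma_add = 0.05)
  cpg2_pop_params(tv_cl = 0.3, tv_v = 3, omega2_cl = omega2_cl,
                  omega2_v = omega2_v, sigma_add = sigma_add)

# Small phase-2-like cohorts are expensive to build; share one per suite run.
cached_phase2_cohort <- local({
  cache <- list()
  function(n = 8, seed = 301) {
    key <- paste(n, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_cohort(study_design(2, n_subjects = n),
                                       cpg2_final_model(2),
                                       mtx_final_model(), seed = seed)
    cache[[key]]
  }
})
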