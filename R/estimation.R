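# Population estimation: FOCE/Laplace approximate marginal likelihood with
# the random-effect vector optimized to its conditional mode per subject,
# quasi-Newton outer optimization on transformed parameters, and
# empirical-Bayes (MAP) individual estimation.

.est_control <- function(control = list()) {
  utils::modifyList(list(
    rel.tol = 1e-6,      # outer convergence, relative OFV change
    iter.max = 200, eval.max = 800,
    inner.maxit = 30,    # Gauss-Newton iterations for the eta mode
    inner.tol = 1e-6,
    jac.step = 1e-4,     # forward-difference step on eta
    ode.rtol = 1e-6, ode.atol = 1e-8,  # solver tolerances inside the fit
    # Additive floor (data units) in the proportional residual variance,
    # v = sigma^2 (f^2 + prop_floor^2).  An unfloored proportional variance
    # gives near-zero predictions unbounded leverage; 0.01 umol/L sits an
    # order of magnitude above the MTX assay's quantification limit, so
    # quantifiable observations keep their full weight.
    prop_floor = 0.01,
    ndeps = 1e-3,        # finite-difference step of the outer optimizer
    its.maxit = 60, its.tol = 2e-3,  # iterated two-stage loop
    inner.starts = "both",  # "both" = prior mode + warm start; "warm" = warm
    trace = 0), control)
}

# ---- Laplace/FOCE machinery -------------------------------------------------

# Conditional-mode (MAP) optimization of eta for one subject and the
# FOCE-with-interaction contribution to -2 log-likelihood.
#
# y:      observation vector (BLQ-censored records already dropped, M1)
# f_fun:  function(eta) -> prediction vector (full-length eta)
# omega2: diagonal IIV variances; entries of 0 pin the matching eta at 0
# sigma:  residual SD (additive: units of y; proportional: fraction)
# etype:  "add" or "prop"
.laplace_subject <- function(y, f_fun, omega2, sigma, etype, eta0 = NULL,
                             ctrl = .est_control(), want_curvature = FALSE) {
  k <- length(omega2)
  active <- which(omega2 > 0)
  ka <- length(active)
  full_eta <- function(ea) {
    e <- numeric(k); e[active] <- ea; e
  }
  if (length(y) == 0) {
    out <- list(nll2 = 0, eta = numeric(k), pred = numeric(0),
                converged = TRUE, deviance = 0, no_obs = TRUE)
    return(out)
  }
  pf2 <- ctrl$prop_floor^2
  vfun <- function(pred) {
    if (etype == "add") rep(sigma^2, length(pred))
    else sigma^2 * (pred^2 + pf2)
  }
  o2a <- omega2[active]
  hfun <- function(ea, pred = NULL) {
    if (is.null(pred)) pred <- f_fun(full_eta(ea))
    v <- vfun(pred)
    sum((y - pred)^2 / v + log(2 * pi * v)) + sum(ea^2 / o2a)
  }

  f_safe <- function(eta) {
    p <- tryCatch(f_fun(eta), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) rep(NA_real_, length(y)) else p
  }
  jac <- function(ea, pred) {
    J <- matrix(0, length(y), ka)
    for (j in seq_len(ka)) {
      ej <- ea; ej[j] <- ej[j] + ctrl$jac.step
      J[, j] <- (f_safe(full_eta(ej)) - pred) / ctrl$jac.step
    }
    J
  }
  gn_parts <- function(ea, pred, J) {
    r <- y - pred
    v <- vfun(pred)
    if (etype == "add") {
      dtdf <- -2 * r / v
      w <- 1 / v
    } else {
      vp <- 2 * sigma^2 * pred
      dtdf <- -2 * r / v - r^2 * vp / v^2 + vp / v
      w <- 1 / v + vp^2 / (2 * v^2)  # expected information incl. interaction
    }
    g <- drop(crossprod(J, dtdf)) + 2 * ea / o2a
    Hh <- crossprod(J, w * J) + diag(1 / o2a, ka)
    list(g = g, Hh = Hh)
  }

  # Levenberg-Marquardt-damped Gauss-Newton from one starting point: the
  # near-noise-free limit turns the conditional problem into a stiff
  # nonlinear least-squares valley that an undamped step overshoots.
  run_gn <- function(ea_start) {
    ea <- pmin(pmax(ea_start, -10), 10)
    pred <- f_safe(full_eta(ea))
    h0 <- hfun(ea, pred)
    if (!is.finite(h0)) return(NULL)
    J <- NULL; J_stale <- TRUE; conv <- FALSE
    lambda <- 1e-4
    for (it in seq_len(ctrl$inner.maxit)) {
      if (is.null(J) || J_stale) { J <- jac(ea, pred); J_stale <- FALSE }
      p <- gn_parts(ea, pred, J)
      dH <- diag(p$Hh)
      accepted <- FALSE
      for (try in 1:12) {
        Hd <- p$Hh + lambda * diag(pmax(dH, 1e-10), ka)
        step <- tryCatch(-solve(Hd, p$g / 2), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          if (max(abs(step)) > 3) step <- step * 3 / max(abs(step))
          ea_new <- pmin(pmax(ea + step, -10), 10)
          pred_new <- f_safe(full_eta(ea_new))
          h_new <- hfun(ea_new, pred_new)
          if (is.finite(h_new) && h_new <= h0) {
            accepted <- TRUE
            lambda <- max(lambda * 0.3, 1e-8)
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e12) break
      }
      if (!accepted) { conv <- TRUE; break }
      moved <- max(abs(ea_new - ea))
      dh <- h0 - h_new
      ea <- ea_new; pred <- pred_new; h0 <- h_new
      J_stale <- moved > 1e-3   # J was computed a short step away
      if (moved < ctrl$inner.tol || dh < 1e-9 * (abs(h0) + 1)) {
        conv <- TRUE; break
      }
    }
    if (is.null(J) || J_stale) J <- jac(ea, pred)  # curvature at the mode
    list(ea = ea, pred = pred, h = h0, J = J, conv = conv)
  }

  if (ka > 0) {
    # Multi-start: the prior mode plus the warm start (when distinct).  The
    # conditional objective of the rescue model can have competing basins;
    # tracking only one makes the outer objective discontinuous.
    warm_ok <- !is.null(eta0) && max(abs(eta0[active])) > 1e-8
    starts <- if (warm_ok && ctrl$inner.starts == "warm")
      list(eta0[active])
    else if (warm_ok) list(numeric(ka), eta0[active])
    else list(numeric(ka))
    if (ctrl$inner.starts == "wide") {
      # axis multi-start for one-shot MAP calls, where no warm start exists
      # and a wrong basin directly distorts the forecast
      for (j in seq_len(ka)) for (s0 in c(0.5, -0.5)) {
        e <- numeric(ka); e[j] <- s0
        starts <- c(starts, list(e))
      }
    }
    best <- NULL
    for (st in starts) {
      r <- run_gn(st)
      if (!is.null(r) && (is.null(best) || r$h < best$h)) best <- r
    }
    if (is.null(best))
      stop("subject prediction failed at the prior mode")
    ea <- best$ea; pred <- best$pred; h0 <- best$h
    J <- best$J; conv <- best$conv
    p <- gn_parts(ea, pred, J)
    ldH <- determinant(p$Hh, logarithm = TRUE)$modulus
    nll2 <- h0 + sum(log(o2a)) + as.numeric(ldH)
  } else {
    ea <- numeric(0)
    pred <- f_safe(full_eta(ea))
    h0 <- hfun(ea, pred)
    J <- NULL
    nll2 <- h0
    conv <- TRUE
  }
  out <- list(nll2 = nll2, eta = full_eta(ea), pred = pred,
              converged = conv, deviance = h0, no_obs = FALSE)
  if (want_curvature && ka > 0) {
    out$J <- J
    out$active <- active
    out$v <- vfun(pred)
    out$Hh <- gn_parts(ea, pred, J)$Hh
  }
  out
}

# First-order (FO) approximation of a subject's -2 log-likelihood: linearize
# the model about eta = 0, giving a Gaussian marginal with mean f(0) and
# covariance J Omega J' + V(f(0)).  No inner optimization, smooth in the
# population parameters; used to initialize the conditional estimation.
.fo_subject <- function(y, f_fun, omega2, sigma, etype,
                        ctrl = .est_control()) {
  k <- length(omega2)
  if (length(y) == 0) return(0)
  f0 <- f_fun(numeric(k))
  if (any(!is.finite(f0))) return(NA_real_)
  v <- if (etype == "add") rep(sigma^2, length(y))
       else sigma^2 * (f0^2 + ctrl$prop_floor^2)
  active <- which(omega2 > 0)
  J <- matrix(0, length(y), length(active))
  for (j in seq_along(active)) {
    e <- numeric(k); e[active[j]] <- ctrl$jac.step
    J[, j] <- (f_fun(e) - f0) / ctrl$jac.step
  }
  Cov <- J %*% (omega2[active] * t(J)) + diag(v, length(v))
  L <- tryCatch(chol(Cov), error = function(e) NULL)
  if (is.null(L)) return(NA_real_)
  z <- backsolve(L, y - f0, transpose = TRUE)
  2 * sum(log(diag(L))) + length(y) * log(2 * pi) + sum(z^2)
}

# ---- model adapters ---------------------------------------------------------

# Per-subject fit context: y, f_fun(pop, eta), residual type.
.context_cpg2 <- function(cohort, units_per_mg, ctrl) {
  lapply(cohort, function(s) {
    o <- s$obs[s$obs$analyte == "CPG2" & !s$obs$blq, , drop = FALSE]
    o <- o[order(o$time), , drop = FALSE]
    d <- s$doses[s$doses$analyte == "CPG2", , drop = FALSE]
    t0 <- d$time; dur <- d$duration
    rate <- d$amount / units_per_mg / dur
    cov <- s$covariates
    times <- o$time
    list(y = o$dv, times = times, etype = "add",
         f_fun = function(pop, eta) {
           p <- cpg2_individual(pop, cov, eta)
           .cpg2_conc_core(times, t0, dur, rate, p$cl, p$v)
         })
  })
}

.context_mtx <- function(cohort, cpg2_fits, units_per_mg, ctrl) {
  stopifnot(length(cpg2_fits) == length(cohort))
  lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    o <- s$obs[s$obs$analyte == "MTX" & !s$obs$blq, , drop = FALSE]
    o <- o[order(o$time), , drop = FALSE]
    doses <- s$doses
    cov <- s$covariates
    pc <- cpg2_fits[[i]]
    times <- o$time
    mtx_rows <- doses$analyte == "MTX"
    # The MTX dosing history usually ends before the first CPG2 dose and
    # before every observation; that segment is linear and is propagated in
    # closed form, so the stiff integrator only runs over the catalyst era.
    fast <- nrow(doses[mtx_rows, ]) > 0 &&
      all(doses$time[mtx_rows] + doses$duration[mtx_rows] <= 0) &&
      all(doses$duration[mtx_rows] > 0) &&
      (length(times) == 0 || all(times >= 0))
    if (fast) {
      mtx_inf <- .infusion_table(doses, "MTX", units_per_mg)
      cpg2_doses <- doses[!mtx_rows, , drop = FALSE]
      f_fun <- function(pop, eta) {
        p <- mtx_individual(pop, cov, eta)
        x0 <- .linear_amounts_at(mtx_inf, p, 0)
        out <- solve_mtx(cpg2_doses, p, pc, times = times,
                         init = mtx_state(xc = x0[1], xp = x0[2]),
                         units_per_mg = units_per_mg,
                         rtol = ctrl$ode.rtol, atol = ctrl$ode.atol)
        out$conc[match(times, out$time)]
      }
    } else {
      f_fun <- function(pop, eta) {
        p <- mtx_individual(pop, cov, eta)
        out <- solve_mtx(doses, p, pc, times = times,
                         units_per_mg = units_per_mg,
                         rtol = ctrl$ode.rtol, atol = ctrl$ode.atol)
        out$conc[match(times, out$time)]
      }
    }
    list(y = o$dv, times = times, etype = "prop", f_fun = f_fun)
  })
}

# Iterated two-stage estimation: alternate empirical-Bayes (MAP) estimation
# of every subject's random effects with closed-form moment updates of the
# population parameters.  Typical values absorb the mean conditional-mode
# deviation; covariate exponents (CPG2 model) absorb the regression of the
# deviations on the log covariate; IIV variances are the mean squared
# deviations plus the mean posterior variance (curvature correction); the
# residual variance uses shrinkage-corrected degrees of freedom.
.run_its <- function(ctxs, cohort, init, model, fixed, ctrl) {
  pop <- init
  n <- length(ctxs)
  if (model == "cpg2") {
    tv_names <- c("tv_cl", "tv_v")
    om_names <- c("omega2_cl", "omega2_v")
    sig_name <- "sigma_add"
    th_names <- c("theta_cl", "theta_v")
    cov_names <- c(pop$cov_cl, pop$cov_v)
  } else {
    tv_names <- c("tv_clr", "tv_vc", "tv_vp", "tv_alpha")
    om_names <- c("omega2_clr", "omega2_vc", "omega2_vp", "omega2_alpha")
    sig_name <- "sigma_prop"
    th_names <- cov_names <- rep(NA_character_, 4)
  }
  k <- length(tv_names)
  logcov <- matrix(NA_real_, n, k)
  for (j in seq_len(k))
    if (!is.na(cov_names[j]))
      logcov[, j] <- log(vapply(cohort, function(s)
        cov_value(s$covariates, cov_names[j]), numeric(1)))

  warm <- vector("list", n)
  track <- function(p) {
    v <- c(unlist(p[tv_names]), unlist(p[om_names]), p[[sig_name]],
           unlist(p[th_names[!is.na(th_names)]]))
    v
  }
  converged <- FALSE
  iter <- 0
  ctrl_i <- ctrl
  for (iter in seq_len(ctrl$its.maxit)) {
    # after the opening sweeps the modes move smoothly with the updates, so
    # the prior-mode restart is only re-enabled every few iterations
    ctrl_i$inner.starts <- if (iter <= 2 || iter %% 5 == 0) "both" else "warm"
    old <- track(pop)
    omega2 <- .omega2_of(pop, model)
    sigma <- .sigma_of(pop, model)
    E <- matrix(0, n, k)
    Vd <- matrix(0, n, k)
    q_sum <- 0; n_obs <- 0; edf <- 0
    for (i in seq_len(n)) {
      cx <- ctxs[[i]]
      li <- .laplace_subject(cx$y, function(eta) cx$f_fun(pop, eta),
                             omega2, sigma, cx$etype, eta0 = warm[[i]],
                             ctrl = ctrl_i, want_curvature = TRUE)
      warm[[i]] <- li$eta
      E[i, ] <- li$eta
      if (!is.null(li$Hh)) {
        Vp <- tryCatch(solve(li$Hh), error = function(e) NULL)
        if (!is.null(Vp)) {
          Vd[i, li$active] <- pmax(diag(Vp), 0)
          edf <- edf + sum(1 - pmin(diag(Vp) / omega2[li$active], 1))
        }
      } else if (isTRUE(li$no_obs)) {
        Vd[i, ] <- omega2
      }
      if (length(cx$y)) {
        r <- cx$y - li$pred
        q_sum <- q_sum + if (cx$etype == "add") sum(r^2)
                         else sum(r^2 / (li$pred^2 + ctrl$prop_floor^2))
        n_obs <- n_obs + length(cx$y)
      }
    }
    # typical values absorb the mean deviation
    for (j in seq_len(k)) {
      if (tv_names[j] %in% fixed) next
      mj <- max(min(mean(E[, j]), 1), -1)
      pop[[tv_names[j]]] <- pop[[tv_names[j]]] * exp(mj)
      E[, j] <- E[, j] - mj
      # covariate exponent update by damped regression on the log
      # covariate; undamped updates can oscillate and diverge on small
      # resampled cohorts where the covariate spread is thin
      if (!is.na(cov_names[j]) && !(th_names[j] %in% fixed)) {
        x <- logcov[, j] - mean(logcov[, j])
        if (sum(x^2) > 0) {
          b <- 0.7 * sum(x * E[, j]) / sum(x^2)
          b <- max(min(b, 1), -1)
          th_new <- max(min(pop[[th_names[j]]] + b, 20), -20)
          b <- th_new - pop[[th_names[j]]]
          pop[[th_names[j]]] <- th_new
          E[, j] <- E[, j] - b * x
        }
      }
    }
    for (j in seq_len(k))
      if (!(om_names[j] %in% fixed))
        pop[[om_names[j]]] <- max(mean(E[, j]^2 + Vd[, j]), 1e-6)
    if (!(sig_name %in% fixed) && n_obs > 0) {
      s2 <- q_sum / max(n_obs - edf, 1)
      pop[[sig_name]] <- sqrt(max(s2, 1e-8))
    }
    # near-zero variance components jitter at the MAP-noise scale and must
    # not hold up convergence; judge changes against a sensible scale
    dif <- max(abs(track(pop) - old) / pmax(abs(old), 0.05), na.rm = TRUE)
    if (ctrl$trace > 0)
      cat(sprintf("[its %d] max log-change %.5f\n", iter, dif))
    if (dif < ctrl$its.tol) { converged <- TRUE; break }
  }
  list(pop = pop, converged = converged, iterations = iter,
       message = if (converged) "ITS converged" else "ITS hit iteration cap")
}

# ---- parameter packing ------------------------------------------------------

# Optimization bounds are broad pharmacological plausibility ranges on the
# transformed scale; they exist to keep the optimizer away from regions
# where the stiff system cannot be integrated, not to inform the estimate.
.cpg2_meta <- function(pop) {
  nm <- c("tv_cl",
          if (!is.na(pop$cov_cl)) "theta_cl",
          "tv_v",
          if (!is.na(pop$cov_v)) "theta_v",
          "omega2_cl", "omega2_v", "sigma_add")
  trans <- ifelse(grepl("^theta", nm), "id", "log")
  lower <- ifelse(grepl("^theta", nm), -20,
                  ifelse(grepl("^omega2", nm), log(1e-6), log(1e-4)))
  upper <- ifelse(grepl("^theta", nm), 20,
                  ifelse(grepl("^omega2", nm), log(4), log(1e3)))
  data.frame(name = nm, trans = trans, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

.mtx_meta <- function(pop) {
  nm <- c("tv_clr", "tv_vc", "tv_vp", "tv_alpha",
          "omega2_clr", "omega2_vc", "omega2_vp", "omega2_alpha",
          "sigma_prop")
  lower <- c(rep(log(1e-3), 3), log(10), rep(log(1e-4), 4), log(1e-3))
  upper <- c(rep(log(1e3), 3), log(1e9), rep(log(4), 4), log(3))
  data.frame(name = nm, trans = "log", lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

.pack <- function(pop, meta) {
  vapply(seq_len(nrow(meta)), function(i) {
    v <- pop[[meta$name[i]]]
    if (meta$trans[i] == "log") log(max(v, 1e-10)) else v
  }, numeric(1))
}

.unpack <- function(par, meta, template) {
  pop <- template
  for (i in seq_len(nrow(meta))) {
    v <- if (meta$trans[i] == "log") exp(par[i]) else par[i]
    pop[[meta$name[i]]] <- v
  }
  pop
}

.omega2_of <- function(pop, model) {
  if (model == "cpg2") c(pop$omega2_cl, pop$omega2_v)
  else c(pop$omega2_clr, pop$omega2_vc, pop$omega2_vp, pop$omega2_alpha)
}

.sigma_of <- function(pop, model) {
  if (model == "cpg2") pop$sigma_add else pop$sigma_prop
}

# ---- public API -------------------------------------------------------------

#' Likelihood-ratio inclusion threshold
#'
#' Critical change in objective function value (-2 log-likelihood) for a
#' nested-model comparison: the upper chi-square quantile with `df` degrees
#' of freedom.  At `df = 1`, `p = 0.001` this is 10.828, the covariate
#' inclusion rule used throughout model building.
#'
#' @param df degrees of freedom (>= 1)
#' @param p significance level in (0, 1)
#' @return critical delta-OFV
#' @examples
#' lrt_threshold(1, 0.001)  # 10.828
#' @export
lrt_threshold <- function(df, p) {
  if (df < 1) stop("df must be >= 1")
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("p must be in (0, 1)")
  qchisq(1 - p, df)
}

#' Objective function value (approximate -2 log-likelihood)
#'
#' Computes the population objective function for a cohort under a given
#' population model, using a first-order-conditional (FOCE-with-interaction
#' / Laplace) approximation: for every subject the random-effect vector is
#' optimized to its conditional mode and the marginal likelihood is
#' approximated by a Gaussian integral around that mode.  The OFV is
#' additive over subjects; below-quantification-limit records are dropped
#' (M1 method).
#'
#' @param pop population parameters ([cpg2_pop_params()] or
#'   [mtx_pop_params()])
#' @param cohort a `pk_cohort` (or list of `pk_subject`s)
#' @param model `"cpg2"` (one-compartment CPG2 popPK) or `"cpg2-mtx"` (the
#'   coupled MTX model; CPG2 individual parameters must be supplied)
#' @param cpg2_fits for `"cpg2-mtx"`: per-subject CPG2 parameters, either a
#'   list of `list(cl=, v=)` or the output of [cpg2_posthoc()]
#' @param units_per_mg CPG2 potency constant
#' @param control list of numerical settings, see source of `.est_control`
#' @return the OFV, with per-subject conditional modes in attribute `"etas"`
#' @export
neg2ll <- function(pop, cohort, model = c("cpg2", "cpg2-mtx"),
                   cpg2_fits = NULL, units_per_mg = 1000, control = list()) {
  model <- match.arg(model)
  ctrl <- .est_control(control)
  ctxs <- if (model == "cpg2") .context_cpg2(cohort, units_per_mg, ctrl)
          else .context_mtx(cohort, cpg2_fits, units_per_mg, ctrl)
  omega2 <- .omega2_of(pop, model)
  sigma <- .sigma_of(pop, model)
  etas <- matrix(0, length(ctxs), length(omega2))
  ofv <- 0
  for (i in seq_along(ctxs)) {
    cx <- ctxs[[i]]
    li <- .laplace_subject(cx$y, function(eta) cx$f_fun(pop, eta),
                           omega2, sigma, cx$etype, ctrl = ctrl)
    ofv <- ofv + li$nll2
    etas[i, ] <- li$eta
  }
  structure(ofv, etas = etas)
}

#' Fit a population model
#'
#' Maximum (approximate) likelihood estimation of typical values, IIV
#' variances and the residual variance by quasi-Newton minimization of the
#' FOCE/Laplace objective on log-transformed (positivity-constrained)
#' parameters, with covariate exponents unconstrained.  `Q` and `Km` of the
#' MTX model are fixed constants and are never estimated.  Standard errors
#' come from the central-difference Hessian of the objective at the optimum;
#' per-subject conditional modes (empirical-Bayes etas) are refreshed there.
#'
#' @inheritParams neg2ll
#' @param init initial population parameters; also defines the covariate
#'   structure being fitted
#' @param fixed character vector of parameter names held at their `init`
#'   values (e.g. `"omega2_vp"`); structural constants `q_fixed`/`km_fixed`
#'   are always fixed
#' @param estimate_se compute standard errors (adds one Hessian evaluation)
#' @param method `"foce"` optimizes the conditional-mode (FOCE/Laplace)
#'   objective by quasi-Newton search -- the default, and well suited to the
#'   closed-form CPG2 model; `"its"` is iterated two-stage estimation
#'   (alternating per-subject MAP estimation with analytic moment updates of
#'   the typical values, IIV variances and residual variance) -- the
#'   recommended setting for the stiff coupled MTX model, whose marginal
#'   objective is expensive and rugged under direct search; `"fo"` is the
#'   first-order approximation (linearization about eta = 0) and `"fo-foce"`
#'   refines an FO optimum under FOCE
#' @return object of class `pk_fit` with elements `theta` (natural-scale
#'   estimates), `se`, `ofv`, `etas`, `pop` (updated parameter object),
#'   `converged`, and bookkeeping fields
#' @export
fit_population <- function(cohort, init, model = c("cpg2", "cpg2-mtx"),
                           cpg2_fits = NULL, fixed = character(),
                           estimate_se = TRUE, units_per_mg = 1000,
                           method = c("foce", "its", "fo", "fo-foce"),
                           control = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (length(cohort) == 0) stop("cannot fit an empty cohort")
  ctrl <- .est_control(control)
  ctxs <- if (model == "cpg2") .context_cpg2(cohort, units_per_mg, ctrl)
          else .context_mtx(cohort, cpg2_fits, units_per_mg, ctrl)
  meta <- if (model == "cpg2") .cpg2_meta(init) else .mtx_meta(init)
  par0 <- .pack(init, meta)
  free <- !(meta$name %in% fixed)
  if (!any(free)) stop("no free parameters to estimate")

  warm <- new.env(parent = emptyenv())
  warm$etas <- vector("list", length(ctxs))

  make_obj <- function(approx) function(pf) {
    par <- par0; par[free] <- pf
    pop <- .unpack(par, meta, init)
    omega2 <- .omega2_of(pop, model)
    sigma <- .sigma_of(pop, model)
    total <- 0
    for (i in seq_along(ctxs)) {
      cx <- ctxs[[i]]
      if (approx == "fo") {
        nll2 <- tryCatch(
          .fo_subject(cx$y, function(eta) cx$f_fun(pop, eta),
                      omega2, sigma, cx$etype, ctrl = ctrl),
          error = function(e) NA_real_)
        if (!is.finite(nll2)) return(1e10)
      } else {
        li <- tryCatch(
          .laplace_subject(cx$y, function(eta) cx$f_fun(pop, eta),
                           omega2, sigma, cx$etype,
                           eta0 = warm$etas[[i]], ctrl = ctrl),
          error = function(e) NULL)
        if (is.null(li) || !is.finite(li$nll2)) return(1e10)
        warm$etas[[i]] <- li$eta
        nll2 <- li$nll2
      }
      total <- total + nll2
    }
    if (ctrl$trace > 0) cat(sprintf("[%s] OFV %.4f\n", approx, total))
    total
  }

  np <- sum(free)
  run_opt <- function(start, approx, maxit) {
    # finite-difference steps must stay above the integration noise of the
    # adaptive ODE solver, so the differencing width is set explicitly
    optim(start, make_obj(approx), method = "L-BFGS-B",
          lower = meta$lower[free], upper = meta$upper[free],
          control = list(maxit = maxit,
                         factr = ctrl$rel.tol / .Machine$double.eps,
                         ndeps = rep(ctrl$ndeps, np)))
  }
  if (method == "its") {
    its <- .run_its(ctxs, cohort, init, model, fixed, ctrl)
    pop_hat <- its$pop
    par_hat <- .pack(pop_hat, meta)
    opt <- list(convergence = if (its$converged) 0L else 1L,
                message = its$message, counts = c(its$iterations, NA))
    opt$par <- par_hat[free]
  } else if (method == "fo-foce") {
    opt_fo <- run_opt(par0[free], "fo", ctrl$iter.max)
    opt <- run_opt(opt_fo$par, "foce", ctrl$iter.max)
  } else {
    opt <- run_opt(par0[free], method, ctrl$iter.max)
  }
  obj <- make_obj(if (method == "fo") "fo" else "foce")
  par_hat <- par0; par_hat[free] <- opt$par
  pop_hat <- .unpack(par_hat, meta, init)

  se <- rep(NA_real_, nrow(meta))
  if (estimate_se) {
    H <- tryCatch(optimHess(opt$par, obj,
                            control = list(ndeps = rep(ctrl$ndeps, np))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov_log)) {
        d <- diag(cov_log)
        d[d < 0] <- NA
        se_t <- sqrt(d)
        nat <- vapply(which(free), function(i) {
          if (meta$trans[i] == "log") exp(par_hat[i]) else 1
        }, numeric(1))
        se[free] <- se_t * nat   # delta method for log-scale parameters
      }
    }
  }

  final <- neg2ll(pop_hat, cohort, model = model, cpg2_fits = cpg2_fits,
                  units_per_mg = units_per_mg, control = control)
  theta <- setNames(vapply(meta$name, function(n) pop_hat[[n]], numeric(1)),
                    meta$name)
  structure(list(model = model, method = method, theta = theta,
                 se = setNames(se, meta$name),
                 ofv = as.numeric(final), etas = attr(final, "etas"),
                 pop = pop_hat,
                 converged = opt$convergence == 0,
                 message = opt$message,
                 iterations = unname(opt$counts[1]),
                 n_subjects = length(ctxs), fixed = fixed,
                 units_per_mg = units_per_mg, control = ctrl),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("population fit (%s): %d subjects, OFV %.3f, %s\n",
              x$model, x$n_subjects, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = signif(x$theta, 4),
                    se = signif(x$se, 3))
  print(tab)
  invisible(x)
}

#' Empirical-Bayes (MAP) individual estimation
#'
#' With population parameters fixed, maximizes the per-subject posterior
#' over the random effects given (a subset of) the subject's observations,
#' returning the individual parameters and conditional-mode deviations.
#' With no usable observations the prior mode (eta = 0, covariate-model
#' typical values) is returned with `no_obs = TRUE`.
#'
#' @inheritParams neg2ll
#' @param subject a `pk_subject`
#' @param pop fixed population parameters (typically a final model)
#' @param obs optional replacement observation table (e.g. a sampling
#'   subset); defaults to the subject's own observations
#' @param cpg2_fit for `"cpg2-mtx"`: the subject's CPG2 parameters
#'   (`list(cl=, v=)`)
#' @return list of class `pk_map`: `eta`, `params` (individual parameters),
#'   `deviance` (penalized deviance at the mode), `no_obs`
#' @export
map_estimate <- function(subject, pop, model = c("cpg2", "cpg2-mtx"),
                         obs = NULL, cpg2_fit = NULL, units_per_mg = 1000,
                         control = list()) {
  model <- match.arg(model)
  ctrl <- .est_control(control)
  if (is.null(control$inner.starts)) ctrl$inner.starts <- "wide"
  s <- subject
  if (!is.null(obs)) s$obs <- obs
  ctx <- if (model == "cpg2") .context_cpg2(list(s), units_per_mg, ctrl)[[1]]
         else .context_mtx(list(s), list(cpg2_fit), units_per_mg, ctrl)[[1]]
  omega2 <- .omega2_of(pop, model)
  li <- .laplace_subject(ctx$y, function(eta) ctx$f_fun(pop, eta),
                         omega2, .sigma_of(pop, model), ctx$etype,
                         ctrl = ctrl)
  params <- if (model == "cpg2") cpg2_individual(pop, s$covariates, li$eta)
            else mtx_individual(pop, s$covariates, li$eta)
  structure(list(eta = li$eta, params = params, deviance = li$deviance,
                 fitted = li$pred, times = ctx$times,
                 no_obs = isTRUE(li$no_obs), model = model),
            class = "pk_map")
}

#' Post hoc CPG2 parameters for a cohort
#'
#' MAP estimation of each subject's CPG2 clearance and volume under a fixed
#' CPG2 population model; the coupled MTX model consumes these as the
#' catalyst forcing, mirroring the sequential popPK -> popPK-PD analysis.
#'
#' @inheritParams neg2ll
#' @param pop_cpg2 fixed CPG2 population model
#' @return list (one element per subject) of `list(cl, v, eta)`
#' @export
cpg2_posthoc <- function(cohort, pop_cpg2, units_per_mg = 1000,
                         control = list()) {
  lapply(cohort, function(s) {
    m <- map_estimate(s, pop_cpg2, model = "cpg2",
                      units_per_mg = units_per_mg, control = control)
    list(cl = m$params$cl, v = m$params$v, eta = m$eta)
  })
}
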