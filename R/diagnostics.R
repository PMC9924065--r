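# Goodness of fit, nonparametric bootstrap, and visual predictive check.

#' Goodness-of-fit table
#'
#' For every quantifiable observation used in the fit, the population
#' prediction (PRED, random effects at zero), the individual prediction
#' (IPRED, random effects at the empirical-Bayes conditional mode) and the
#' conditional weighted residual (CWRES).  CWRES standardizes the residual
#' by the model covariance implied by the first-order expansion of the
#' subject's prediction about the conditional mode:
#' \eqn{y - (f(\hat\eta) - J\hat\eta)} scaled by
#' \eqn{chol(J \Omega J' + V)^{-1}}, with V the residual variance at IPRED.
#'
#' @inheritParams neg2ll
#' @param fit a [fit_population()] result
#' @return data.frame with columns `id`, `time`, `nominal`, `analyte`,
#'   `observed`, `pred`, `ipred`, `cwres`
#' @export
gof_table <- function(cohort, fit, cpg2_fits = NULL, control = list()) {
  stopifnot(inherits(fit, "pk_fit"))
  ctrl <- .est_control(control)
  model <- fit$model
  pop <- fit$pop
  ctxs <- if (model == "cpg2")
    .context_cpg2(cohort, fit$units_per_mg, ctrl)
  else .context_mtx(cohort, cpg2_fits, fit$units_per_mg, ctrl)
  omega2 <- .omega2_of(pop, model)
  sigma <- .sigma_of(pop, model)
  analyte <- if (model == "cpg2") "CPG2" else "MTX"

  rows <- list()
  for (i in seq_along(ctxs)) {
    cx <- ctxs[[i]]
    if (length(cx$y) == 0) next
    s <- cohort[[i]]
    o <- s$obs[s$obs$analyte == analyte & !s$obs$blq, , drop = FALSE]
    pred <- cx$f_fun(pop, numeric(length(omega2)))
    li <- .laplace_subject(cx$y, function(eta) cx$f_fun(pop, eta),
                           omega2, sigma, cx$etype, ctrl = ctrl,
                           want_curvature = TRUE)
    ipred <- li$pred
    if (!is.null(li$J)) {
      ea <- li$eta[li$active]
      E <- ipred - drop(li$J %*% ea)
      Cov <- li$J %*% (omega2[li$active] * t(li$J)) + diag(li$v,
                                                           length(li$v))
      cw <- drop(solve(t(chol(Cov)), cx$y - E))
    } else {
      v <- if (cx$etype == "add") rep(sigma^2, length(cx$y))
           else sigma^2 * (ipred^2 + ctrl$prop_floor^2)
      cw <- (cx$y - ipred) / sqrt(v)
    }
    rows[[length(rows) + 1]] <- data.frame(
      id = s$id, time = o$time, nominal = o$nominal, analyte = analyte,
      observed = cx$y, pred = pred, ipred = ipred, cwres = cw,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits each replicate from the
#' original estimates, and reports per-parameter medians and 2.5/97.5
#' percentile confidence intervals over the converged replicates, together
#' with the convergence fraction.  Replicates are drawn from a single master
#' seed and the whole procedure is reproducible.
#'
#' @inheritParams neg2ll
#' @param fit the original [fit_population()] result (defines model,
#'   starting values and potency constant)
#' @param n_boot number of bootstrap replicates
#' @param seed master RNG seed
#' @return list of class `pk_boot`: `estimates` (replicate x parameter
#'   matrix, non-converged rows dropped), `summary` (original estimate,
#'   median, ci_lo, ci_hi), `converged_fraction`, `n_boot`
#' @export
bootstrap_fit <- function(cohort, fit, n_boot = 1000, seed = 1,
                          cpg2_fits = NULL, control = list()) {
  stopifnot(inherits(fit, "pk_fit"))
  n <- length(cohort)
  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  est <- matrix(NA_real_, n_boot, length(fit$theta),
                dimnames = list(NULL, names(fit$theta)))
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- idx_mat[b, ]
    boot_cohort <- structure(unclass(cohort)[idx], class = "pk_cohort")
    boot_cpg2 <- if (!is.null(cpg2_fits)) cpg2_fits[idx] else NULL
    f <- tryCatch(
      fit_population(boot_cohort, fit$pop, model = fit$model,
                     cpg2_fits = boot_cpg2, fixed = fit$fixed,
                     estimate_se = FALSE, method = fit$method,
                     units_per_mg = fit$units_per_mg, control = control),
      error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      est[b, ] <- f$theta
      ok[b] <- TRUE
    }
  }
  kept <- est[ok, , drop = FALSE]
  smry <- data.frame(
    parameter = names(fit$theta),
    original = unname(fit$theta),
    median = apply(kept, 2, median),
    ci_lo = apply(kept, 2, quantile, probs = 0.025, names = FALSE),
    ci_hi = apply(kept, 2, quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(estimates = kept, summary = smry,
                 converged_fraction = mean(ok), n_boot = n_boot,
                 seed = seed),
            class = "pk_boot")
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("bootstrap: %d replicates, %.1f%% converged\n",
              x$n_boot, 100 * x$converged_fraction))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the cohort's own design (times,
#' doses, covariates), computes the 5th/50th/95th percentiles of observed
#' and simulated concentrations per nominal-time bin, and returns the
#' simulation-based 95% confidence envelope for each percentile.  Window
#' samples are binned by their window label.  Bins with no quantifiable
#' observations are dropped with a warning.
#'
#' @inheritParams neg2ll
#' @param n_sim number of simulated replicate datasets
#' @param seed RNG seed
#' @return list of class `vpc_result` with `bins` (a data.frame with
#'   observed percentiles and simulated envelopes) and `n_sim`
#' @export
vpc <- function(cohort, pop, model = c("cpg2", "cpg2-mtx"),
                cpg2_fits = NULL, n_sim = 1000, seed = 1,
                units_per_mg = 1000, control = list()) {
  model <- match.arg(model)
  ctrl <- .est_control(control)
  analyte <- if (model == "cpg2") "CPG2" else "MTX"
  omega2 <- .omega2_of(pop, model)
  sigma <- .sigma_of(pop, model)
  etype <- if (model == "cpg2") "add" else "prop"

  # design: all scheduled draws (including those censored in the data)
  design <- lapply(cohort, function(s)
    s$obs[s$obs$analyte == analyte, , drop = FALSE])
  ctxs_all <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    s$obs <- design[[i]]
    s$obs$blq <- FALSE   # predict at every scheduled time
    if (model == "cpg2") .context_cpg2(list(s), units_per_mg, ctrl)[[1]]
    else .context_mtx(list(s), list(cpg2_fits[[i]]), units_per_mg,
                      ctrl)[[1]]
  })
  nominal <- unlist(lapply(design, function(d) d$nominal))
  med_t <- tapply(unlist(lapply(design, function(d) d$time)), nominal,
                  median)
  bins <- names(sort(med_t))

  pctl <- function(v, nm) {
    out <- matrix(NA_real_, length(bins), 3,
                  dimnames = list(bins, c("p5", "p50", "p95")))
    for (b in bins) {
      x <- v[nm == b & !is.na(v)]
      if (length(x))
        out[b, ] <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    }
    out
  }

  obs_v <- unlist(lapply(design, function(d) ifelse(d$blq, NA, d$dv)))
  obs_p <- pctl(obs_v, nominal)
  empty <- rowSums(is.na(obs_p)) == 3
  if (any(empty))
    warning(sprintf("dropping empty VPC bins: %s",
                    paste(bins[empty], collapse = ", ")))

  set.seed(seed)
  sims <- array(NA_real_, c(n_sim, length(bins), 3))
  for (r in seq_len(n_sim)) {
    vals <- unlist(lapply(ctxs_all, function(cx) {
      eta <- rnorm(length(omega2), 0, sqrt(omega2))
      pred <- cx$f_fun(pop, eta)
      e <- apply_residual_error(pred, analyte, sigma)
      cz <- censor_assay(e$value, analyte)
      ifelse(cz$below_lloq | e$floored, NA, e$value)
    }))
    sims[r, , ] <- pctl(vals, nominal)
  }
  env <- function(j, pr) apply(sims[, , j, drop = FALSE], 2, quantile,
                               probs = pr, na.rm = TRUE, names = FALSE)
  tab <- data.frame(
    bin = bins, time = as.numeric(med_t[bins]),
    obs_p5 = obs_p[, 1], obs_p50 = obs_p[, 2], obs_p95 = obs_p[, 3],
    sim_p5_lo = env(1, 0.025), sim_p5_med = env(1, 0.5),
    sim_p5_hi = env(1, 0.975),
    sim_p50_lo = env(2, 0.025), sim_p50_med = env(2, 0.5),
    sim_p50_hi = env(2, 0.975),
    sim_p95_lo = env(3, 0.025), sim_p95_med = env(3, 0.5),
    sim_p95_hi = env(3, 0.975),
    stringsAsFactors = FALSE)
  tab <- tab[!empty, , drop = FALSE]
  tab <- tab[order(tab$time), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(bins = tab, n_sim = n_sim, analyte = analyte),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC (%s): %d bins, %d simulated replicates\n",
              x$analyte, nrow(x$bins), x$n_sim))
  print(x$bins[, c("bin", "time", "obs_p5", "obs_p50", "obs_p95")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
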