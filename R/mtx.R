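#' MTX compartment state
#'
#' @param xc amount in the central compartment, umol
#' @param xp amount in the peripheral compartment, umol
#' @param cum_renal cumulative renally eliminated amount, umol
#' @param cum_degraded cumulative catalytically degraded (plus first-order
#'   non-renal) amount, umol
#' @return named numeric state vector
#' @export
mtx_state <- function(xc = 0, xp = 0, cum_renal = 0, cum_degraded = 0) {
  if (any(c(xc, xp, cum_renal, cum_degraded) < 0))
    stop("state amounts must be non-negative")
  c(xc = xc, xp = xp, cum_renal = cum_renal, cum_degraded = cum_degraded)
}

#' Initialize compartment amounts from an observed concentration
#'
#' Estimation-oriented initialization when the MTX dosing history is not
#' carried: the central amount is `c0 * Vc` and the peripheral amount is set
#' at the distribution steady ratio `xp = xc * k12/k21`.
#'
#' @param c0 observed plasma MTX concentration, umol/L
#' @param params individual MTX parameters from [mtx_individual()]
#' @return state vector as in [mtx_state()]
#' @export
init_from_conc <- function(c0, params) {
  stopifnot(c0 >= 0)
  xc <- c0 * params$vc
  mtx_state(xc = xc, xp = xc * params$k12 / params$k21)
}

#' MTX model right-hand side
#'
#' Time derivative of the two-compartment MTX system with renal elimination,
#' optional first-order non-renal elimination (`knr_de`, 0 in the final
#' model) and catalyst-driven Michaelis-Menten decomposition,
#' \deqn{dXc/dt = R_{inf} - (Kr + Knr + K12) Xc + K21 Xp -
#'       \alpha C_{CPG2} [Xc]/(Km + [Xc])}
#' with \eqn{[Xc] = Xc/Vc} in umol/L.  The half-saturation property holds by
#' construction: at \eqn{[Xc] = Km} the Michaelis-Menten elimination rate is
#' \eqn{Vmax/2} with \eqn{Vmax = \alpha C_{CPG2}}.  With `cpg2 = 0` the
#' system is exactly the linear two-compartment model.
#'
#' @param t time, h (unused by the autonomous part; kept for deSolve
#'   compatibility)
#' @param state state vector as from [mtx_state()]
#' @param params individual MTX parameters from [mtx_individual()]
#' @param cpg2 plasma CPG2 concentration at `t`, mg/L
#' @param infusion_rate active MTX infusion rate, umol/h
#' @return named list whose first element is the derivative vector
#' @export
mtx_rhs <- function(t, state, params, cpg2 = 0, infusion_rate = 0) {
  xc <- state[["xc"]]; xp <- state[["xp"]]
  conc <- xc / params$vc
  mm <- params$alpha * cpg2 * conc / (params$km + conc)
  dxc <- infusion_rate - (params$kr + params$knr_de + params$k12) * xc +
    params$k21 * xp - mm
  list(c(xc = dxc,
         xp = params$k12 * xc - params$k21 * xp,
         cum_renal = params$kr * xc,
         cum_degraded = mm + params$knr_de * xc),
       cpg2 = cpg2)
}

# Closed-form amounts (xc, xp) of the linear two-compartment system (no
# catalyst) at time `t_end`, starting from zero before the first infusion.
# Used for the pre-CPG2 dosing history, which is linear because the final
# model has no first-order non-renal elimination (and CPG2 is absent).
.linear_amounts_at <- function(mtx_inf, p, t_end) {
  ke <- p$kr + p$knr_de
  A <- rbind(c(-(ke + p$k12), p$k21),
             c(p$k12, -p$k21))
  ev <- eigen(A)
  V <- ev$vectors; Vi <- solve(V); d <- ev$values
  expA <- function(dt) V %*% (exp(d * dt) * Vi)
  knots <- sort(unique(c(mtx_inf[, 1], mtx_inf[, 2], t_end)))
  knots <- knots[knots <= t_end]
  x <- c(0, 0)
  for (k in seq_len(length(knots) - 1)) {
    a <- knots[k]; b <- knots[k + 1]
    rate <- sum(mtx_inf[a >= mtx_inf[, 1] - 1e-12 & a < mtx_inf[, 2], 3])
    E <- expA(b - a)
    x <- drop(E %*% x)
    if (rate > 0)
      x <- x + drop(solve(A, (E - diag(2)) %*% c(rate, 0)))
  }
  x
}

# Build the infusion table (start, end, rate) for one analyte.
# CPG2 rates are mg/h (after potency conversion); MTX rates umol/h.
.infusion_table <- function(doses, analyte, units_per_mg) {
  d <- doses[doses$analyte == analyte & doses$duration > 0, , drop = FALSE]
  if (nrow(d) == 0)
    return(matrix(numeric(0), ncol = 3))
  amt <- if (analyte == "CPG2") d$amount / units_per_mg else d$amount
  cbind(start = d$time, end = d$time + d$duration, rate = amt / d$duration)
}

#' Simulate the coupled CPG2-MTX system
#'
#' Integrates the MTX compartment system with the plasma CPG2 concentration
#' supplied as a closed-form forcing function.  A stiff-capable adaptive
#' integrator (`deSolve::lsoda`) is used and the integration is restarted at
#' every dose-event boundary (infusion start/end, bolus), since the
#' Michaelis-Menten term switches on sharply when CPG2 appears.
#'
#' @param doses dose-event data.frame covering both analytes (see
#'   [dose_event()]); MTX rows with `duration == 0` are boluses
#' @param p_mtx individual MTX parameters from [mtx_individual()]
#' @param p_cpg2 individual CPG2 parameters (elements `cl`, `v`); may be
#'   `NULL` when no CPG2 doses are present
#' @param times output time grid, h (may start before 0; phase-2 histories
#'   carry the HD-MTX infusion at negative times)
#' @param init initial state at `min(times, dose times)`; default all-zero
#' @param units_per_mg CPG2 potency constant, see [cpg2_conc()]
#' @param rtol,atol integrator tolerances
#' @param engine `"C"` (compiled right-hand side, default) or `"R"` (pure-R
#'   reference implementation of the same model)
#' @return data.frame with columns `time`, `xc`, `xp`, `cum_renal`,
#'   `cum_degraded`, `conc` (plasma MTX, umol/L), `cpg2` (plasma CPG2, mg/L)
#'   and `dosed` (cumulative MTX amount administered, umol)
#' @export
solve_mtx <- function(doses, p_mtx, p_cpg2 = NULL, times,
                      init = NULL, units_per_mg = 1000,
                      rtol = 1e-8, atol = 1e-10,
                      engine = c("C", "R")) {
  engine <- match.arg(engine)
  stopifnot(length(times) >= 1)
  times <- sort(unique(times))
  if (is.null(p_cpg2)) {
    if (any(doses$analyte == "CPG2"))
      stop("CPG2 doses present but `p_cpg2` not supplied")
    p_cpg2 <- list(cl = 1, v = 1)
  }

  cpg2_inf <- .infusion_table(doses, "CPG2", units_per_mg)
  mtx_inf  <- .infusion_table(doses, "MTX", units_per_mg)
  bolus <- doses[doses$analyte == "MTX" & doses$duration == 0, , drop = FALSE]

  t0 <- min(c(times[1], doses$time))
  tend <- max(times)
  knots <- sort(unique(c(t0, tend,
                         cpg2_inf[, 1:2], mtx_inf[, 1:2], bolus$time)))
  knots <- knots[knots >= t0 & knots <= tend]

  y <- if (is.null(init)) mtx_state() else init
  stopifnot(length(y) == 4)

  if (engine == "C") {
    parms <- c(p_mtx$kr, p_mtx$k12, p_mtx$k21, p_mtx$knr_de,
               p_mtx$alpha, p_mtx$km, p_mtx$vc,
               p_cpg2$cl, p_cpg2$v,
               nrow(cpg2_inf), t(cpg2_inf),
               nrow(mtx_inf), t(mtx_inf))
    if (length(parms) > 400)
      stop("too many dose events for the compiled model (max ~60)")
    parms <- c(parms, numeric(400 - length(parms)))
  } else {
    cpg2_pars <- p_cpg2
    rhs_r <- function(t, y, parms) {
      cc <- if (nrow(cpg2_inf) > 0)
        cpg2_conc(t, doses, cpg2_pars, units_per_mg) else 0
      inr <- if (nrow(mtx_inf) > 0)
        sum(mtx_inf[t >= mtx_inf[, 1] & t < mtx_inf[, 2], 3]) else 0
      mtx_rhs(t, y, p_mtx, cpg2 = cc, infusion_rate = inr)
    }
  }

  out_t <- numeric(0); out_y <- NULL
  record <- function(tt, yy, cc) {
    out_t <<- c(out_t, tt)
    out_y <<- rbind(out_y, c(yy, cc))
  }
  cc_at <- function(tt) {
    if (nrow(cpg2_inf) > 0) cpg2_conc(tt, doses, p_cpg2, units_per_mg) else 0
  }
  if (times[1] == t0) record(t0, y, cc_at(t0))

  for (k in seq_len(length(knots) - 1)) {
    a <- knots[k]; b <- knots[k + 1]
    # apply boluses scheduled at the segment start
    hit <- which(abs(bolus$time - a) < 1e-12)
    if (length(hit)) y[1] <- y[1] + sum(bolus$amount[hit])
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    run_seg <- function(rt, at) {
      suppressWarnings(
        if (engine == "C") {
          deSolve::lsoda(y, seg_times, func = "cpg2mtx_derivs",
                         parms = parms, dllname = "cpg2mtx",
                         initfunc = "cpg2mtx_init",
                         nout = 1, outnames = "cpg2",
                         rtol = rt, atol = at, maxsteps = 50000)
        } else {
          deSolve::lsoda(y, seg_times, func = rhs_r, parms = NULL,
                         rtol = rt, atol = at, maxsteps = 50000)
        })
    }
    # relaxed-tolerance retries: the Michaelis-Menten switch-on can defeat
    # the corrector at extreme parameter trials during estimation
    sol <- run_seg(rtol, atol)
    if (attr(sol, "istate")[1] < 0) sol <- run_seg(rtol * 100, atol * 1e4)
    if (attr(sol, "istate")[1] < 0) sol <- run_seg(1e-4, 1e-4)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol)))
      stop(sprintf("ODE solver failed in segment [%g, %g] h", a, b))
    y <- unname(sol[nrow(sol), 2:5])
    names(y) <- c("xc", "xp", "cum_renal", "cum_degraded")
    keep <- sol[, 1] %in% times & sol[, 1] > a
    if (any(keep))
      for (i in which(keep)) record(sol[i, 1], sol[i, 2:5], sol[i, 6])
  }

  out <- data.frame(time = out_t,
                    xc = out_y[, 1], xp = out_y[, 2],
                    cum_renal = out_y[, 3], cum_degraded = out_y[, 4])
  out$conc <- out$xc / p_mtx$vc
  out$cpg2 <- out_y[, 5]
  # cumulative MTX dose administered by each output time
  dosed <- numeric(length(out_t))
  if (nrow(mtx_inf) > 0)
    for (i in seq_len(nrow(mtx_inf))) {
      frac <- pmin(pmax((out_t - mtx_inf[i, 1]) /
                          (mtx_inf[i, 2] - mtx_inf[i, 1]), 0), 1)
      dosed <- dosed + frac * mtx_inf[i, 3] * (mtx_inf[i, 2] - mtx_inf[i, 1])
    }
  if (nrow(bolus) > 0)
    for (i in seq_len(nrow(bolus)))
      dosed <- dosed + (out_t >= bolus$time[i] - 1e-12) * bolus$amount[i]
  out$dosed <- dosed
  rownames(out) <- NULL
  out
}
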