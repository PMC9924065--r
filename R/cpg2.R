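#' Dose events
#'
#' One row per administration.  CPG2 doses are recorded in units (U) and
#' converted to mass by the potency constant at simulation time; MTX doses
#' are recorded in umol.  `duration` must be positive for infusions; a zero
#' duration denotes a bolus (MTX only).
#'
#' @param time start of administration, h
#' @param amount dose amount (U for CPG2, umol for MTX)
#' @param duration infusion duration, h (CPG2 is given over 5 min = 1/12 h)
#' @param analyte `"CPG2"` or `"MTX"`
#' @return data.frame with one row per event
#' @export
dose_event <- function(time, amount, duration, analyte = c("CPG2", "MTX")) {
  analyte <- match.arg(analyte)
  stopifnot(time >= -Inf, amount > 0, duration >= 0)
  if (analyte == "CPG2" && duration <= 0)
    stop("CPG2 doses are infusions and need duration > 0")
  data.frame(time = time, amount = amount, duration = duration,
             analyte = analyte, stringsAsFactors = FALSE)
}

#' Plasma CPG2 concentration (closed form)
#'
#' One-compartment intravenous-infusion model with first-order elimination,
#' evaluated as a superposition over all CPG2 dose events.  Doses in U are
#' converted to mg by `units_per_mg`; concentrations are mg/L.
#'
#' The no-elimination limit (CL = 0) is handled exactly: the concentration at
#' the end of an infusion is then total infused mass / V.
#'
#' @param t times, h (vectorized; must be non-negative relative to nothing in
#'   particular -- times before the first dose give 0)
#' @param doses dose-event data.frame (rows with `analyte != "CPG2"` are
#'   ignored)
#' @param params individual parameters with elements `cl` (L/h) and `v` (L),
#'   e.g. from [cpg2_individual()]
#' @param units_per_mg CPG2 potency, U per mg.  The label potency of the
#'   product is not public; this constant is used only to map simulated doses
#'   onto the concentration scale and cancels in any fit that uses the same
#'   value.  Default 1000 U/mg.
#' @return concentrations, mg/L, same length as `t`
#' @export
cpg2_conc <- function(t, doses, params, units_per_mg = 1000) {
  if (any(!is.finite(t))) stop("times must be finite")
  d <- doses[doses$analyte == "CPG2", , drop = FALSE]
  .cpg2_conc_core(t, d$time, d$duration,
                  d$amount / units_per_mg / d$duration,
                  params$cl, params$v)
}

# Superposition kernel on pre-extracted infusion vectors (mg/h rates).
.cpg2_conc_core <- function(t, t0, dur, rate, cl, v) {
  stopifnot(v > 0, cl >= 0)
  ke <- cl / v
  conc <- numeric(length(t))
  for (i in seq_along(t0)) {
    te <- pmin(pmax(t - t0[i], 0), dur[i])   # time spent infusing
    post <- pmax(t - t0[i] - dur[i], 0)      # time since infusion end
    if (ke > 1e-12) {
      conc <- conc + rate[i] / cl * (1 - exp(-ke * te)) * exp(-ke * post)
    } else {
      conc <- conc + rate[i] * te / v        # no-elimination limit
    }
  }
  conc
}
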