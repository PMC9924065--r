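# Covariate screening and forward-backward stepwise selection for the CPG2
# popPK model.  Candidates enter one at a time as power functions on CL or V
# (theta_i = tv_theta x covariate^theta), compared by the likelihood-ratio
# test on the change in OFV.

.with_covariate <- function(pop, param, candidate, exponent = 1) {
  if (param == "cl") {
    pop$cov_cl <- candidate
    pop$theta_cl <- if (is.na(candidate)) 0 else exponent
  } else {
    pop$cov_v <- candidate
    pop$theta_v <- if (is.na(candidate)) 0 else exponent
  }
  pop
}

#' Screen covariates for the CPG2 model
#'
#' Fits, one at a time, a power covariate model on CL and on V for every
#' candidate, and reports the drop in OFV relative to the base model with
#' the chi-square (1 df) p-value, sorted by delta-OFV.  Candidates whose fit
#' fails are reported as not calculated (`NA`).
#'
#' @param cohort a `pk_cohort`
#' @param base base population model ([cpg2_pop_params()]); its fit defines
#'   the reference OFV
#' @param candidates covariate names to screen (must exist in the subjects'
#'   covariates), e.g. `c("bsa", "weight", "height")`
#' @param units_per_mg CPG2 potency constant
#' @param method estimation method, see [fit_population()].  Whatever the
#'   fitting method, the reported delta-OFV is always the FOCE objective
#'   evaluated at the two fits' estimates
#' @param control estimation settings passed to [fit_population()]
#' @return data.frame with columns `model`, `parameter`, `covariate`,
#'   `delta_ofv`, `df`, `p_value`
#' @export
screen_covariates <- function(cohort, base,
                              candidates = c("bsa", "weight", "height"),
                              units_per_mg = 1000, method = "foce",
                              control = list()) {
  if (length(candidates) == 0)
    return(data.frame(model = character(), parameter = character(),
                      covariate = character(), delta_ofv = numeric(),
                      df = integer(), p_value = numeric()))
  base_fit <- fit_population(cohort, base, model = "cpg2",
                             estimate_se = FALSE, method = method,
                             units_per_mg = units_per_mg, control = control)
  rows <- list()
  for (param in c("cl", "v")) {
    for (cand in candidates) {
      cand_pop <- .with_covariate(base_fit$pop, param, cand)
      fit <- tryCatch(
        fit_population(cohort, cand_pop, model = "cpg2",
                       estimate_se = FALSE, method = method,
                       units_per_mg = units_per_mg,
                       control = control),
        error = function(e) NULL)
      d <- if (is.null(fit)) NA_real_ else base_fit$ofv - fit$ofv
      rows[[length(rows) + 1]] <- data.frame(
        model = sprintf("%s ~ %s", toupper(param), cand),
        parameter = param, covariate = cand,
        delta_ofv = d, df = 1L,
        p_value = if (is.na(d)) NA_real_ else pchisq(max(d, 0), 1,
                                                     lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$delta_ofv, na.last = TRUE), , drop = FALSE]
}

#' Forward-backward stepwise covariate selection
#'
#' Forward inclusion: at each step every candidate not yet on a parameter is
#' tried; the largest OFV drop wins and is kept if it exceeds the
#' likelihood-ratio threshold (default p < 0.001, i.e. delta-OFV > 10.828
#' per degree of freedom).  When competing additions change the same number
#' of degrees of freedom the largest OFV drop is also the smallest AIC, so
#' the AIC tie-break is implied.  Backward elimination then removes any
#' included covariate whose loss costs less than the same threshold.
#'
#' @inheritParams screen_covariates
#' @param p_enter,p_remove significance levels for inclusion / elimination
#' @param max_steps cap on forward-backward sweeps (guards cycling)
#' @param method estimation method, see [fit_population()]
#' @return list with `pop` (selected model parameters), `fit` (its
#'   [fit_population()] result), `selected` (named covariates on `cl`/`v`)
#'   and `history` (data.frame of tried steps)
#' @export
stepwise_select <- function(cohort, base,
                            candidates = c("bsa", "weight", "height"),
                            p_enter = 0.001, p_remove = 0.001,
                            units_per_mg = 1000, method = "foce",
                            control = list(), max_steps = 6) {
  fit_one <- function(pop)
    fit_population(cohort, pop, model = "cpg2", estimate_se = FALSE,
                   method = method, units_per_mg = units_per_mg,
                   control = control)
  cur_fit <- fit_one(base)
  history <- list()
  note <- function(action, label, d, kept)
    history[[length(history) + 1]] <<- data.frame(
      action = action, term = label, delta_ofv = d, kept = kept,
      stringsAsFactors = FALSE)

  for (sweep in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    repeat {
      slots <- c(cl = is.na(cur_fit$pop$cov_cl), v = is.na(cur_fit$pop$cov_v))
      open <- names(slots)[slots]
      if (length(open) == 0) break
      best <- NULL
      for (param in open) {
        for (cand in candidates) {
          f <- tryCatch(fit_one(.with_covariate(cur_fit$pop, param, cand)),
                        error = function(e) NULL)
          if (is.null(f)) next
          d <- cur_fit$ofv - f$ofv
          if (is.null(best) || d > best$d)
            best <- list(d = d, fit = f, param = param, cand = cand)
        }
      }
      if (is.null(best)) break
      lab <- sprintf("%s ~ %s", toupper(best$param), best$cand)
      if (best$d > lrt_threshold(1, p_enter)) {
        note("add", lab, best$d, TRUE)
        cur_fit <- best$fit
        changed <- TRUE
      } else {
        note("add", lab, best$d, FALSE)
        break
      }
    }
    # backward
    for (param in c("cl", "v")) {
      cov_now <- if (param == "cl") cur_fit$pop$cov_cl else cur_fit$pop$cov_v
      if (is.na(cov_now)) next
      f <- tryCatch(fit_one(.with_covariate(cur_fit$pop, param, NA)),
                    error = function(e) NULL)
      if (is.null(f)) next
      d <- f$ofv - cur_fit$ofv   # cost of removal
      lab <- sprintf("%s ~ %s", toupper(param), cov_now)
      if (d < lrt_threshold(1, p_remove)) {
        note("remove", lab, d, TRUE)
        cur_fit <- f
        changed <- TRUE
      } else {
        note("remove", lab, d, FALSE)
      }
    }
    if (!changed) break
  }
  list(pop = cur_fit$pop, fit = cur_fit,
       selected = c(cl = cur_fit$pop$cov_cl, v = cur_fit$pop$cov_v),
       history = if (length(history)) do.call(rbind, history)
                 else data.frame())
}
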