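# Limited-sampling-strategy evaluation: Bayesian forecasting of the 48-h
# plasma MTX concentration from subsets of the phase-2 sampling points.

#' Candidate limited-sampling points
#'
#' The five nominal MTX sampling labels of the phase-2 schedule from which
#' forecasting subsets are drawn: pre-dose, 20 min, 2 h, the 5-8 h window,
#' and 24 h after the first CPG2 dose.
#'
#' @format character vector of length 5
#' @export
LSS_POINTS <- c("pre", "20min", "2h", "5-8h", "24h")

#' Forecast the 48-h MTX concentration by Bayesian estimation
#'
#' Restricts the subject's MTX observations to the given sampling subset,
#' obtains the empirical-Bayes (MAP) individual parameters under the fixed
#' population model, and forward-simulates the coupled system to 48 h after
#' the first CPG2 dose.
#'
#' @param subject a `pk_subject` (phase-2-like, with MTX observations)
#' @param pop MTX population model (typically [mtx_final_model()])
#' @param subset character vector of nominal sampling labels, non-empty
#'   subset of `c("pre", "20min", "2h", "5-8h", "24h")`
#' @param cpg2_fit subject's CPG2 individual parameters (`list(cl=, v=)`)
#' @param units_per_mg CPG2 potency constant
#' @param control estimation settings
#' @return predicted plasma MTX concentration at 48 h, umol/L
#' @export
forecast_48h <- function(subject, pop, subset, cpg2_fit,
                         units_per_mg = 1000, control = list()) {
  if (length(subset) == 0) stop("sampling subset must be non-empty")
  bad <- setdiff(subset, LSS_POINTS)
  if (length(bad))
    stop(sprintf("unknown sampling points: %s", paste(bad, collapse = ", ")))
  obs <- subject$obs[subject$obs$analyte == "MTX" &
                       subject$obs$nominal %in% subset, , drop = FALSE]
  m <- map_estimate(subject, pop, model = "cpg2-mtx", obs = obs,
                    cpg2_fit = cpg2_fit, units_per_mg = units_per_mg,
                    control = control)
  ctrl <- .est_control(control)
  out <- solve_mtx(subject$doses, m$params, cpg2_fit, times = 48,
                   units_per_mg = units_per_mg,
                   rtol = ctrl$ode.rtol, atol = ctrl$ode.atol)
  out$conc[match(48, out$time)]
}

#' Prediction-error metrics
#'
#' Mean error (bias), mean absolute error, and root-mean-squared error of
#' predictions against observations, in prediction units (`pred - obs`
#' convention).
#'
#' @param pred,obs numeric vectors of equal length (n >= 1)
#' @return list with `me`, `mae`, `rmse`
#' @examples
#' error_metrics(c(2, 0), c(1, 1))  # me 0, mae 1, rmse 1
#' @export
error_metrics <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  if (length(pred) < 1) stop("need at least one prediction")
  e <- pred - obs
  list(me = mean(e), mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Classification hit ratio at a concentration threshold
#'
#' Fraction of subjects for whom the predicted and reference concentrations
#' fall on the same side of the threshold.  A value exactly at the threshold
#' counts as "over" (`>=`), consistent with the redosing rule triggering at
#' concentrations above 1 umol/L.
#'
#' @param pred predicted concentrations, umol/L
#' @param truth reference concentrations, umol/L
#' @param threshold decision threshold, umol/L (> 0); default 1.0, the
#'   borderline for an additional CPG2 dose
#' @return concordant fraction between 0 and 1
#' @examples
#' hit_ratio(c(0.5, 2, 1.2), c(0.4, 3, 0.8))
#' @export
hit_ratio <- function(pred, truth, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be positive")
  if (length(pred) == 0 || length(truth) == 0)
    stop("empty concentration vectors")
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  mean((pred >= threshold) == (truth >= threshold))
}

#' Evaluate all limited-sampling subsets
#'
#' Runs the 48-h Bayesian forecast for every non-empty subset of the five
#' phase-2 sampling points (31 subsets), scoring each by ME/MAE/RMSE against
#' the 48-h reference concentration and by the hit ratio at 1.0 umol/L.
#' Subsets containing the 24-h point are flagged, mirroring the study's
#' black/white bar comparison.
#'
#' @param cohort phase-2-like `pk_cohort`
#' @param pop MTX population model
#' @param cpg2_fits per-subject CPG2 parameters (e.g. [cpg2_posthoc()]);
#'   when `NULL` each subject's simulated-truth CPG2 parameters are used
#' @param truth `"simulated"` scores against the error-free simulated 48-h
#'   concentration; `"observed"` scores against the error-perturbed 48-h
#'   observation, mirroring a clinical comparison
#' @param threshold hit-ratio threshold, umol/L
#' @param units_per_mg CPG2 potency constant
#' @param control estimation settings
#' @return data.frame of class `lss_report`, one row per subset, ranked by
#'   RMSE: `subset`, `n_points`, `contains_24h`, `n_subjects`, `me`, `mae`,
#'   `rmse`, `hit_ratio`
#' @export
evaluate_all_subsets <- function(cohort, pop, cpg2_fits = NULL,
                                 truth = c("simulated", "observed"),
                                 threshold = 1.0, units_per_mg = 1000,
                                 control = list()) {
  truth <- match.arg(truth)
  if (is.null(cpg2_fits))
    cpg2_fits <- lapply(cohort, function(s) s$truth$cpg2)
  ref <- vapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (truth == "simulated") s$truth$conc48
    else {
      o <- s$obs[s$obs$analyte == "MTX" & s$obs$nominal == "48h", ]
      if (nrow(o) == 0) NA_real_ else o$dv[1]
    }
  }, numeric(1))
  usable <- which(!is.na(ref))

  subsets <- unlist(lapply(seq_along(LSS_POINTS), function(k)
    utils::combn(LSS_POINTS, k, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(subsets, function(ss) {
    pred <- vapply(usable, function(i)
      forecast_48h(cohort[[i]], pop, ss, cpg2_fits[[i]],
                   units_per_mg = units_per_mg, control = control),
      numeric(1))
    m <- error_metrics(pred, ref[usable])
    data.frame(subset = paste(ss, collapse = "+"),
               n_points = length(ss),
               contains_24h = "24h" %in% ss,
               n_subjects = length(usable),
               me = m$me, mae = m$mae, rmse = m$rmse,
               hit_ratio = hit_ratio(pred, ref[usable], threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rmse), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lss_report", "data.frame")
  out
}

#' @export
print.lss_report <- function(x, ...) {
  cat(sprintf("limited-sampling evaluation: %d subsets, %d subjects\n",
              nrow(x), x$n_subjects[1]))
  print.data.frame(head(x, 10), row.names = FALSE, digits = 3)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
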