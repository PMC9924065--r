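#' Study design descriptor
#'
#' Encodes the two study layouts that the simulator reproduces.
#'
#' Phase 1 (healthy volunteers): two CPG2 dose groups (20 and 50 U/kg,
#' `n/2` subjects each), 5-min infusions at 0 and 48 h, CPG2 sampling at
#' 5 min, 15 min, 2, 8, 12, 24 and 48 h after the first dose and 5 min, 8,
#' 12, 24 and 48 h after the second (12 quantifiable samples per subject;
#' the pre-first-dose draw is identically zero and is not emitted).
#'
#' Phase 2 (delayed-MTX-excretion patients): 50 U/kg CPG2 at time 0, a
#' second 50 U/kg dose at 48 h when the true plasma MTX concentration still
#' exceeds 1 umol/L at the 46-h check; CPG2 sampling at pre-dose, 20 min, 2,
#' 5-8 (window), 12-20 (window), 24 and 48 h; MTX sampling at pre-dose,
#' 20 min, 2, 5-8 (window), 24, 48 h, plus 72 and 96 h when a second dose is
#' given.  Window times are drawn uniformly and recorded as realized times.
#'
#' @param phase 1 or 2
#' @param n_subjects cohort size (> 0); default 16 (phase 1) / 15 (phase 2)
#' @param dose_u_per_kg CPG2 dose(s), U/kg: length-2 for the phase-1 arms,
#'   scalar for phase 2
#' @param missing_prob per-scheduled-point probability that a sample is
#'   missing (the studies' sample accounting implies some missingness;
#'   default 0)
#' @return object of class `study_design`
#' @export
study_design <- function(phase, n_subjects = if (phase == 1) 16L else 15L,
                         dose_u_per_kg = if (phase == 1) c(20, 50) else 50,
                         missing_prob = 0) {
  stopifnot(phase %in% c(1, 2))
  if (n_subjects <= 0) stop("n_subjects must be positive")
  stopifnot(missing_prob >= 0, missing_prob < 1)
  if (phase == 1 && length(dose_u_per_kg) == 1)
    dose_u_per_kg <- rep(dose_u_per_kg, 2)
  structure(list(phase = phase, n_subjects = as.integer(n_subjects),
                 dose_u_per_kg = dose_u_per_kg,
                 missing_prob = missing_prob),
            class = "study_design")
}

#' Apply the residual error model
#'
#' CPG2 uses an additive error (`obs = pred + eps`, mg/L); MTX uses a
#' proportional error (`obs = pred * (1 + eps)`), with
#' `eps ~ Normal(0, sigma^2)`.  Negative results are floored at 0 and
#' flagged.
#'
#' @param pred predicted concentrations
#' @param analyte `"CPG2"` or `"MTX"`
#' @param sigma residual SD (mg/L for CPG2; fraction for MTX)
#' @param seed optional seed for a self-contained draw
#' @return list with `value` (observed) and `floored` (logical)
#' @export
apply_residual_error <- function(pred, analyte = c("CPG2", "MTX"),
                                 sigma, seed = NULL) {
  analyte <- match.arg(analyte)
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(length(pred), 0, sigma)
  obs <- if (analyte == "CPG2") pred + eps else pred * (1 + eps)
  floored <- obs < 0
  obs[floored] <- 0
  list(value = obs, floored = floored)
}

#' Assay censoring
#'
#' Flags values below the lower limit of quantification: 0.5 ng/ml for MTX
#' (0.0011 umol/L via the molar mass 454.44 g/mol) and 1 ng/ml (0.001 mg/L)
#' for CPG2.  Concentrations above the upper limit of quantification are
#' reported after dilution in routine practice, so no upper censoring is
#' applied.
#'
#' @param value concentrations (umol/L for MTX, mg/L for CPG2)
#' @param analyte `"CPG2"` or `"MTX"`
#' @return list with `value` (unchanged) and `below_lloq` (logical)
#' @export
censor_assay <- function(value, analyte = c("CPG2", "MTX")) {
  analyte <- match.arg(analyte)
  lloq <- if (analyte == "MTX") MTX_LLOQ_NG_ML / MTX_MOLAR_MASS
          else CPG2_LLOQ_NG_ML * 1e-3
  list(value = value, below_lloq = value < lloq)
}

# Nominal phase-1 sampling times (h) and labels, relative to the first dose.
.phase1_times <- function() {
  data.frame(
    nominal = c("5min", "15min", "2h", "8h", "12h", "24h", "48h",
                "d2+5min", "d2+8h", "d2+12h", "d2+24h", "d2+48h"),
    time = c(5 / 60, 0.25, 2, 8, 12, 24, 48,
             48 + 5 / 60, 56, 60, 72, 96),
    stringsAsFactors = FALSE)
}

.new_subject <- function(id, cov, doses, obs, truth, arm = NA) {
  structure(list(id = id, arm = arm, covariates = cov, doses = doses,
                 obs = obs, truth = truth),
            class = "pk_subject")
}

.obs_row <- function(time, nominal, analyte, tdv, sigma, missing_prob) {
  if (missing_prob > 0 && runif(1) < missing_prob) return(NULL)
  if (tdv == 0) {
    dv <- 0; blq <- TRUE
  } else {
    e <- apply_residual_error(tdv, analyte, sigma)
    cz <- censor_assay(e$value, analyte)
    dv <- cz$value
    blq <- cz$below_lloq | e$floored
  }
  data.frame(time = time, nominal = nominal, analyte = analyte,
             dv = dv, blq = blq, tdv = tdv, stringsAsFactors = FALSE)
}

.gen_phase1_subject <- function(id, dose_ukg, pop, missing_prob,
                                units_per_mg) {
  cov <- covariates(weight = runif(1, 54.3, 66.9),
                    height = runif(1, 162.6, 184.8),
                    age = runif(1, 20, 40),
                    scr = runif(1, 0.5, 1.1))
  eta <- rnorm(2, 0, sqrt(c(pop$omega2_cl, pop$omega2_v)))
  ind <- cpg2_individual(pop, cov, eta)
  amt <- dose_ukg * cov$weight
  doses <- rbind(dose_event(0, amt, 1 / 12, "CPG2"),
                 dose_event(48, amt, 1 / 12, "CPG2"))
  sched <- .phase1_times()
  tdv <- cpg2_conc(sched$time, doses, ind, units_per_mg)
  obs <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i)
    .obs_row(sched$time[i], sched$nominal[i], "CPG2", tdv[i],
             pop$sigma_add, missing_prob)))
  .new_subject(id, cov, doses, obs,
               truth = list(eta_cpg2 = eta,
                            cpg2 = list(cl = ind$cl, v = ind$v)),
               arm = dose_ukg)
}

.gen_phase2_subject <- function(id, dose_ukg, pop_cpg2, pop_mtx,
                                missing_prob, units_per_mg) {
  runif_log <- function(a, b) exp(runif(1, log(a), log(b)))
  for (try in 1:200) {
    weight <- runif_log(10.7, 78.1)
    # pediatric-to-adult allometry keeps height consistent with weight
    height <- 29.7 * weight^0.41 * exp(rnorm(1, 0, 0.05))
    cov <- covariates(weight = weight, height = height,
                      age = runif_log(1, 75), scr = runif_log(0.23, 3.47))
    scr_baseline <- cov$scr / runif(1, 1, 2.5)
    arf <- acute_renal_failure(scr_now = cov$scr,
                               scr_baseline = scr_baseline)
    dose_gm2 <- runif_log(2.9, 14.3)
    c0 <- runif_log(1.02, 692.32)
    hours_post <- runif(1, 22, 70)
    el <- eligible_for_cpg2(c0, hours_post, arf, dose_gm2)
    if (el$eligible) break
  }
  if (!el$eligible)
    stop("failed to draw an eligible phase-2 subject")

  eta_m <- rnorm(4, 0, sqrt(c(pop_mtx$omega2_clr, pop_mtx$omega2_vc,
                              pop_mtx$omega2_vp, pop_mtx$omega2_alpha)))
  p_mtx <- mtx_individual(pop_mtx, cov, eta_m)
  eta_c <- rnorm(2, 0, sqrt(c(pop_cpg2$omega2_cl, pop_cpg2$omega2_v)))
  p_cpg2 <- cpg2_individual(pop_cpg2, cov, eta_c)

  # HD-MTX 6-h infusion ending well before CPG2; pre-CPG2 kinetics are
  # linear, so the infused amount scales to the target baseline draw.
  unit_dose <- dose_event(-hours_post, 1, 6, "MTX")
  resp <- solve_mtx(unit_dose, p_mtx, times = c(-hours_post, 0))$conc[2]
  amt_umol <- c0 / resp
  doses <- rbind(dose_event(-hours_post, amt_umol, 6, "MTX"),
                 dose_event(0, dose_ukg * cov$weight, 1 / 12, "CPG2"))

  w58 <- runif(1, 5, 8)
  w1220 <- runif(1, 12, 20)
  conc46 <- solve_mtx(doses, p_mtx, p_cpg2, times = c(-hours_post, 46),
                      units_per_mg = units_per_mg)$conc[2]
  second <- conc46 > 1
  if (second)
    doses <- rbind(doses, dose_event(48, dose_ukg * cov$weight, 1 / 12,
                                     "CPG2"))

  cpg2_sched <- data.frame(
    nominal = c("pre", "20min", "2h", "5-8h", "12-20h", "24h", "48h"),
    time = c(0, 1 / 3, 2, w58, w1220, 24, 48), stringsAsFactors = FALSE)
  mtx_nom <- c("pre", "20min", "2h", "5-8h", "24h", "48h")
  mtx_t <- c(0, 1 / 3, 2, w58, 24, 48)
  if (second) {
    mtx_nom <- c(mtx_nom, "72h", "96h")
    mtx_t <- c(mtx_t, 72, 96)
  }
  all_t <- sort(unique(c(mtx_t, 0)))
  prof <- solve_mtx(doses, p_mtx, p_cpg2,
                    times = c(-hours_post, all_t),
                    units_per_mg = units_per_mg)
  mtx_tdv <- prof$conc[match(mtx_t, prof$time)]
  cpg2_tdv <- cpg2_conc(cpg2_sched$time, doses, p_cpg2, units_per_mg)
  conc48 <- prof$conc[match(48, prof$time)]

  obs <- rbind(
    do.call(rbind, lapply(seq_len(nrow(cpg2_sched)), function(i)
      .obs_row(cpg2_sched$time[i], cpg2_sched$nominal[i], "CPG2",
               cpg2_tdv[i], pop_cpg2$sigma_add, missing_prob))),
    do.call(rbind, lapply(seq_along(mtx_t), function(i)
      .obs_row(mtx_t[i], mtx_nom[i], "MTX", mtx_tdv[i],
               pop_mtx$sigma_prop, missing_prob))))
  obs <- obs[order(obs$time, obs$analyte), ]
  rownames(obs) <- NULL

  cov$scr_baseline <- scr_baseline
  .new_subject(id, cov, doses, obs,
               truth = list(eta_cpg2 = eta_c, eta_mtx = eta_m,
                            cpg2 = list(cl = p_cpg2$cl, v = p_cpg2$v),
                            mtx = p_mtx,
                            c0 = c0, hours_post_mtx = hours_post,
                            arf = arf, mtx_dose_g_per_m2 = dose_gm2,
                            amount_umol = amt_umol,
                            conc46 = conc46, conc48 = conc48,
                            second_dose = second,
                            eligibility_rule = el$rule),
               arm = dose_ukg)
}

#' Generate a synthetic study cohort
#'
#' Draws subjects under a [study_design()], simulates their true
#' concentration-time profiles from the supplied population models, applies
#' the residual error models and assay censoring, and returns a cohort that
#' every downstream stage (estimation, diagnostics, forecasting) can consume.
#' Phase-2 covariates are drawn uniformly on the log scale within the
#' observed patient ranges (age 1-75 y, weight 10.7-78.1 kg, serum creatinine
#' 0.23-3.47 mg/dl, MTX dose 2.9-14.3 g/m2), the baseline MTX concentration
#' at the treatment decision is log-uniform on 1.02-692.32 umol/L, and every
#' generated patient satisfies at least one CPG2 selection rule at the start
#' of CPG2 ([eligible_for_cpg2()]).  A second CPG2 dose is appended at 48 h
#' when the true MTX concentration still exceeds 1 umol/L at the 46-h check.
#'
#' @param design a [study_design()]
#' @param pop_cpg2 CPG2 population model ([cpg2_pop_params()])
#' @param pop_mtx MTX population model ([mtx_pop_params()]); required for
#'   phase 2
#' @param seed RNG seed; identical seeds give identical cohorts
#' @param units_per_mg CPG2 potency constant (simulation only)
#' @return object of class `pk_cohort`: a list of `pk_subject`s with the
#'   design and seed as attributes.  Each subject carries its covariates,
#'   dose events, observation table (`time`, `nominal`, `analyte`, `dv`,
#'   `blq`, `tdv` = error-free value) and the simulation truth.
#' @export
generate_cohort <- function(design, pop_cpg2, pop_mtx = NULL, seed = 1,
                            units_per_mg = 1000) {
  stopifnot(inherits(design, "study_design"))
  if (design$phase == 2 && is.null(pop_mtx))
    stop("phase-2 generation requires `pop_mtx`")
  set.seed(seed)
  n <- design$n_subjects
  subjects <- vector("list", n)
  if (design$phase == 1) {
    arms <- rep(design$dose_u_per_kg, length.out = 2)
    arm_of <- rep(arms, each = ceiling(n / 2))[seq_len(n)]
    for (i in seq_len(n))
      subjects[[i]] <- .gen_phase1_subject(i, arm_of[i], pop_cpg2,
                                           design$missing_prob,
                                           units_per_mg)
  } else {
    for (i in seq_len(n))
      subjects[[i]] <- .gen_phase2_subject(i, design$dose_u_per_kg[1],
                                           pop_cpg2, pop_mtx,
                                           design$missing_prob,
                                           units_per_mg)
  }
  structure(subjects, class = "pk_cohort", design = design, seed = seed,
            units_per_mg = units_per_mg)
}

#' @export
print.pk_cohort <- function(x, ...) {
  d <- attr(x, "design")
  nobs <- sum(vapply(x, function(s) nrow(s$obs), integer(1)))
  cat(sprintf("phase-%d synthetic cohort: %d subjects, %d observations\n",
              d$phase, length(x), nobs))
  invisible(x)
}

#' @export
print.pk_subject <- function(x, ...) {
  cat(sprintf("subject %s: %d dose events, %d observations\n",
              x$id, nrow(x$doses), nrow(x$obs)))
  invisible(x)
}
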