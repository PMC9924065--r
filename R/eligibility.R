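#' Acute renal failure criterion
#'
#' A patient is in acute renal failure when either of two criteria holds:
#' (1) at least 12 h after MTX administration the serum creatinine is above
#' the upper reference limit, or the creatinine clearance / glomerular
#' filtration rate is below 70 ml/min; (2) the serum creatinine has risen to
#' at least twice its pre-MTX baseline, or by a factor of at least 1.5 for
#' two consecutive, increasing measurements.
#'
#' @param scr_now current serum creatinine, mg/dl
#' @param scr_baseline pre-MTX serum creatinine, mg/dl
#' @param scr_series ordered post-MTX serum creatinine series, mg/dl (used
#'   for the "1.5-fold, two consecutive and increasing" clause)
#' @param ccr_or_gfr creatinine clearance or GFR, ml/min
#' @param scr_uln upper reference limit for serum creatinine, mg/dl
#' @return logical flag
#' @export
acute_renal_failure <- function(scr_now = NULL, scr_baseline = NULL,
                                scr_series = NULL, ccr_or_gfr = NULL,
                                scr_uln = 1.2) {
  if (is.null(scr_now) && is.null(ccr_or_gfr) && is.null(scr_series))
    stop("no evaluable renal-function input supplied")
  crit1 <- FALSE
  if (!is.null(scr_now)) crit1 <- crit1 || scr_now > scr_uln
  if (!is.null(ccr_or_gfr)) crit1 <- crit1 || ccr_or_gfr < 70
  crit2 <- FALSE
  if (!is.null(scr_now) && !is.null(scr_baseline))
    crit2 <- scr_now >= 2 * scr_baseline
  if (!crit2 && !is.null(scr_series) && !is.null(scr_baseline) &&
      length(scr_series) >= 2) {
    ratio <- scr_series / scr_baseline
    for (i in seq_len(length(scr_series) - 1)) {
      if (ratio[i] >= 1.5 && ratio[i + 1] >= 1.5 &&
          scr_series[i + 1] > scr_series[i]) {
        crit2 <- TRUE
        break
      }
    }
  }
  isTRUE(crit1) || isTRUE(crit2)
}

# Selection rules for CPG2 treatment: threshold concentration (umol/L),
# earliest qualifying hour, and extra condition.
.cpg2_rules <- data.frame(
  conc = c(50, 5, 2, 1, 0.4, 0.3, 0.1),
  hour = c(22, 40, 46, 40, 46, 70, 70),
  cond = c("none", "none", "none", "arf", "arf", "dose_gt_3.5",
           "dose_1_to_3.5"),
  label = c(">=50 umol/L (22 h)",
            ">=5 umol/L (40 h)",
            ">=2 umol/L (46 h)",
            ">=1 umol/L (40 h + ARF)",
            ">=0.4 umol/L (46 h + ARF)",
            ">=0.3 umol/L (70 h and >3.5 g/m2 MTX)",
            ">=0.1 umol/L (70 h and 1-3.5 g/m2 MTX)"),
  stringsAsFactors = FALSE)

#' Eligibility for CPG2 rescue
#'
#' Checks the plasma-MTX-concentration / time selection rules for CPG2
#' treatment.  Thresholds apply as ">= concentration at or after the stated
#' hour"; two rules additionally require acute renal failure, and the two
#' 70-h rules are stratified by the MTX dose intensity (over vs within
#' 1-3.5 g/m2).  The first matching rule (in table order) is reported.
#'
#' @param mtx_conc plasma MTX concentration, umol/L
#' @param hours_post_mtx time since the start of MTX administration, h
#' @param arf acute renal failure flag, see [acute_renal_failure()]
#' @param mtx_dose_g_per_m2 MTX dose intensity, g/m2 (required only by the
#'   70-h rules)
#' @return list with `eligible` (logical) and `rule` (matched rule label or
#'   `NA`)
#' @examples
#' eligible_for_cpg2(60, 22)
#' eligible_for_cpg2(1.5, 40, arf = TRUE)
#' @export
eligible_for_cpg2 <- function(mtx_conc, hours_post_mtx, arf = FALSE,
                              mtx_dose_g_per_m2 = NA) {
  stopifnot(mtx_conc >= 0, hours_post_mtx >= 0)
  for (i in seq_len(nrow(.cpg2_rules))) {
    r <- .cpg2_rules[i, ]
    if (mtx_conc < r$conc || hours_post_mtx < r$hour) next
    ok <- switch(r$cond,
                 none = TRUE,
                 arf = isTRUE(arf),
                 dose_gt_3.5 = !is.na(mtx_dose_g_per_m2) &&
                   mtx_dose_g_per_m2 > 3.5,
                 dose_1_to_3.5 = !is.na(mtx_dose_g_per_m2) &&
                   mtx_dose_g_per_m2 >= 1 && mtx_dose_g_per_m2 <= 3.5)
    if (ok)
      return(list(eligible = TRUE, rule = r$label))
  }
  list(eligible = FALSE, rule = NA_character_)
}
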