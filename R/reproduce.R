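#' Worked example: evaluate the packaged final models
#'
#' Recomputes the headline typical-value quantities of the fitted models at
#' their reference covariate values: MTX renal clearance at body weight
#' 60 kg / serum creatinine 1.0 mg/dl, peripheral volume at 60 kg, central
#' volume at a body-weight-to-BSA ratio of 1, the maximum decomposition rate
#' per unit catalyst concentration, the fixed constants Q and Km, and the
#' phase-1 CPG2 clearance at the healthy-volunteer mean body size (DuBois
#' BSA from 169.6 cm / 60.9 kg), also expressed per kg.
#'
#' @return data.frame with columns `quantity`, `value`, `units`
#' @examples
#' final_model_summary()
#' @export
final_model_summary <- function() {
  mtx <- mtx_final_model()
  # reference covariates: BW 60 kg, Scr 1 mg/dl; BW/BSA ratio forced to 1
  p_ref <- mtx_individual(mtx, covariates(weight = 60, bsa = 60, scr = 1))
  cp1 <- cpg2_final_model(1)
  bsa1 <- bsa_dubois(169.6, 60.9)
  cl1 <- cpg2_individual(cp1, covariates(weight = 60.9, bsa = bsa1))$cl
  data.frame(
    quantity = c("MTX renal clearance (BW 60 kg, Scr 1 mg/dl)",
                 "MTX central volume (BW/BSA = 1)",
                 "MTX peripheral volume (BW 60 kg)",
                 "Vmax per unit CPG2 concentration (alpha)",
                 "intercompartmental clearance Q (fixed)",
                 "Michaelis constant Km (fixed)",
                 "phase-1 mean BSA (DuBois, 169.6 cm / 60.9 kg)",
                 "phase-1 CPG2 clearance at mean BSA",
                 "phase-1 CPG2 clearance, weight-normalized"),
    value = c(p_ref$clr, p_ref$vc, p_ref$vp, p_ref$alpha,
              mtx$q_fixed, mtx$km_fixed,
              bsa1, cl1, cl1 * 1000 / 60 / 60.9),
    units = c("L/h", "L", "L", "model units", "L/h", "umol/L",
              "m2", "L/h", "ml/min/kg"),
    stringsAsFactors = FALSE)
}
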