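#' Body surface area (DuBois-DuBois)
#'
#' BSA in m^2 from height and weight by the DuBois-DuBois formula
#' \eqn{0.007184 \times H^{0.725} \times W^{0.425}}.
#'
#' @param height_cm height in cm (strictly positive)
#' @param weight_kg body weight in kg (strictly positive)
#' @return body surface area in m^2
#' @examples
#' bsa_dubois(169.6, 60.9)
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be strictly positive")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Body surface area (Mosteller)
#'
#' Alternative BSA formula \eqn{\sqrt{H \times W / 3600}}.
#'
#' @inheritParams bsa_dubois
#' @return body surface area in m^2
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be strictly positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Subject covariates
#'
#' Container for the demographic and biochemical covariates entering the
#' covariate models: body weight (kg), height (cm), BSA (m^2), age (years),
#' serum creatinine (mg/dl) and, optionally, creatinine clearance (ml/min).
#' BSA is derived from height and weight when not supplied.
#'
#' @param weight body weight, kg
#' @param height height, cm
#' @param bsa body surface area, m^2; derived via `bsa_formula` when `NULL`
#' @param age age, years
#' @param scr serum creatinine, mg/dl
#' @param ccr creatinine clearance, ml/min (optional)
#' @param bsa_formula formula used to derive BSA when absent
#' @return an object of class `covariates` (named list)
#' @examples
#' covariates(weight = 60.9, height = 169.6)
#' @export
covariates <- function(weight, height = NULL, bsa = NULL, age = NULL,
                       scr = NULL, ccr = NULL,
                       bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  if (is.null(bsa)) {
    if (is.null(height))
      stop("either `bsa` or `height` (with `weight`) must be given")
    bsa <- switch(bsa_formula,
                  dubois = bsa_dubois(height, weight),
                  mosteller = bsa_mosteller(height, weight))
  }
  vals <- list(weight = weight, height = height, bsa = bsa,
               age = age, scr = scr, ccr = ccr)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop(sprintf("covariate `%s` must be strictly positive", nm))
  }
  structure(vals, class = "covariates")
}

# Look up a covariate value by name, failing with a clear message.
cov_value <- function(cov, name) {
  v <- cov[[name]]
  if (is.null(v))
    stop(sprintf("covariate `%s` is required by the model but missing", name))
  v
}
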