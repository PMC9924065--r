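---
title: "Modelling glucarpidase rescue of high-dose methotrexate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucarpidase rescue of high-dose methotrexate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpg2mtx)
```

## The problem

High-dose methotrexate (HD-MTX, >= 1 g/m2) is curative chemotherapy for
leukaemia, lymphoma and osteosarcoma, but delayed renal excretion of MTX is
a medical emergency: sustained plasma concentrations cause acute kidney
injury, which further blocks excretion.  Glucarpidase (carboxypeptidase G2,
CPG2) is the rescue enzyme: given intravenously, it cleaves circulating MTX
into inactive DAMPA and glutamate within minutes.  Because CPG2 never
enters cells and MTX redistributes from tissue back into plasma, the plasma
MTX concentration *rebounds* over the following days, and a second CPG2
dose is indicated when the concentration is still above 1.0 umol/L about
two days after the first.

`cpg2mtx` implements a coupled population pharmacokinetic/pharmacodynamic
(popPK-PD) description of this rescue, a synthetic-cohort generator
emulating a healthy-volunteer dose study and a delayed-excretion patient
study, population estimation machinery, diagnostics, and an evaluation of
limited blood-sampling strategies for forecasting the decisive 48-h MTX
concentration.

## The structural model

CPG2 itself follows a one-compartment intravenous-infusion model with
first-order elimination, evaluated in closed form ([cpg2_conc()]):
individual clearance and volume follow power covariate models on body
surface area,

$$CL_i = tvCL \cdot BSA_i^{\theta_1} e^{\eta_{i,CL}}, \qquad
  V_i = tvV \cdot BSA_i^{\theta_2} e^{\eta_{i,V}},$$

with lognormal inter-individual variability (IIV) and additive residual
error in mg/L.

MTX follows a two-compartment model in amounts $X_c$ (central) and $X_p$
(peripheral).  Renal elimination is first order ($K_r$); non-renal
elimination in these patients is *entirely* catalyst-driven and saturable:

$$\frac{dX_c}{dt} = -(K_r + K_{12})X_c + K_{21}X_p
  - \frac{\alpha\,[\mathrm{CPG2}]\,[X_c]}{K_m + [X_c]},$$

where $[X_c] = X_c/V_c$ is the plasma MTX concentration, $K_m$ the
Michaelis constant, and $\alpha$ converts the plasma CPG2 concentration
into a maximum decomposition rate, $V_{max} = \alpha [\mathrm{CPG2}]$.  A
first-order non-renal constant (`knr_de`) is retained for the general form
of the equation but is zero in the final model.  Clearance
parameterization ties the micro constants to physiology: $CLr = K_r V_c$
and $Q = K_{12} V_c = K_{21} V_p$, with $Q$ fixed at 0.0778 L/h (a
published Japanese adult value; estimating it destabilized all other
intervals) and $K_m$ fixed at 86 umol/L.

The packaged final models ([cpg2_final_model()], [mtx_final_model()])
carry the fitted constants, e.g. $CLr$ (L/h) $= 3.248 \cdot BW/Scr/60$,
$V_c$ (L) $= 0.386\cdot BW/BSA$, $V_p$ (L) $= 3.052 \cdot BW/60$,
$\alpha = 6.545\times 10^5$.  Body weight is standardized at 60 kg: the
/60 divisors are part of the published formulas and are kept literal.

### Units and two deliberate conventions

MTX amounts are umol, MTX concentrations umol/L (the scale on which $K_m$
is quoted); CPG2 concentrations are mg/L.  $\alpha$ therefore carries
units (umol/h)/(mg/L) internally; the published unit statement for
$\alpha$ does not dimension-check, so its magnitude is honoured as a
model-unit constant and reported as such.

CPG2 doses are prescribed in units (U) while the concentration model works
in mass.  The product's U-to-mg conversion is not public; the simulator
uses a single named constant `units_per_mg` (default 1000 U/mg) for the
mapping.  Any fit that uses the same constant on both the dose and the
prediction side is unaffected by its value; only the absolute scale of
simulated CPG2 concentrations (and hence the interplay of $\alpha$ with
the assay's additive error) depends on it.

The MTX residual error is proportional, $C = C^*(1+\varepsilon)$.  The
published residual estimate ("1.414", no units) cannot be a fractional SD
-- it would imply a 141% CV and a quarter of all observations negative,
contradicting the published conditional weighted residuals -- so the final
model here defaults to a 30% proportional SD, a conventional magnitude for
HPLC MTX data.  This is the one published constant we do not adopt
verbatim; it is flagged in the constructor documentation.

## Numerical treatment

The coupled system is stiff by design: at rescue concentrations the MM
term eliminates central MTX on a time scale of seconds while
redistribution acts over days.  `solve_mtx()` integrates with `lsoda`
(compiled right-hand side, CPG2 supplied as a closed-form forcing
function), restarts the integrator at every dose boundary, and defaults to
`rtol 1e-8 / atol 1e-10`.  Failed segments are retried at relaxed
tolerances before an error is raised -- this matters only for the extreme
parameter trials an optimizer generates.  The linear pre-CPG2 dosing
history is propagated in closed form (matrix exponential via the 2x2
eigen-decomposition) during estimation.

Inside the likelihood the solver runs at `rtol 1e-6 / atol 1e-8` (1e-5 /
1e-7 for the scaled-down recovery studies below): the objective tolerates
far more integration error than the reported profiles do, and the outer
finite-difference steps are chosen (1e-3 on the transformed scale) to stay
above the integration noise.

## Estimation

`neg2ll()` implements an FOCE-with-interaction / Laplace approximation:
per subject, the random-effect vector is optimized to its conditional mode
(damped Gauss-Newton with a trust region, multi-started from the prior
mode and a warm start), and the marginal likelihood is approximated by a
Gaussian integral using the expected-information curvature at that mode.
Random effects whose variance is zero are pinned, which reproduces the
extended-least-squares deviance in the no-IIV limit.  On a
one-random-effect model the approximation agrees with Gauss-Hermite
quadrature to well under 0.1 OFV units (see the test suite).  The
proportional residual variance is stabilized as
$\sigma^2(f^2 + 0.01^2)$ umol/L: the unstabilized variance hands
near-zero predictions unbounded leverage, while a floor an order of
magnitude above the assay's quantification limit (0.0011 umol/L) leaves
quantifiable observations -- including the small post-rescue
concentrations that identify $\alpha$ -- at essentially full weight.

`fit_population()` offers four methods.  `"foce"` (default) minimizes the
FOCE objective by bounded quasi-Newton search on log-transformed
parameters (covariate exponents unconstrained) and is used for the CPG2
model, whose closed-form predictions make the objective cheap and smooth.
For the coupled MTX model the conditional objective is rugged: competing
posterior basins for individual subjects exchange global status under
sub-percent parameter changes, which makes any cold-started mode tracker
discontinuous.  `"its"` -- iterated two-stage estimation, alternating MAP
estimation of every subject's random effects with analytic moment updates
of the typical values, IIV variances (curvature-corrected) and residual
variance -- is deterministic, robust and about an order of magnitude
cheaper, and is the recommended method for the coupled model.  `"fo"` and
`"fo-foce"` (first-order initialization) are provided for completeness.
Standard errors come from the central-difference Hessian of the objective
at the estimates.  Bounds on the transformed parameters are broad
plausibility ranges whose only purpose is to keep trial points inside the
integrable region.

Covariate screening and forward-backward stepwise selection
(`screen_covariates()`, `stepwise_select()`) use the likelihood-ratio
test at p < 0.001 per degree of freedom (critical delta-OFV 10.828);
because competing single additions change the same number of parameters,
picking the largest OFV drop is also the AIC tie-break.

## The synthetic cohorts

`generate_cohort()` emulates the two study designs rather than any
released data (none exist).

*Phase 1*: 16 healthy adult men, two CPG2 dose arms (20 and 50 U/kg, n = 8
each), 5-min infusions at 0 and 48 h, 12 quantifiable CPG2 samples per
subject.  Covariates are drawn uniformly within the published cohort
ranges (height 162.6-184.8 cm, weight 54.3-66.9 kg, age 20-40 y).

*Phase 2*: delayed-excretion patients.  Covariates are log-uniform within
the published patient ranges (age 1-75 y, weight 10.7-78.1 kg, serum
creatinine 0.23-3.47 mg/dl, MTX dose intensity 2.9-14.3 g/m2); height is
tied to weight through a pediatric-to-adult allometry
($H = 29.7\,W^{0.41}$, 5% lognormal scatter) fitted to the published
extremes, because independent draws produce impossible bodies.  The
baseline MTX concentration at the treatment decision is log-uniform on the
published 1.02-692.32 umol/L range; each subject carries a 6-h HD-MTX
infusion whose amount is back-solved (the pre-CPG2 system is linear) so
the model concentration at CPG2 start equals that draw.  The recorded dose
intensity used by the eligibility rules is drawn independently of the
back-solved amount -- a deliberate simplification.  Every generated
patient satisfies at least one selection rule ([eligible_for_cpg2()]) at
CPG2 start, by rejection sampling.  A second 50-U/kg dose is appended at
48 h exactly when the true simulated concentration exceeds 1 umol/L at the
46-h check, which also switches on the 72-h and 96-h samples.  Window
samples (5-8 h, 12-20 h) are drawn uniformly and recorded at their
realized times.  Observations receive the analyte's residual error
(negative draws floored and flagged) and assay censoring at the
quantification limits (MTX 0.5 ng/ml, CPG2 1 ng/ml; no upper censoring,
since routine assays dilute).  Below-limit records are dropped from
estimation (M1).

What the generator does *not* emulate: leucovorin rescue and urine data,
assay cross-reactivity with DAMPA, correlated covariates beyond the
height-weight tie, informative missingness (a per-point missingness
probability is exposed, default 0), and any real between-patient
correlation of baseline concentration with renal function.  Passing tests
therefore demonstrate internal consistency of the method chain under the
stated design, not fidelity to any real cohort.

## Diagnostics and forecasting

`gof_table()` reports PRED (random effects at zero), IPRED (empirical-
Bayes mode) and CWRES, computed from the first-order expansion about the
conditional mode -- residuals standardized by
$\mathrm{chol}(J\Omega J' + V)^{-1}$.  `bootstrap_fit()` resamples
subjects with replacement under a master seed and reports percentile
intervals with the convergence fraction.  `vpc()` simulates replicate
datasets at the cohort's own design, bins by nominal time (window samples
by their window), and overlays observed 5/50/95th percentiles on
simulated confidence envelopes; covariates are kept at their original
values, since the schedule is fixed by design.

`forecast_48h()` restricts a patient's MTX observations to a sampling
subset, MAP-estimates the individual parameters under the final model
(CPG2 individual parameters coming from the CPG2 popPK post hoc step,
mirroring the sequential analysis), and forward-simulates to 48 h.
`evaluate_all_subsets()` scores all 31 non-empty subsets of {pre-dose,
20 min, 2 h, 5-8 h, 24 h} by ME/MAE/RMSE (pred - obs convention) and by
the hit ratio at 1.0 umol/L; a value exactly at the threshold counts as
"over", consistent with the redosing rule.  Against simulated truth the
subsets containing the 24-h sample dominate, reproducing the study's
qualitative finding that the pre-dose and 24-h samples carry the
information about the rebound.  By default the "observed" 48-h value is
the error-free simulated truth; a flag switches to the error-perturbed
observation to mirror a clinical comparison.

## Problem sizes and the shipped checks

The automated checks run, among others: quadrature-oracle comparisons on
a one-random-effect model; recovery of the phase-2 CPG2 model from ten
replicate cohorts of 50 subjects (median typical-value bias within 10%);
recovery of the coupled MTX model from three replicate cohorts of 30
patients by ITS (typical values within 20% in the median -- the IIV here
is 30-90% CV, so single replicates scatter); conservation of mass on
every simulated subject; and the 24-h-sample ranking on a 15-patient
cohort.  These sizes were chosen to exercise every stage at meaningful
statistical resolution while keeping a full run on a single CPU to
roughly ten minutes.

## Known limitations

* The estimator family is an approximation validated against quadrature on
  small models, not against the proprietary software used in the original
  analyses; absolute OFV values are not comparable across implementations.
* ITS updates typical values and variances by moments of the conditional
  modes; with sparse designs it inherits shrinkage bias in the variances.
* The covariate-selection machinery covers single power terms on CL and V
  of the CPG2 model; the MTX covariate structure is taken as published
  rather than re-searched.
* The second-dose rule uses the true simulated concentration; a clinical
  implementation would use an assayed value with error.
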