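---
title: "Methods: nonparametric population PK and dosing simulation of piperacillin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonparametric population PK and dosing simulation of piperacillin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pippk)
```

This vignette is the package's own account of its methods: the structural
and statistical model, the estimation algorithm and its numerical choices,
what the synthetic-data generator emulates, and the limits of what the
package's passing tests demonstrate.

## Structural model

Piperacillin kinetics in critically ill adults are described by a linear
two-compartment model with zero-order infusion input; the one-compartment
model is the special case `KCP = KPC = 0`. The closed-form solution is used
everywhere. Writing the system matrix `M` with eigenvalues `-alpha`,
`-beta` (the hybrid constants, `alpha + beta = ke + KCP + KPC`,
`alpha * beta = ke * KPC`), both the matrix exponential and its integral are
evaluated by two-point Lagrange interpolation on the eigenvalues. The form
`(1 - exp(-x))/x` is computed with `expm1` and a series fallback near zero,
so the limit `beta -> 0` needs no special casing in transient simulation.
Numerically guarded degeneracies:

* a repeated root `alpha == beta` (measure-zero in the parameter space) is
  split by a 1e-7 relative nudge of `KPC`;
* periodic steady state does not exist when `KPC = 0` (the peripheral
  compartment only accumulates); since central kinetics then decouple, a
  one-compartment branch with rate `ke + KCP` is used for `C(t)`.

Steady state under repeated dosing is computed from periodic initial
conditions: a 2x2 linear solve of `(I - E(tau)) A0 = A_single(tau)`, not a
run-in simulation. A long run-in is retained in the test suite as an oracle
(piperacillin's terminal phase under a slow peripheral return can need
hundreds of simulated doses to converge, which is exactly why the closed
form is preferred). Closed-form profiles agree with an adaptive
Runge-Kutta/BDF integration of the mass-balance system (deSolve) to better
than 1e-6 relative over random parameter draws.

Units are hours, milligrams, litres and mg/L throughout; a bolus is an
infusion of duration zero. Nominal infusion durations are treated as exact.

## Observation model and likelihood

Observed concentrations are modelled as Gaussian around the model
prediction with the heteroscedastic residual SD
`SD(C) = gamma * (C0 + C1 * C)`; the fitted piperacillin model uses
`gamma = 5`, `C0 = 1`, `C1 = 0.1` (an additive-lambda variant is available).
The SD is evaluated **at the model prediction**, not at the observed value.
This is a deliberate choice: with residual noise of this magnitude
(asymptotically ~50% CV), weighting each observation by the SD of its own
noisy value systematically over-weights observations that happened to fall
low and biases clearance upward — in self-simulation experiments the fitted
mean clearance rose ~50% above truth under observation-based weighting,
while prediction-based weighting (the correctly specified likelihood for
data whose noise scales with the true concentration) recovers the
generating population. Concentrations below an assay's lower limit are used
as-is when positive; true zeros are not modelled.

## Nonparametric population estimation

The population distribution of `(TVCL, V, KCP, KPC)` is a discrete
distribution (support points with probability weights) estimated by
maximum likelihood — the nonparametric analogue of the random-effects
distribution, able to express skewness and subpopulations that parametric
fits assume away. The fit alternates:

1. **Weights.** For fixed support, the mixing weights solve a convex
   problem; multiplicative EM updates (monotone by construction) run to a
   relative objective change below 1e-8 or 2000 iterations. Per-subject
   likelihood rows are max-scaled so magnitudes down to `exp(-700)` and far
   beyond cannot underflow.
2. **Pruning and condensation.** Points with weight below `1e-8 * max`
   are dropped. Near-duplicates — within 0.5% of each parameter's (log)
   range of a heavier point, max-norm — are merged into their heavier
   neighbour. Without condensation the EM solution carries clusters of
   near-tied neighbouring points whose perturbation offspring grow
   exponentially across cycles; merging keeps the support at the search's
   resolution and enforces a minimum pairwise distance. If a merge ever
   loses likelihood, the cycle is redone without merging.
3. **Refinement.** Survivors are perturbed by `+/- delta` along each axis;
   `delta` starts at 20% of the searchable range and halves whenever a
   cycle stops improving the likelihood, down to 0.1%. After the radius is
   exhausted it is re-expanded once more if the preceding sweep still
   improved the fit. Each cycle also receives a fresh batch of 64
   quasi-random candidates: a purely local, axis-aligned refinement can
   stall in a secondary mixture configuration (observed as fitted `-2LL`
   20-40 above an oracle solution on some synthetic datasets), and cheap
   global exploration closes that gap.
4. **Polish.** After the grid converges, each support point with
   non-negligible weight is moved to a local optimum of its
   responsibility-weighted likelihood by Nelder-Mead — the M-step of the
   mixture EM, which cannot decrease the mixture likelihood. Grid moves are
   axis-aligned and cannot follow the curved `V`-`KCP`-`KPC` likelihood
   ridge; the polish walks along it (on noise-free single-subject-type data
   it moves the support from several percent off truth onto the generating
   parameters almost exactly). Subjects sharing a sampling design are
   evaluated in one vectorized call to keep this step affordable.

The search operates in **unit log coordinates** of the bounded box
(default `TVCL` 0.3-15 L/h, `V` 2-50 L, `KCP`, `KPC` 0.001-5 /h):
pharmacokinetic parameters are positive scale parameters, and uniform
candidate placement on a linear scale concentrates density at implausibly
large values — empirically this inflated the weakly identified `V`, `KCP`
and `KPC` along their likelihood ridge, and log-scale placement removed
most of that drift. The initial grid is a seeded Latin hypercube of
`20 * 2^4 = 320` points; the whole fit is deterministic given its seed.

The covariate model enters the likelihood per subject: a support point
carries `TVCL`, and subject-level clearance is `TVCL * (CRCL/60)`.
Covariate screening (`covariate_screen()`) regresses per-subject posterior
parameter estimates on candidate covariates with linear, quadratic, log and
power shapes ranked by r-squared; it is meant to be run against a
no-covariate (base) fit, since posteriors from the covariate model already
have the renal effect divided out. Model comparison uses `-2LL`, AIC and
BIC with `p = 4` structural parameters; support-point count is not
penalized (a convention, stated in `fit_metrics()`; error-model parameters
are fixed inputs here, not estimated, which is a known simplification).

## Posteriors, diagnostics, validation

Individual posteriors reweight the population support by each subject's
likelihood (Bayes' rule in the log domain). "Population" and "individual"
predictions are the prior- and posterior-weighted mean predictions.
Diagnostics follow standard practice: observed-vs-predicted OLS with
t-based slope CI; a visual predictive check that simulates `n >= 100`
replicates of every observation (support resampling plus residual noise)
and reports both pooled 5th/50th/95th bands per nominal time and the
fraction of observations inside their own simulated 90% interval; rank-based
normalized prediction distribution errors with the mid-rank convention and
finite boundary values `qnorm(1/(2 n_sim))`. The npde here are **marginal**:
no decorrelation across an individual's observations is applied, which is
the appropriate simplification for designs with a handful of samples per
subject and is why the self-simulation variance check uses a generous band.
Bland-Altman agreement uses pair-mean percent differences by default
(`100 * (obs - pred) / pair mean`), with an absolute mode whose bias equals
the mean prediction error exactly.

External validation applies the fitted model unchanged as a prior to a new
cohort (recomputing clearance from each external subject's CrCL), computes
prediction errors `obs - pred` (negative bias = observed below predicted),
and reports MPE and RMSPE with normal-approximation 95% CIs, for the full
data and for observations below a concentration cutoff (default 100 mg/L,
the typical calibrated assay range of a development dataset). The 20% bias
acceptance rule is evaluated relative to the mean observed concentration of
the evaluated subset — the denominator is not standardized in the
literature, so it is explicit and configurable here. MPE/RMSPE defaults use
the posterior (individual) predictions; population-based values are one
argument away.

## Dosing simulation

`sample_population()` draws parameter sets either by resampling a fitted
support (the default with a fit in hand) or from independent log-normal
marginals matched by moments to the reference population means and SDs
(`pip_population_moments()`), so dosing simulations can run without any
patient data. The renal scenario applies `CL = TVCL * (CRCL/60)` per draw.
For each draw one steady-state interval is evaluated in closed form and
`fT>MIC` — the fraction of the interval with unbound concentration
(`fu = 0.70` for all subjects; protein binding is assumed constant at 30%)
strictly above the MIC — is measured by locating threshold crossings with
bisection to 1e-6 h on a 201-point scan of the piecewise-exponential
profile. Ties at exactly the MIC count as failure; the boundary has measure
zero under continuous kinetics, so this is a pure convention. PTA is the
fraction of draws attaining the target fraction (0.5 or 1.0) of the
interval; FTA weights the PTA curve by an MIC frequency distribution
truncated at the clinical breakpoint (16 mg/L), with 85% as the optimality
threshold and 90% as the PTA adequacy threshold. The bundled
`synthetic_mic_pseudomonas()` distribution is an invented wild-type-shaped
stand-in — use a current surveillance distribution for real decisions. Body
size does not alter the kinetics in this model (no body-size covariate
survived into the final model), so BMI is carried only as a descriptive
covariate.

Monte Carlo defaults (`n_sim = 1000`) put the binomial SE of a PTA value at
most at ~0.016.

## Synthetic cohorts: what they emulate, and what they do not

`generate_cohort()` reproduces the statistical structure the analysis
assumes: 24 subjects at steady state on day 5; regimens 4 g q8h (probability
0.5) or the individually designed 2 g q6h / 3.3 g q4h alternatives (0.25
each — assignment frequencies are not part of the cohort summary the
generator matches, so these are a
fixed package choice); 0.5-h infusions; one to three samples per interval at
pre-dose, 1 h and 3 h (probabilities 0.25/0.5/0.25, keeping the latest
times when fewer than three); covariates log-normal with median and IQR
matched to the cohort description (CrCL median 60, IQR 47-83; 38% male);
true parameters log-normal matched by moments to the reference population
moments
with the renal covariate link; residual noise from the final error model,
with negative concentrations resampled (truncation, counted and reported).
Day-5 steady state is emulated with closed-form periodic profiles rather
than five literal days of dosing — equivalent under time-invariant
parameters. CrCL is generated independently of age and weight by default
(only marginal summaries are matched); a correlated mode via Cockcroft-Gault
from generated age/weight/creatinine is available through the covariate
calculators. External-validation cohorts reproduce two typical rich
designs (20 subjects, 4 g q6h, 20-min infusions, six samples; 10 subjects,
4 g every 8 h, 0.5-1 h infusions, twenty samples over two intervals) with a
higher-clearance population (CrCL ~92-122).

The generator draws noise that truly follows the model, uses exact nominal
times, and holds renal function constant — real ICU data do none of these.
Passing recovery and calibration tests therefore demonstrate internal
consistency of estimator and generator, not performance on real patients.

### The recovery design

The parameter-recovery study (`rich_recovery_design()`) samples each of 50
subjects on **two occasions**: five samples after the first dose
(0.3-4 h) and five across a day-5 steady-state interval. This is not
incidental. At steady state the likelihood has a flat ridge connecting `V`,
`KCP` and `KPC` — a slow peripheral return (`KPC` ~0.08/h, half-time ~9 h)
cannot be resolved within one periodic interval, and in simulation even the
oracle solution restricted to the true parameter vectors drifts 20-40% in
mean `V` on a noticeable fraction of datasets. First-dose data pin `V`
(known dose, no accumulated peripheral mass) but leave `CL` nearly free
(little drug is eliminated within one early interval). Only the combined
design identifies both: across 20 seeds at the final error model's noise,
the fit recovers mean `CL` within 15% and mean `V` within 20% on all seeds.
The event schema's `OCC` column expresses such designs in data files.

## Known limitations

* The error-model parameters (`gamma`, `C0`, `C1`, `lambda`) are inputs,
  not estimated; selecting an error model means comparing fits under
  candidate models by `-2LL`/AIC/BIC.
* Interoccasion variability, saturable elimination, three-compartment
  kinetics, lag times and BLQ censoring mechanisms are out of scope.
* The npde omit the covariance decorrelation step (documented above).
* The discrete population distribution makes weighted quantiles step
  functions; the reported median is the smallest support value whose
  cumulative weight reaches 0.5.
* FTA values depend entirely on the MIC distribution supplied; the bundled
  one is synthetic.
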