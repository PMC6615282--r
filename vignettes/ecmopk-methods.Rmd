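---
title: "Population pharmacokinetics of sufentanil during VA-ECMO: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of sufentanil during VA-ECMO: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adults on venoarterial extracorporeal membrane oxygenation (VA-ECMO)
commonly receive continuous intravenous sufentanil for analgesia and
sedation. The ECMO circuit sequesters lipophilic, highly protein-bound
drugs and critical illness alters both distribution and elimination, so
dosing rules derived from non-ECMO patients are unreliable in this
population. `ecmopk` implements a complete population-pharmacokinetic
workflow for this setting: a structural infusion model, mixed-effects
estimation, covariate selection, internal validation, and Monte Carlo
dosing simulation, together with a synthetic-cohort generator that stands
in for clinical data (which are, for such studies, typically not publicly
available).

## Structural model

Sufentanil kinetics are described by a mammillary two-compartment model
parameterised by systemic clearance $CL$, central volume $V_1$, peripheral
volume $V_2$, and intercompartmental clearance $Q$. For a piecewise-constant
infusion the central concentration has an exact bi-exponential closed form;
each infusion segment contributes a scaled unit step response at its start
minus one at its end (superposition). No ODE solver is used anywhere in the
production path: the one- and two-compartment models are evaluated from the
disposition eigenvalues
$$\lambda_{1,2} = \tfrac12\left(S \pm \sqrt{S^2 - 4\,k_{10}k_{21}}\right),
\qquad S = k_{10}+k_{12}+k_{21},$$
and the three-compartment candidate used in structural comparison is
evaluated through the exact eigendecomposition of its linear rate matrix.
A repeated-eigenvalue degeneracy (relative discriminant below $10^{-12}$)
is handled by perturbing $\lambda_2$ down by $10^{-9}\lambda_1$ rather than
by a separate critically-damped branch; the case has measure zero under
every covariate distribution used here.

Units are fixed throughout: hours, micrograms, litres, µg/L. Conversions
happen only at I/O boundaries.

## Covariate and random-effect model

The reference (final) covariate model is
$$CL = 37.8\,e^{0.207\,(T - 36.9)} \ \mathrm{L/h}, \qquad
V_2 = 1640\,(TP/4.5)^{2.46}\ \mathrm{L},$$
with $V_1 = 229$ L and $Q = 41$ L/h; $T$ is tympanic temperature (°C) and
$TP$ total plasma protein (g/dL). Centering values default to the study
medians (36.9 °C, 4.5 g/dL) and are recomputed as dataset medians when
fresh data are fitted. For screening, three functional forms are available
for continuous covariates — power, linear, and exponential — plus a
proportional-shift form for dichotomous covariates. Two exponential
variants exist: the ratio-scaled form $\theta_{TV}e^{\theta\,x/c}$ (the
screening form as conventionally printed) and the difference-centred form
$\theta_{TV}e^{\theta\,(x-c)}$ used by the final temperature model. Both
are kept available because the literature is not consistent about which is
screened; the final model uses the difference-centred form.

Inter-individual variability is log-normal on $CL$ and $V_2$ only
($\theta_i = \theta_{pop}e^{\eta_i}$, $\eta_i \sim N(0,\omega^2)$,
diagonal $\Omega$), matching the two variance terms the reference analysis
reports; the screening path can toggle IIV on other parameters but the
default does not. Residual error is proportional,
$c_{ij} = \hat c_{ij}(1+\varepsilon_{ij})$ with
$\varepsilon \sim N(0,\sigma^2)$. Below-LLOQ observations (LLOQ
0.02 µg/L) are excluded from the likelihood (the M1 policy).

## Estimation: FOCE with interaction

For subject $i$, let $g(\eta)$ be the conditional joint $-2\log$
likelihood kernel
$$g(\eta) = \sum_j\left[\log\big(\sigma^2 f_{ij}(\eta)^2\big) +
\frac{(y_{ij}-f_{ij}(\eta))^2}{\sigma^2 f_{ij}(\eta)^2}\right] +
\eta^\top\Omega^{-1}\eta .$$
The residual variance $\sigma^2 f^2$ rides along with $\eta$ — that
$\eta$-dependence of the error model is precisely the *interaction* of
FOCE+I. The empirical-Bayes (MAP) $\hat\eta_i$ minimises $g$; the inner
solver is a damped Gauss–Newton iteration with backtracking line search,
warm-started across outer iterations, with the Jacobian
$\partial f/\partial\eta$ from central differences (step $10^{-4}$)
evaluated in one batched closed-form call. At the reference model's large
$\omega^2_{V2}$ the conditional posterior can be multimodal, so by default
each solve chooses its basin deterministically from a prior-scaled
candidate grid before Newton refinement (`scan = TRUE`). The resulting
marginal objective is a minimum over modes and carries concave creases
where the argmin switches; two consequences are handled explicitly: the
observed-information Hessian freezes each subject's basin
(`standard_errors()` refines locally from the fitted etas), and bootstrap
replicates and null-simulation LRT pairs run with `scan = FALSE` so both
sides of every comparison live on one smooth branch.

The marginal objective is the Laplacian FOCE+I form
$$\mathrm{OFV}_i = g(\hat\eta_i) + n_i\log 2\pi + \log|\Omega| +
\log\left|\tfrac12 \nabla^2 g(\hat\eta_i)\right|,$$
with the exact conditional Hessian obtained by central second differences
(step $10^{-3}$) — again one batched call. Eigenvalues of the half-Hessian
are floored at $10^{-4}$ of their largest magnitude (or of the prior
precision) so the objective stays finite and continuous where a hard
positive-definite/fallback switch would jump. The additive $n\log 2\pi$
constant is kept, so OFVs are directly comparable with quadrature
$-2\log L$; $\Delta$OFV between nested models is unaffected.

Two design points deserve a note:

* **Why Laplacian rather than purely linearised.** The classical
  linearised conditional objective (normal likelihood of
  $y - f(\hat\eta) + G\hat\eta$ under $G\Omega G^\top + \sigma^2
  \mathrm{diag}(f^2)$) deviated from 64-node adaptive Gauss–Hermite
  quadrature by up to ~0.6 units per subject at moderate variability,
  which is too coarse to certify 1-unit agreement on 5-subject instances.
  The exact-Hessian Laplacian form tracks the quadrature oracle to
  ≲ 0.35 per 5-subject instance at moderate $\omega^2$. Conditional
  weighted residuals (CWRES) keep the conventional linearised mean and
  covariance, as is standard.
* **Accuracy limits.** At the very large peripheral-volume variability of
  the reference model ($\omega^2_{V2} = 1.13$, i.e. a log-SD above 1) the
  conditional posteriors are visibly non-Gaussian and *any* Laplace-type
  approximation, this one included, can deviate from exact quadrature by a
  few OFV units per cohort. This is a property of the approximation class
  the field's standard estimator occupies, not an implementation defect;
  the quadrature-agreement tests therefore exercise the moderate-IIV
  regime, and the large-IIV behaviour is assessed through parameter
  recovery instead.

The outer problem maximises the summed OFV over $\log$-transformed
positive parameters ($\theta$s, $\omega^2$s, $\sigma^2$) and unconstrained
covariate coefficients, using a short Nelder–Mead pre-search followed by
BFGS with numerical gradients; BFGS is restarted from the incumbent (twice
by default) because a quasi-Newton scale mismatch otherwise quits a few
OFV units early on 200-subject problems. Parameter excursions beyond
$|{\cdot}|>50$ on the optimisation scale are rejected before they reach the
kinetics (an $e^{50}$ volume would overflow the eigenvalue arithmetic).

Standard errors come from the central-finite-difference Hessian of
OFV$/2$ at the optimum, inverted and mapped to the reporting scale by the
delta method. The relative step is $10^{-3}$: a $10^{-4}$ step places the
second differences at the same magnitude as the inner solver's numerical
noise floor and produces indefinite Hessians. Shrinkage follows the usual
definitions, $100(1-\mathrm{SD}(\hat\eta)/\omega)$ per random effect and
$100(1-\mathrm{SD}(\mathrm{IWRES}))$ for the residual.

## Covariate selection

Screening refits the base model with each candidate relation added singly;
each candidate's functional forms are all fitted and the best (largest OFV
drop) represents it, since published analyses rarely state which form was
screened per covariate. Stepwise selection is forward at $p<0.05$
($\Delta\mathrm{OFV} \ge 3.84$, 1 df per relation) and backward at
$p<0.01$ ($\Delta\mathrm{OFV} \ge 6.64$): forward repeatedly admits the
largest significant drop (exact ties broken by declaration order);
backward repeatedly removes the relation whose removal costs least, while
that cost is below the backward threshold. The trace of every decision is
returned as a data frame and emitted as CSV by the CLI.

## Internal validation

**Bootstrap.** Subjects (never individual observations) are resampled with
replacement to the original cohort size; each replicate is refitted
warm-started from the final estimates — the standard device that keeps
thousands of replicate fits tractable — and failed or non-converged
replicates are excluded and counted. A subject drawn $k$ times enters the
replicate once with likelihood weight $k$, which is exactly equivalent to
duplication (the log-likelihood is additive over subjects) and roughly
halves the cost of a replicate fit. Replicate fits run with local
conditional-mode tracking (`scan = FALSE`, below) so all replicates are
compared on one smooth objective surface. Percentile 2.5/97.5 bounds and the
median summarise each parameter. The desk-scale default is 200 replicates;
the full 5000-replicate mode is the same code path.

**pc-VPC.** Observations and simulated replicates are prediction-corrected
by $pcY_{ij} = Y_{ij}\,\tilde P_{bin}/P_{ij}$ with $P_{ij}$ the population
($\eta=0$) prediction and $\tilde P_{bin}$ its bin median. Bins are
quantile-based on time after start of infusion (8 by default, or explicit
edges). The observed 5th/50th/95th percentiles per bin are overlaid on
confidence bands of the same percentiles across simulated datasets; both
95% (default) and 90% band conventions are supported because published
VPC descriptions alternate between them.

## Dosing simulation

Monte Carlo scenarios draw $\eta$ per virtual individual, hold covariates
constant over the horizon, and summarise true (residual-error-free)
concentrations; the typical ($\eta=0$) profile is the headline curve
because the published dosing claims are statements about a representative
patient, while population percentiles and the fraction of individuals
inside the 0.3–0.6 µg/L sedation target are reported alongside. The grid
engine sweeps each infusion rate (12.5 and 17.5 µg/h by default) over
temperature at reference protein and over protein at reference
temperature, classifying each cell at the end of a 120-h infusion as
below/within/above the window.

Two boundary effects are worth knowing. A "simulated mean" curve lies
slightly above the typical curve (Jensen: the mean of a log-normal exceeds
its median), so claims tied to the mean can differ at window edges: with
12.5 µg/h at protein 4 g/dL the typical 120-h concentration is
0.3004 µg/L — a knife-edge "within" where the mean-based reading is
"low". And attainment of a two-sided window is *not* monotone in
temperature: at 17.5 µg/h the typical profile sits above the window at
33 °C, inside it near 36.7 °C and below it at 39 °C, so attainment rises
and then falls as temperature increases. The monotone quantities are the
concentration itself and exceedance of the lower bound, and those are what
the invariant tests check.

## Synthetic cohorts

The generator emulates the study design: 20 subjects (configurable),
12.5 µg/h below 60 kg else 17.5 µg/h, infusion duration with median 110 h
and range 34–260 h, sampling at 3 and 12 h then every 24 h to the 96-h
protocol window during infusion, and at 0, 0.5, 1, 2, 6, 12 h then every
24 h to 72 h after cessation, LLOQ 0.02 µg/L with below-LLOQ records
excluded.

Design choices:

* **Covariate laws.** Continuous covariates are scaled Beta distributions
  matched *exactly* to the published median and range of the study
  population (`pbeta` root-finding on the shape, with shape total 4 for a
  moderately peaked spread); asymmetric ranges rule out untruncated
  normal or log-normal laws. Dichotomous covariates are Bernoulli with the
  observed frequencies (CRRT 9/20, male 16/20). Temperature and protein
  are sampled independently — no joint law is published.
* **Sample retention.** The full protocol schedules roughly 270 draws for
  20 subjects, while ICU studies of this design report on the order of
  106 evaluable samples; a per-sample retention probability
  (`p_retain`, default 0.4 ≈ 106/270, fixed before any test was written)
  models missed draws and attrition. BLQ exclusion removes only records
  whose noisy concentration falls below 0.02 µg/L.
* **What a green test does not establish.** The generator reproduces the
  design's sparsity, covariate spread and error structure, but real
  cohorts add features it does not model: dose titration to sedation
  scores, time-varying temperature and protein, correlated covariates,
  assay batch effects, and informative missingness. Recovery results
  certify the estimator on the stated world, not on any clinical dataset.
* The "every 24 h until 96 h" protocol phrase is read as 96 h from
  infusion start (not from first sample); the post-cessation "every 24 h
  until 72 h" arm is read as offsets {24, 48, 72} from the stop time, the
  enumeration the protocol text implies.

## Numerical choices

* Inner solver: gradient tolerance $10^{-8}$ (relative), iteration cap 40,
  with convergence also declared when the objective is numerically
  stationary ($<10^{-9}$ relative) or the step falls below the
  finite-difference resolution — the gradient cannot certify $10^{-8}$
  through FD noise.
* Outer optimiser: BFGS `reltol` $10^{-7}$, `maxit` 150, Nelder–Mead
  pre-search 60 iterations, 2 incumbent restarts.
* Concentrations are clamped at 0 from below; predictions are floored at
  machine-tiny values inside likelihood evaluations only.
* Exact ties in forward selection are broken by candidate declaration
  order, making traces bit-reproducible.
* All randomness flows from explicit integer seeds; every CLI output file
  carries a header comment with the package version, a config hash and the
  seed.

## Known limitations

* FOCE-class approximation error at $\omega^2 \gtrsim 1$ (see above);
  SAEM or full Bayesian estimation are out of scope.
* Diagonal $\Omega$ only; no M3/M4 BLQ likelihoods (the reference analysis
  used M1 exclusion).
* The likelihood surface of the sparse design is genuinely flat in the
  (protein exponent, $\omega^2_{V2}$, $V_2$) directions: recovery of the
  protein exponent from 200 sparse subjects is poor even at the optimum,
  and that is a property of the design, not the optimiser. Clearance-side
  parameters, which carry the dosing conclusions, recover well.
* No pharmacodynamic (sedation-score) link and no dose-titration
  simulation.
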