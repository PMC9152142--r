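---
title: "Latent change score models of multimodal gray-matter integrity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent change score models of multimodal gray-matter integrity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmintegrity)
```

## The scientific problem

Aging brains lose gray-matter tissue, and aerobic exercise may slow that
loss.  Any single MRI measure of a region — gray-matter probability from
voxel-based morphometry (VBM), magnetization-transfer saturation (MT), or
mean diffusivity (MD) — mixes the construct of interest with
modality-specific measurement error.  `gmintegrity` therefore models a
*latent structural-integrity factor* per region of interest (ROI): at each
of three occasions the factor loads on the three modality indicators, with
VBM as the reference indicator (loading fixed to 1), MT loading positively
and MD negatively (higher diffusivity means less intact tissue).  Change is
modeled with latent change score models (LCSMs): with integrity factors
$\eta_1, \eta_2, \eta_3$,

$$\eta_2 = \eta_1 + \Delta_{21}, \qquad \eta_3 = \eta_2 + \Delta_{32},$$

where the $\Delta$ are latent change factors with free means, variances and
covariances.  A two-group (active controls, ACG, vs. exercisers, EG)
version of the model asks three ordered questions per ROI: does the
measurement structure hold across groups and occasions (factorial
invariance); do mean changes differ between groups; and, where reliable
individual differences in change exist, is change in integrity coupled to
change in cardiovascular fitness (VO~2~peak), via a bivariate LCSM whose
standardized fitness-change/integrity-change covariance is the coupling
$\phi$.

## The estimation engine

No part of the model machinery is delegated: the package carries its own
compact multigroup SEM kernel in RAM parameterization.  A model is a pair
of matrices per group — directed paths $A$, symmetric (co)variances $S$ —
plus a mean vector $M$ and a manifest filter $F$, giving implied moments

$$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top, \qquad \mu = F(I-A)^{-1}M.$$

Free parameters are *labels* placed in those matrices; the same label at
several positions (or in several groups) is an equality constraint.  Every
constrained model used in a likelihood-ratio test reuses its parent's
labels, so nesting is verifiable by label-set inclusion.

Estimation is full-information maximum likelihood (FIML): each case
contributes a multivariate-normal deviance over its observed variables
only, so missing data (dropout, screened outliers) need no deletion or
imputation.  Cases are grouped by missingness pattern; the pattern-wise sum
is algebraically identical to case-by-case evaluation (a tested contract).
The objective and its analytic gradient (chain rule through the RAM
algebra) are implemented in C++ (RcppArmadillo), which is what makes the
package's replication-based test suites affordable: one two-group,
eleven-manifest bivariate model fits in roughly a tenth of a second.

Numerical choices, all of which matter for reproducibility:

* **Optimizer.** Bounded quasi-Newton (L-BFGS-B) with analytic gradients;
  convergence tolerance `factr = 1e5` (about $10^{-11}$ relative on the
  deviance); variance parameters bounded below at $10^{-6}$ except when a
  boundary hypothesis fixes them to exactly 0.
* **Restarts.** Up to `restarts` attempts, the first from start values, the
  rest jittered by 10% through a deterministic linear-congruential stream
  (so fits never touch R's global RNG); attempts stop early once two
  consecutive attempts fail to improve a converged optimum.  This keeps
  simulation loops fast without giving up basin exploration.
* **Start values.** Manifest mean labels and variances of exogenous
  manifests start at their observed moments; structural parameters at
  fixed, documented defaults.  This matters for raw-scale covariates such
  as age.
* **Standard errors** come from the inverse of one-half the numerical
  Hessian of $-2\ln L$; a non-positive-definite Hessian (boundary,
  Heywood-adjacent solutions) yields missing SEs with a warning, never a
  silent pseudo-inverse.
* **Reference models.** The saturated model (free means and covariances
  per group) has a closed form for complete data and is FIML-optimized
  under missingness, started at available-case moments; the independence
  model factorizes per variable and is closed-form always.  Tiny negative
  $\chi^2$ (below $10^{-6}$) is clipped to 0 with a warning; anything
  larger triggers a refit of the saturated model and then a hard error, on
  the view that a silently wrong $\chi^2$ is worse than a failed run.
* **Fit indices.** RMSEA uses the $N-1$ convention with $N$ the total
  sample across groups and no multigroup inflation factor; its 95% CI
  inverts the noncentral-$\chi^2$ CDF in the noncentrality parameter.  CFI
  is computed against the independence baseline.  With cross-group equality
  constraints a multigroup model can legitimately have *more* df than the
  independence baseline, so the package does not require
  `baseline df >= model df`; the CFI formula handles this case.
  Exactly identified models (df = 0) report RMSEA as undefined — their fit
  is perfect by definition, not evidence.

## Invariance testing and directional inference

The invariance ladder runs, in order: group invariance at occasion 1
(configural to metric, df = 2; metric to strict, df = 3, on the one-factor
model of the three indicators) and time invariance with groups collapsed
(pooled data, single group; configural to metric, df = 4; metric to strict,
df = 6 on the longitudinal model).  "Metric" equates loadings, "strict"
additionally equates residual variances.  Indicator intercepts are held
equal across occasions at *every* level (with the VBM intercept fixed to 0)
so that latent change means remain interpretable; this df accounting is a
reconstruction of a conventional ladder, chosen so the step degrees of
freedom come out as 2/3/4/6.  Each step uses a two-sided likelihood-ratio
test at $\alpha = 0.05$, uncorrected across the 12 ROIs (a deliberately
liberal screen, flagged as such); the ladder stops at the first failure
(`stopAtFailure = FALSE` runs all steps, which calibration studies need).

Substantive hypotheses are directional: exercisers are expected to gain
(positive change), controls to decline (negative change).  For df = 1
likelihood-ratio tests the one-sided p is $p/2$ when the free estimate's
sign matches the hypothesized direction and $1 - p/2$ otherwise; for
df > 1 only two-sided p-values are reported, since halving has no analogue.
Loadings are tested by one-sided Wald tests ($z =$ estimate/SE).
"Reliable individual differences in change" is a boundary test — variance
of a latent change and every covariance involving it fixed to 0 — whose
reference distribution is a chi-square mixture; the implementation halves
the two-sided p (the 50:50 mixture heuristic) and labels the result a
heuristic in its output.

Within-modality cross-occasion residual covariances are constrained equal
(one parameter per modality per group): a participant-level method effect
per modality, constant over occasions, is the minimal mechanism for these
covariances, and the generator realizes them exactly that way.

## The synthetic-data generator

`simConfig()` / `simulateStudy()` generate study tables from the same
structure the models assume, so every downstream stage is testable without
any data download and parameter recovery is measurable against stored
latent draws.  Defaults describe a six-month at-home exercise intervention
in older adults: 35 controls and 40 exercisers, MRI at 0/3/6 months,
VO~2~peak (mL/kg/min) at months 0 and 6.  Loadings and residual scales are
set so baseline standardized loadings are about 0.53 (VBM), 0.46 (MT) and
−0.86 (MD) — MD the strongest indicator; these are generator knobs, not
claims about any particular dataset.  Controls decline on average (−0.04
and −0.06 latent units over the two intervals) while exercisers maintain;
change SDs default to 0.15; fitness change averages 2.3 mL/kg/min in
exercisers (about 10% of a 23 mL/kg/min baseline) versus 0.7 in controls.
The coupling between fitness change and first-interval integrity change is
drawn via one joint multivariate-normal latent vector
$(\eta_1, \Delta_{21}, \Delta_{32}, \mathrm{fit}_1, \Delta\mathrm{fit})$ —
not post-hoc residual mixing — so the generator's coupling *is* the
bivariate LCSM estimand; its covariance matrix is checked for positive
semi-definiteness at construction, with the offending ROI/group named on
failure.  Baseline–change and change–change latent covariances default to
0 so recovery tests have an interpretable truth.  Missingness is monotone
dropout (8% per follow-up occasion) plus 2% cell-level MCAR; gross
outliers add ±6 population SDs to 0.2% of MRI cells, so the 4-SD screen
provably catches them.  VBM indicators carry a small intracranial-volume
slope so the ICV adjustment has something real to remove.

What the generator does *not* emulate: spatial structure within ROIs,
scanner drift or batch effects, non-normal indicator distributions,
informative (outcome-dependent) dropout, and practice or re-test effects.
Passing tests therefore demonstrate that the estimator recovers the
assumed data-generating process, not that real MRI data satisfy these
assumptions.

## Data hygiene

The pipeline order is fixed and asserted: univariate 4-SD screen on raw
values per (variable, occasion); Mahalanobis screen per variable across
its occasions on complete cases (classical product-moment covariance,
$\chi^2$ cutoff at $1 - 0.001$ with df = number of occasions, all
occasions of a flagged case removed); ICV adjustment of VBM
(`adjusted = raw − b (ICV − mean ICV)`, `b` the least-squares slope);
compliance-based exclusion; then longitudinal ("stacked") standardization
to pooled mean 0 / SD 1 per variable, a single affine transform that
preserves between-occasion mean differences.  Whether the univariate
screen should run before or after ICV adjustment is genuinely open; raw
values were chosen because detection "within each measure and time point"
reads most naturally on the measured scale.  Sample SDs use the $n-1$
denominator throughout.  Compliance requires 1890 total minutes (21 weeks
x 90 min/week), no zero-activity pause longer than 2 weeks, and (for
exercisers) a non-negative least-squares wattage slope over active weeks —
a numeric operationalization of "steady or slightly increasing" intensity;
non-compliant participants keep their baseline rows and lose occasions
2–3 (`"fully-excluded"` mode drops them entirely, since the exact
bookkeeping is not reconstructible from the text of record).

## Sensitivity computations

`sensitivityF()` inverts noncentral-F power for the within-between
(time-by-group) interaction: numerator df $(g-1)(m-1)\varepsilon$,
denominator df $(N-g)(m-1)\varepsilon$, noncentrality
$\lambda = f^2 N m \varepsilon / (1-\rho)$, with $\rho = 0.5$ and
$\varepsilon = 1$ as explicit (never silent) conventional defaults.
`sensitivityR()` solves power for the test of a zero correlation either
exactly — integrating the exact sample-correlation density (Hotelling's
form with a Gaussian-hypergeometric factor, evaluated by series) above the
null critical value — or via the Fisher-z closed form; the two agree
within 0.005 for $N \ge 50$ (a tested invariant).  Both roots are found by
bisection to $10^{-6}$.  At $\alpha = 0.05$, power 0.95, $N = 75$, these
give $f \approx 0.19$ and (one-tailed) $r \approx 0.367$, the quantities
`scripts/acceptance.R` recomputes.

## Problem sizes used by the test suite

Chosen as regimes where the relevant asymptotics are trustworthy, and
stated here as the package's own design: parameter recovery runs 200
replications of the bivariate two-group model at $n = 400$ (200 per group)
with change SDs 0.35/0.25 and coupling 0.5 — an interior, well-identified
regime — fitted on the generator's raw scale so the configured values are
the exact truth; type-I calibration runs 500 null replications at the same
size, checking every ladder step and the one-sided df = 1 group-difference
test against binomial 99% bounds around 5%; the Mahalanobis screen is
calibrated at $n = 5000$.  Generator self-consistency uses
$n_{\mathrm{ACG}} = 2000$ and population-moment checks $n = 5000$.

## Known limitations

* The engine targets this family of models; it has no ordinal or robust
  estimators, bootstrap SEs, definition variables, or latent-class
  extensions.
* The boundary (variance-in-change) p-value is a flagged heuristic, not an
  exact mixture computation.
* Standardized estimates beyond |1| are reported with a warning rather
  than clipped; they signal a non-positive-definite latent block and
  should be read as such.
* With heavy missingness the saturated reference model is itself an
  iterative FIML fit; its convergence quality bounds the accuracy of
  $\chi^2$ and the derived indices (the package polishes and errors rather
  than report a negative $\chi^2$).
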