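---
title: "Models and methods: muscle mechanics, actin kinetics and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: muscle mechanics, actin kinetics and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibractin)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Contractile models

### Hill force–velocity hyperbola

Shortening muscle obeys, to good approximation, the rectangular hyperbola
$(T + a)(V + b) = (V_0 + b)\,a$, equivalently
$V(T) = a(V_0 + b)/(T + a) - b$. `fit_hill_fv()` estimates $a$ (force
units), $b$ (velocity units) and $V_0$ (unloaded shortening velocity) by
ordinary least squares on velocity residuals — velocity is the measured
response after a controlled drop in force, so it carries the measurement
error. Three choices are deliberate:

* **The curve is not forced through $(T_0, 0)$.** All three parameters are
  free positive regression coefficients; $T_0$ enters only through the
  initialization and the reported curvature ratio $a/T_0$. Real preparations
  often show a high-force deviation from the hyperbola, and constraining
  the intercept would bias $a$ and $b$.
* **Initialization and restarts.** Starting values $a_0 = 0.25\,T_0$,
  $V_{0,0} = \max V$, $b_0 = a_0 V_{0,0}/T_0$ reflect typical mammalian
  curvature. Levenberg–Marquardt occasionally stalls on poor starts, so up
  to ten seeded log-normal perturbations of the start are tried;
  persistent failure returns a structured `converged = FALSE` object
  rather than an error, so batch processing continues.
* **Power.** $W(T) = T\,V(T)$ vanishes at $T = 0$ and at
  $T_{max} = aV_0/b$ and peaks at the closed form
  $T^* = \sqrt{a(T_{max}+a)} - a$. `power_from_fit()` evaluates both the
  closed form and a dense grid and reports the closed-form optimum; the
  grid serves as an internal cross-check. For curvatures
  $a/T_0 \in [0.2, 0.5]$ on hyperbolae through $(T_0,0)$ the optimum load
  falls in $[0.28, 0.38]\,T_0$ — the familiar "one third of isometric
  force".

### Force–pCa sigmoid

Calcium activation is summarized by
$T_{rel}(\mathrm{pCa}) = 1/(1 + 10^{\,n_H(\mathrm{pCa} - pK)})$, the Hill
sigmoid in base 10 because pCa is $-\log_{10}[\mathrm{Ca}^{2+}]$. $n_H$
measures cooperativity, $pK$ the pCa of half-maximal force; the fitted
curve passes through 0.5 at $pK$ by construction. Tensions must be
normalized to the force at saturating calcium before fitting. All-zero or
all-one tension vectors are rejected as unidentifiable. The same restart
strategy as the force–velocity fit applies.

### T1 relation and the strain–force regression

Small length steps ($\pm$ a few nm per half-sarcomere) applied to an
isometrically contracting fibre give end-of-step forces that are linear in
step size. The line's slope is the half-sarcomere stiffness and its
abscissa intercept magnitude the half-sarcomere strain
$Y_0 = |{-\mathrm{intercept}/\mathrm{slope}}|$ — invariant to rescaling
all forces, as a strain should be. A flat relation (zero slope) is flagged
degenerate instead of raising. Across calcium levels, `regress_strain_force()`
fits $Y_0 = s_0 + C_f\,T_0$ by ordinary least squares. No end-compliance
correction is applied to $Y_0$.

### Passive modulus

The passive stress–sarcomere-length record from incremental stretch is
smoothed with a low-order polynomial (default cubic — only the local
tangent is needed, so a flexible local smoother is preferable to committing
to an exponential constitutive law) and the Young's modulus is the tangent
at 3.0 µm. Because strain conventions vary, the tangent is reported both
per µm of sarcomere length and per unit strain with
strain $= (sl - sl_{slack})/sl_{slack}$; the slack length (default 2.2 µm,
a typical relaxed mouse fibre value) must be supplied for the latter to be
meaningful, and both numbers are labelled.

## Actin biochemistry

### Binding isotherms

Co-sedimentation gives the fraction of ligand pelleting with F-actin at
each actin concentration; `fit_binding_isotherm()` fits
$f([A]) = [A]/([A] + K_d)$. Ligand depletion is ignored by default — the
assay incubates a fixed ligand concentration with up to 30 µM actin, and
the simple saturation form is the standard reduction — but a
depletion-corrected quadratic model (exact equilibrium complex
concentration) is available with `depletion = TRUE`. Data with fractions
never exceeding 0.05 are reported as "no measurable Kd" (the behaviour of
a non-binding domain) rather than fitted.

### Pyrene polymerization

Raw traces are normalized by subtracting the baseline (mean of the first
*k* points, default 5) and dividing by the plateau amplitude (mean of the
last *k*). The "linear region" slope is not defined canonically anywhere,
so it is operationalized deterministically: the maximum slope over sliding
windows (default width 10% of the trace) whose normalized values lie
entirely within the 10–60% band — above the lag phase, below plateau
saturation. The window width is configurable and should be narrowed for
traces that spend little of their length in the rising phase. Conversion
to nM actin/s multiplies the normalized slope by the polymerizable pool,
(total actin − critical concentration)·1000; the critical concentration
defaults to the textbook barbed-end value 0.1 µM and is recorded in the
result.

### Depolymerization

Disassembly traces are normalized by the assay's own convention: the final
time point of the F-actin-plus-Latrunculin-A control maps to 0 and each
trace's maximum to 1. The "disassembly rate" is the initial linear slope
over the first 60 s (configurable); an exponential-fit mode is provided as
an alternative since the literature uses both conventions, and the linear
initial slope is the default because it makes no model assumption. The
protection conferred by an actin-binding protein is
$100\,(1 - \mathrm{rate}_{plus}/\mathrm{rate}_{free})$ %.

## Morphometry

Z-line width is measured "at the base" of an averaged density profile:
background is the median of the outer 20% of positions (the feature is
centred in the boxed region by construction of the averaging), the base is
the contiguous region around the peak exceeding background + 5% of the
background-subtracted peak height, and the two edges are located by linear
interpolation between samples. On noiseless trapezoids whose shoulders are
resolved by the grid the measurement is exact; a perfectly sharp edge is
blurred by at most one sample spacing per side. The 5% threshold is a
package definition of "base" (no numerical definition exists in common
use) and is recorded in every result. Both per-profile and pooled-profile
averaging modes are provided, since ">100 Z-lines per muscle" style
reports are ambiguous between the two.

Fibre populations, fusion index, EdU fractions, myotube widths, ΔΔCt
(efficiency fixed at 2 unless overridden; replicate folds aggregated by
geometric mean, the natural average of ratios), luciferase ratios and
densitometry are direct arithmetic on already-extracted measurements, with
validation, conservation guarantees (counts sum to inputs, distributions
sum to 100%) and explicit error cases.

## Synthetic data and fixtures

Each generator draws from exactly the model its analysis stage assumes,
with additive Gaussian noise on the observable — the simplest model
consistent with fluorometry and densitometry error — clipped to $[0,1]$
where the observable is a physical fraction. With `noise_sd = 0` every
generated point satisfies its model equation to machine precision, which
is what makes exact round-trip (parameter-recovery) testing possible. All
generators require an explicit seed and restore the caller's RNG state.

`reference_fixtures()` packages named datasets whose ground truths are
calibrated to headline effect sizes: binding isotherms with Kd 7.6 and
4.6 µM; depolymerization pairs returning 80% and 90% initial-rate
decreases; Z-line profile pairs with 23% and 89% base-width increases
(WT base width 60 nm, a typical adult value, on a 0.1-nm grid so edge
crossings are fully resolved); a fibre population with an exact 48% mean
CSA reduction; myotube widths with an exact 36% reduction; and a Ct table
encoding a 2.5-fold induction. Two calibration details:

* The depolymerization protection parameter is solved by root-finding on
  the full noiseless pipeline (normalize, then 60-s linear initial rates)
  rather than set to 0.8/0.9 analytically, because a linear initial-rate
  fit over a finite window of an exponential decay underestimates the rate
  constant by a curvature-dependent factor; the calibrated protections
  (≈0.843 and ≈0.923 for the 80% and 90% fixtures at $k_0 = 0.01$ /s) are
  stored in the ground truth alongside the target percentage.
* The paired-percentage fixtures (fibre CSA, myotube width) scale the
  control draws by the effect factor instead of drawing the two groups
  independently, so the sample-mean ratio equals the ground-truth scale
  exactly; an independent draw would recover the effect only up to
  sampling error.

Because no measurement-noise magnitudes are standard for these assays,
fixture noise levels are package choices: the recovery suites use noise
SDs of 0.05 on bound fractions, 2–5% of scale on velocities and tensions,
and 5% of peak amplitude on profiles — conservative values for
densitometry and fluorometry. The generators emulate the statistical
structure of each assay, not its physics: no nucleation–elongation
kinetics, no optics, no sarcomere inhomogeneity, no correlated drift.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-conditioned under the assumed error model, not that they
are robust to every artefact of real recordings.

## Problem sizes and determinism

The validation suites use 9-point load and concentration grids, 601-point
kinetic traces, 0.1–0.5-nm profile grids, 20-draw noiseless recovery
sweeps and 200-replicate noise studies — large enough for stable medians,
small enough to run in seconds. Grid-search oracles (independent
brute-force minimizers) cross-check the nonlinear fitters to three
significant figures in the test suite. All stochastic tests fix their
seeds; reruns are bit-identical.

## Known limitations

* The Hill fits assume homoscedastic Gaussian error on the response;
  heteroscedastic weighting is not implemented.
* The T1 module consumes already-extracted (step, force) points;
  extracting the end-of-step force from raw force transients is upstream
  and out of scope, as are image segmentation and gel densitometry.
* The binding fit's default ignores ligand depletion; with 10 µM ligand
  and Kd below ~5 µM the depletion-corrected model should be preferred.
* Hierarchical (mixed-model) statistics across fibres and muscles are
  deliberately left to dedicated tools; the package returns per-unit
  estimates and descriptive comparisons only.
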