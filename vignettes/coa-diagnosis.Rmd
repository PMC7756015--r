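---
title: "Non-invasive CoA diagnosis from a stenosis pressure-flow curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive CoA diagnosis from a stenosis pressure-flow curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaflow)
```

## The problem

Coarctation of the aorta (CoA) is a congenital narrowing of the aortic
isthmus.  The hemodynamic reference standard for its diagnosis is invasive:
a catheter measures the peak systolic pressure gradient (PSPG) across the
lesion, with PSPG >= 20 mmHg diagnostic.  The anatomic alternative in the
ESC guidelines — a >= 50% diameter narrowing relative to the aorta at the
diaphragm — uses no flow information at all and is known to under-call
hemodynamically significant lesions.

`coaflow` implements a middle road: simulate steady flow through the
patient's arch geometry under a *family* of outflow boundary conditions,
and summarize the lesion not by any single simulated gradient (which would
inherit the arbitrariness of the chosen boundary condition) but by the
coefficients of its pressure-flow curve

$$\bar{\Delta p} = f\,\bar{Q} + s\,\bar{Q}^2,$$

where $f$ (mmHg·s/cm³) is the viscous friction of the narrowed segment and
$s$ (mmHg·s²/cm⁶) its expansion loss — the kinetic energy dissipated where
the jet re-expands into the post-stenotic lumen.  Both are properties of
the geometry, nearly independent of the flow and pressure levels at which
they are probed; that invariance is the method's central claim, and the
test suite checks it directly (features move by far less than 0.1% when the
inlet pressure spans 70–90 mmHg or when disjoint halves of the resistance
sweep are used).

A logistic model on the pair,

$$P(\text{CoA}) = \frac{1}{1 + e^{-(a f + b s + c)}},$$

is the diagnostic classifier, evaluated by stratified 5-fold
cross-validation against the 20 mmHg catheterization label, with the ESC
narrowing-rate rule as comparator.

## The reduced-order model

Patient imaging is not consumed here.  Instead an `aorta_network` is a
rooted tree of `vessel_segment`s — piecewise-linear lumen radius profiles
along a centerline — with one inlet, four outlets (brachiocephalic, left
carotid, left subclavian, distal descending aorta) and exactly one lesion
segment.  Each segment obeys

$$\Delta p = f_{\mathrm{seg}} Q + s_{\mathrm{seg}} Q^2,$$

with $f_{\mathrm{seg}}$ the Poiseuille integral $\int 8\mu/(\pi r(x)^4)\,dx$
(closed form per profile interval) and $s_{\mathrm{seg}} = 0$ except on the
lesion, where the Borda–Carnot sudden-expansion form applies:

$$s = K_e \frac{\rho}{2}\left(\frac{1}{A_{\min}} - \frac{1}{A_{\mathrm{ref}}}\right)^2,$$

with $A_{\min}$ the minimal lesion lumen area, $A_{\mathrm{ref}}$ the area
at the lesion start plane and $K_e = 1$ by default.  Blood is treated as
Newtonian with $\mu$ = 0.004 Pa·s and $\rho$ = 1060 kg/m³ (3.0e-5 mmHg·s
and 7.95e-4 mmHg·s²/cm² in the package's mmHg/cm/s unit system); the walls
are rigid and the flow steady.

Each outlet carries a single-resistance lumped parameter model draining to
a common reference pressure (0 mmHg by default — the model needs *some*
venous reference and results are insensitive to it because the features are
boundary-condition invariant; it is configurable).  A prescribed total
resistance is split over the four outlets with conductance proportional to
$d_i^{\,e}$.  The default exponent $e = 1$ follows the "inverse diameters"
allocation; $e = 3$ (Murray's law, flow proportional to diameter cubed) is
available because the two conventions coexist in the boundary-condition
literature and the choice is immaterial to the features (tested).

### The sweep protocol

The inlet is held at a static pressure of 80 mmHg (normal physiological
range).  The total outlet resistance starts at 9.6 mmHg·s/cm³ and is scaled
by 1, 1/2, 1/3, 1/4, 1/5, 1/6 — six steady solutions per patient, each
yielding one $(\bar Q, \bar{\Delta p})$ pair read between the lesion start
and end planes.  Scaling multiplies every outlet resistance, preserving the
allocation ratios.  `fit_pressure_flow_curve()` then estimates $(f, s)$.

Although the curve is often fit by iterative nonlinear least squares, the
model is *linear* in $(f, s)$, so the default path solves the normal
equations on the design $[\bar Q, \bar Q^2]$ exactly, with an active-set
treatment of the constraints $f, s \ge 0$: if the unconstrained optimum
leaves the quadrant, the best feasible boundary solution is taken, so a
non-stenotic tube reports $s$ exactly 0 rather than a small negative
number.  A Levenberg–Marquardt path (`method = "gauss_newton"`, via
minpack.lm) is provided for fidelity with iterative workflows and must
agree to 1e-8 (tested).

### The steady solver

Unknowns are the junction pressures.  `solve_segment_network()` runs damped
Newton with the analytic Jacobian $\partial Q/\partial(\Delta p) =
1/(f + 2s|Q|)$, started from the linearized (all-viscous) circuit solution;
convergence is declared at a mass-balance residual of 1e-12 relative to the
characteristic flow, with a stall guard at the double-precision floor set
by the stiffest segment conductance.  On the rare Newton failure a
nonlinear Gauss–Seidel bisection pass precedes a final Newton polish.
Backflow is outside the model's scope: the physiologic parameter ranges
shipped never produce it and the solver errors loudly if it occurs.  The
test suite compares the solver against an algorithmically independent
oracle — shooting by bisection on the inlet flow, with recursive bisection
at branch junctions — on 100 random networks, to 1e-8 relative flow.

## The virtual cohort

No patient data ship with the package.  `generate_cohort()` draws virtual
pediatric cohorts whose *statistical structure* matches what the analysis
assumes:

* **Size and composition.** Default n = 65 with a target CoA prevalence of
  38/65; ages 1 month–14 years (lognormal, median 12 months), ~54% male,
  BSA from an age curve (≈0.29 m² at 1 month, ≈1.37 m² at 14 years) with
  8% lognormal scatter.
* **Geometry.** Arch dimensions scale with $\sqrt{\mathrm{BSA}}$: the
  pre-lesion isthmus reference diameter is 1.0·√BSA cm, the ascending
  aorta 1.6× that, and the diaphragm-level aorta 0.95× the reference
  (distal tapering).  The isthmus lesion narrows the lumen by a severity
  fraction spanning 5–80%, with a morphology mixture from discrete
  (V-shaped throat) to tubular (a plateau at the minimal radius up to ~36%
  of the segment).  Morphology matters: it decouples the viscous
  coefficient from the expansion loss at fixed anatomic severity, which is
  what gives $f$ diagnostic information complementary to $s$.
* **Labels.** The catheterization ground truth is the lesion's own law
  evaluated at a peak-systolic flow of 160·BSA cm³/s (lognormal, 25% CV) —
  deliberately *not* the resting-sweep conditions the features are computed
  under.  Measured PSPG adds truncated Gaussian noise (σ = 2 mmHg, an
  assumed measurement-error scale; the label rule is PSPG >= 20 mmHg,
  boundary inclusive).  This resting-vs-peak asymmetry plus noise is why
  classification is good but imperfect, as in real cohorts.
* **Calibration.** The location of the latent severity prior is calibrated
  by bisection so the realized positive count lands within ±10% of the
  target prevalence; every other draw is fixed first, so a cohort is a
  byte-reproducible function of (config, seed).
* **Mismatch knobs.** `k_e_range` and `reynolds_friction` (a transitional
  $t\,Q^{1.5}$ lesion term with $t = 0.3\sqrt{f_{\mathrm{true}}
  s_{\mathrm{true}}}$) inject model error for robustness experiments; with
  both off (default) the generator and the fitted model share the same
  functional form and recovery of $(f_{\mathrm{true}}, s_{\mathrm{true}})$
  is exact to solver precision.

What the generator does **not** emulate: imaging and segmentation error,
pulsatile flow, wall compliance, associated congenital lesions of the arch
branches, and the anatomic diversity of real CoA (kinks, arch hypoplasia
with multiple discrete levels).  Passing tests therefore certify the
*inference machinery* — solver, curve fit, classifier, evaluation design —
under a faithful generative model of the study's assumptions, not clinical
performance on real images.

## Evaluation design

`stratified_partition()` divides the cohort into five equal folds (13
patients each at n = 65), exact on the label (per-fold positive counts
within ±1) and approximately balanced on sex and age: within each label
patients are shuffled with the given seed, stably sorted by (sex,
age-rank), and dealt round-robin.  Age-rank avoids arbitrary age bins; the
seeded shuffle acts exactly where the sort is tied.  Folds are indexed
1..k.

`cross_validate()` fits the combined model, $f$-only and $s$-only on each
training split, scores both splits, and reports AUC (Mann–Whitney with
DeLong variance and normal CI), sensitivity, specificity and accuracy at an
operating threshold chosen on the *training* split.  The operating rule is
the Youden-index optimum by default — the evaluation needs *some* operating
point and the choice of rule is genuinely open; a fixed 0.5 threshold is
supported.  Youden candidates are midpoints between consecutive distinct
scores, so a separable training set puts the cut between the classes.
Averages across folds are unweighted.  Folds whose test split holds a
single class are reported as degenerate and excluded from averages with a
warning.  The ESC comparator calls narrowing >= 0.50 positive (inclusive
boundary) with the narrowing rate defined as one minus the ratio of minimal
lesion diameter to diaphragm-level aortic diameter.

DeLong machinery (placement values; paired test for correlated AUCs) and
the tie-aware Spearman matrix are implemented directly and cross-checked in
the tests against pROC, a stratified bootstrap, and brute-force average
ranks.  The logistic fit is iteratively reweighted least squares on
internally standardized features ($f$ and $s$ differ by orders of
magnitude), converged at a log-likelihood change below 1e-10, with complete
separation detected and capped rather than left to diverge; it is
cross-checked against `glm`.  All p-values are two-sided.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(run_config(seed = 42))
print(report)
```

The report carries the per-fold and fold-averaged metrics for the four
classifiers and the Spearman matrix of (PSPG, f, s).  On default seeds the
suite verifies the qualitative ordering this pipeline is designed to
exhibit: the combined model's mean test AUC exceeds both single-feature
models and 0.90; the ESC rule is near-perfectly specific but at least 0.3
less sensitive than the combined model; and PSPG rank-correlates more
strongly with $s$ than with $f$.

## Numerical and design choices, in one place

* Units: mmHg, cm³/s, cm everywhere; explicit unit fields in all file
  formats (geometry/cohort JSON, sweep/feature CSV, report JSON, all
  versioned and round-tripped by their readers).
* Lesion planes are exact in the generator; `lesion_jitter` (cm) emulates
  observer placement of the start/end planes, default 0 since no noise
  magnitude is established.
* Minimum lesion diameter is twice the minimal profile radius between the
  lesion planes; diameters are stored as radii internally.
* Curve fitting is unweighted least squares.
* Tie handling: AUC counts ties as 1/2; Spearman uses average ranks;
  Youden ties resolve to the lowest (most sensitive) midpoint.
* Problem sizes in the shipped tests: 100 random networks for the
  solver-oracle comparison, 65-patient cohorts for the end-to-end and
  recovery checks, 400-replicate noise studies and a 2000-replicate
  bootstrap for the statistics oracles; the full suite runs in well under
  a minute.

## Limitations

The reduced-order network cannot represent three-dimensional jet dynamics;
its expansion-loss constant is exact by construction rather than an
empirical fit.  Steady flow ignores inertia, so the resting sweep and the
peak-systolic label live on the same quasi-static curve — real pulsatile
gradients deviate from it.  The ESC comparator is evaluated on generated
geometry, where the narrowing rate is known exactly; measurement error in
real diameter readings would blur its (here perfect) specificity.  Negative
flows (severe runoff, diastolic reversal) are out of scope.
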