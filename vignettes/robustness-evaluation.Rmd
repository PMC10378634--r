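---
title: "Daily robustness-band evaluation for proton head-and-neck plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily robustness-band evaluation for proton head-and-neck plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Intensity-modulated proton therapy (IMPT) plans for head-and-neck cancer are
optimized *robustly*: instead of a geometric margin, the optimizer demands
target coverage under a set of worst-case scenarios combining a rigid setup
error of magnitude $S$ (commonly 3 or 5 mm) with a multiplicative range
error $1 \pm \delta$ (commonly $\delta = 3.5\%$) that models CT-to-stopping-
power uncertainty. Whether the chosen $S$ actually brackets what is delivered
day to day is an empirical question: each fraction the patient is set up with
a residual six-degree-of-freedom (6-DOF) error, and the dose actually
received can fall outside the envelope the plan was optimized against.

`rtrobust` implements the analysis chain for that question:

1. enumerate the uncertainty scenarios and build, per structure and metric,
   the **robustness band** $[m_{R\min}, m_{R\max}]$ — the min–max envelope of
   the metric over all scenarios (the nominal scenario is always a member,
   so the band always contains the planned value);
2. recompute each fraction's metrics under its 6-DOF setup error and flag
   values outside the closed band;
3. quantify out-of-band fractions with the **fractional dose deviation** for
   the target D95%,
   $$\mathrm{FDD} = \frac{\max(D_{fx} - D_{R\max},\; D_{R\min} - D_{fx},\; 0)}
   {D_{Rx}} \times 100,$$
   and the **fractional volumetric deviation** for V100%, the analogous
   excursion in percentage points of volume;
4. compare patient classes and setup settings with Student's t-tests.

The deviation formulas are printed in their source with a `Min`, which is
negative for every out-of-band value (exactly one argument is positive);
all reported quantities are described as absolute deviations, so the package
returns the nonnegative magnitude and documents the discrepancy.

Metrics follow common clinical reporting: D95% and V100% for clinical target
volumes (CTVs), maximum voxel dose for serial organs at risk (cord-like) and
mean dose for parallel ones (parotid-like). `Dmax` is the single hottest
voxel — no 0.03 cc smoothing — because the source analysis does not specify
one; this is stated prominently rather than silently chosen.

## The synthetic cohort

Real inputs (planning-system dose grids recomputed on daily synthetic CTs)
are not publicly available, so the package ships a synthetic stand-in that
is itself first-class, tested code. It emulates the *structure* of the
original cohort, not its numbers:

* **Phantom.** A voxel grid (default $48 \times 48 \times 64$ at 2 mm) with
  a compact ellipsoidal primary CTV at the isocenter (semi-axes 14/14/16 mm,
  prescription 67.1 Gy), optionally an elongated superior–inferior nodal CTV
  — a capsule of radius 8 mm and half-length 34 mm offset 36 mm laterally
  (prescription 63.0 Gy) — plus a posterior cord-like cylinder (max-dose
  metric) and two lateral parotid-like ellipsoids (mean-dose metric).
  Prescription levels are the cohort means reported for the patients this
  emulates.
* **Dose model.** Each beam deposits
  $w \cdot L(r_\perp) \cdot Z(d)$: a Gaussian lateral penumbra times a
  1-D spread-out-Bragg-peak-like depth profile — linear proximal ramp from
  70% entrance dose, plateau of height 1 over $[R - M, R]$, held at 1 up to
  the effective range $R \cdot \rho$ (range scale $\rho$), then a
  half-logistic distal falloff $2 / (1 + e^{2(d - R\rho)/s})$. The beam
  isocenter sits at mid-plateau. Setup error is applied as a rigid transform
  of the anatomy with beams fixed; dose is evaluated analytically at the
  transformed points, so there is no interpolation error and the nominal
  dose is bit-reproducible. This is the simplest model whose metrics respond
  to both rigid 6-DOF error (through $L$ and the plateau edges) and range
  scaling (through the distal edge); heterogeneity, scatter and the nuclear
  halo are ignored.

  A note on the falloff: a logistic *centred* on $R\rho$ would leave the
  plateau short of 1 by a visible amount. The half-logistic keeps the
  mid-plateau dose exactly $w$ (the closed form the tests pin to $10^{-9}$)
  while the 50% depth, $R\rho + s\ln 3 / 2$, still scales with $\rho$ to
  well within half a voxel — both properties the acceptance tests assert.
* **Plans.** Two opposed lateral beams cover the primary with ~6–8 mm of
  plateau margin beyond the target and a soft penumbra
  ($\sigma_\perp = 30$ mm); PNN plans add superior/inferior nodal beams
  whose plateau (with small, clinically realistic ~3 mm margins) covers the
  capsule's length and whose narrow penumbra ($\sigma_\perp = 10$ mm)
  grazes its radius. Nodal beam weights are calibrated (fixed point, six
  iterations) so the nominal secondary D95 hits its prescription, emulating
  simultaneous-integrated-boost planning; `normalize_plan()` then applies
  the single global rescale that sets the nominal primary D95 to
  prescription exactly.

  The geometry was chosen so the cohort expresses the mechanisms the
  analysis is about. Two constraints are worth recording. First, plateau
  margins matter: without distal/proximal margin the primary's metric
  responds steeply to along-axis error and the whole cohort is far more
  fragile than the clinical plans being emulated. Second, the nodal chain
  must sit clear of the primary field's distal edge under *all* range
  scenarios: if dose spilling from the primary field peaks at an anatomy
  displacement strictly between 3 and 5 mm, the metric response is
  non-monotone on the scenario interval and the 5 mm band no longer nests
  the 3 mm band — an artifact of superposed static fields that jointly
  optimized clinical plans do not exhibit, and one the default geometry
  deliberately avoids.
* **Daily errors.** Per-axis independent Gaussians. Translation SDs are
  back-converted from the reported class-mean 3-D shift magnitudes
  (4.4 mm primary-only, PO; 2.7 mm primary-plus-neck-nodal, PNN) via
  $\mathbb{E}\lVert v\rVert = 2\sigma\sqrt{2/\pi}$, giving 2.76 and
  1.69 mm per axis. Rotation SDs come from the reported mean pitch
  displacements (10.3 mm PO, 6.5 mm PNN) read as arc length at a 30 cm
  lever radius — the only stated rotational quantities are printed in
  length units — giving 2.0° and 1.2° per axis. Rotations are intrinsic
  yaw (about z) → pitch (about x) → roll (about y) about the plan
  isocenter; the source does not state an order, so this one is fixed and
  documented. The cohort is 2 PO + 4 PNN patients with 28–48 fractions each
  (203 total).

**What a green test does and does not establish.** The generator applies
the *full* sampled couch shift to the delivered dose. In the emulated
workflow the recorded couch shift is largely corrected by image guidance,
and the recomputed dose reflects residual alignment plus anatomical change;
deformation, weight loss and contour drift are not modelled at all.
Absolute out-of-band percentages here are therefore higher than the
clinical report's, and a green acceptance run certifies the *qualitative*
structure — band nesting, the 3-vs-5 mm ordering, the primary-vs-secondary
mechanism, equation fidelity — never the clinical percentages themselves.

## Scenario sets

The band construction defaults to the common 21-scenario planning-system
convention: $\{0, \pm S\hat{x}, \pm S\hat{y}, \pm S\hat{z}\} \times
\{1-\delta, 1, 1+\delta\}$. The source states only $S$ and $\delta$, not the
combinatorics, so two variants are selectable: `reduced15` (the 7 shifts
paired with the two extreme range scales, plus the nominal scenario) and
`corners27` (26 corner/axis directions, each normalized to magnitude $S$ to
keep the setup-error interpretation, plus zero, times 3 range scales).
Rotational uncertainty is excluded from scenario bands — robustness settings
are stated in millimetres — and enters only through the daily errors.
Whether range and setup perturbations should be crossed or evaluated
separately is likewise unstated; the Cartesian product is assumed.

## Numerical conventions

* `d_at_volume(p)` interpolates linearly between the descending order
  statistics bracketing fractional rank $pN/100$ (equivalently a type-7
  quantile at $(N - pN/100)/(N-1)$, which is how the tests cross-check it);
  `v_at_dose` counts voxels with dose $\ge$ threshold, ties covered, no
  partial-voxel interpolation.
* Band membership uses closed intervals: a value exactly on a bound is
  within robustness (generous, documented).
* Daily fraction doses are recomputed at `range_scale = 1`: range error is a
  planning uncertainty, not a daily observable in this pipeline.
* Mean deviations are averaged over out-of-band fractions only, matching the
  way such results are reported; `summarize_deviations(include_zeros = TRUE)`
  averages over all fractions for sensitivity analysis.
* OAR band violations are reported as excursions in Gy; prescription scaling
  is meaningful only for targets.
* `shift_magnitude()` uses translations only — mixing degrees and
  millimetres in one norm is dimensionally unsound.
* Student's t is the classical pooled-variance form (a Welch option exists
  behind a flag); no multiple-testing correction is applied, matching the
  emulated analysis. Fractions are pooled as independent observations
  within classes; within-patient correlation is ignored — a known
  limitation of the original design, retained deliberately.
* Reproducibility: one root seed; per-patient substreams derive as
  `(root * 69069 + stream * 104729) mod (2^31 - 1)`, computed exactly in
  doubles, so cohorts are reproducible regardless of evaluation order. The
  configuration's FNV-1a hash is embedded in JSON outputs and the manifest.

## File formats

Grids (dose in Gy, masks) use a plain-text two-file format — a JSON header
with shape/spacing/origin plus a one-value-per-line table in array order —
because no NIfTI reader is available in the supported dependency set; the
format round-trips bit-faithfully and keeps every artifact diffable. Shift
logs, band tables, per-fraction records and DVH curves are CSV with fixed
documented headers; summaries and statistics are JSON. `import_external()`
accepts these formats in place of the synthetic model so externally
recomputed doses can be analysed unchanged.

## Known limitations

* The analytic dose model has no heterogeneity, scatter tails, or beam-angle
  dependence in depth; its hotspots (~10% over prescription near field
  junctions) are larger than a clinically optimized plan would show.
* Course-total dose accumulation across fractions, NTCP/TCP modelling,
  deformable registration and adaptive-replanning triggers are out of scope.
* The statistical layer intentionally mirrors the emulated analysis
  (fraction-level pooling, no mixed effects); conclusions about
  between-class differences inherit that simplification.
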