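---
title: "Comparing conformal arc and static-field thoracic plans: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing conformal arc and static-field thoracic plans: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcdosim)
```

## What the package computes

`arcdosim` implements the quantitative machinery used to compare dynamic
conformal arc (DCAT) and static-field conformal (3D CRT) thoracic
radiotherapy plans:

* **geometric target descriptors** -- volume, surface area, sphericity
  and a shell-based sphericity surrogate, margin expansion, minimum
  structure distances, isocentre displacement, structure overlap;
* **DVH plan metrics** -- conformation number CN, homogeneity index HI,
  dose homogeneity dispersion DHD, VxGy, mean doses, hottest-volume
  doses, and planning-constraint checks;
* **gamma-index agreement** between a measured (film-like) and a
  calculated dose distribution;
* **a per-medium error decomposition** of calculated-vs-measured dose
  over a cohort of plans (systematic error M, its spread Sigma across
  plans, random error sigma);
* **paired cohort statistics** -- a Shapiro-Wilk-gated choice between the
  paired t-test and the Wilcoxon signed-rank test, Spearman rank
  correlations, and per-patient variant rankings;
* **a synthetic thorax phantom and beam model** that generates every
  input the pipeline needs, so the whole analysis runs end to end with
  no patient data.

## Shape statistics

Sphericity compares an object's surface area with that of the
equal-volume sphere:

$$\Psi = \frac{\pi^{1/3}\,(6V)^{2/3}}{A},$$

so a perfect sphere gives exactly 1 and concave, multi-lobed shapes fall
towards 0.  Treatment planning systems report structure volumes but
rarely surface areas; the shell surrogate uses only the CTV and PTV
volumes and the margin $d$ that built the PTV from the CTV.
Approximating the mid-shell surface area by the shell volume over the
margin, $\tilde A = (V_{PTV}-V_{CTV})/d$ and
$\tilde V = (V_{CTV}+V_{PTV})/2$, gives

$$\tilde\Psi = \frac{\pi^{1/3}\, d\, \bigl(3 (V_{CTV}+V_{PTV})\bigr)^{2/3}}
  {V_{PTV}-V_{CTV}}.$$

$\tilde\Psi$ behaves like $\Psi$ but may exceed 1: for concentric
spheres with a 20 mm CTV radius and a 5 mm margin it evaluates to about
1.020, and it tends to the mid-shell sphericity as $d \to 0$.

```{r shell}
v_ctv <- 4 / 3 * pi * 2^3      # cm^3, r = 20 mm
v_ptv <- 4 / 3 * pi * 2.5^3    # r = 25 mm
sphericity_like(v_ctv, v_ptv, 5)
```

### Mask-derived surface area

Volume is voxel count times voxel volume.  Surface area is measured by a
marching-tetrahedra triangulation of the 0.5 level set of the binary
mask after Gaussian smoothing with a 1.25-voxel sigma.  Two biases
compete in any such estimator: smoothing pulls the level set inward
proportionally to the local curvature (an $O(h^2)$ area deficit on a
sphere of radius $r$, $h$ the spacing), while the piecewise-linear
triangulation of a wiggling interpolated field adds a small
scale-invariant area excess.  At a 1-voxel sigma the two terms have
opposite signs and cross near 1 mm spacing, which makes the error
non-monotone in the spacing; at 1.25 voxels the curvature term dominates
at every spacing of interest, so the sphere error decreases monotonically
(about +3.3%, +0.65% and +0.02% in $\Psi$ at 2, 1 and 0.5 mm).  Plain
face counting was rejected: it overestimates smooth surfaces by a
constant factor (3/2 for a sphere) and never converges.

### Margin expansion and distances

`expand_margin()` performs a Euclidean dilation through an exact
separable distance transform: a voxel joins the output when its centre
lies within the (possibly anisotropic) margin of the input voxel-centre
set.  This is the convention of mainstream image-analysis toolkits.  It
carries a discretization bias relative to continuous geometry: dilating a
digitized 20 mm sphere by 5 mm on a 1 mm grid gives a volume about 2.4%
below the analytic 25 mm sphere, because the discrete centre set
under-reaches the continuous surface by a fraction of a voxel; at 0.5 mm
the deficit is close to 1%.  Minimum distances (`min_distance()`,
`distance_to_skin()`) use the same transform and are exact for voxel
centres, which the tests confirm against all-pairs searches.  A
`per_slice` variant reproduces scripts that scan structure files slice
by slice; the 3D distance is never larger.

## DVH metrics

The cumulative DVH is computed on uniform dose-bin edges (default
0.01 Gy): the value at dose $t$ is the fraction of structure voxels with
dose $\ge t$.  $D_2$ and $D_{98}$ interpolate the cumulative curve
linearly between bin edges (the interpolation rule is a package choice;
bin width bounds its effect).  The derived indices are

$$\mathrm{CN} = \frac{TV_{RI}}{TV}\cdot\frac{TV_{RI}}{V_{RI}}, \qquad
\mathrm{HI} = \frac{D_2 - D_{98}}{D_{nom}}, \qquad
\mathrm{DHD} = \frac{\mathrm{sd}(D_{PTV})}{\overline{D_{PTV}}},$$

with the reference isodose at 95% of the prescription by default, and
$V_{RI}$ restricted to the external contour when one is supplied (else
the whole grid).  The lungs keep their overlap with the target (the lung
mask is not target-subtracted).  D1cc is the hottest-1-cm^3 dose,
interpolated between sorted voxel doses.  Planning constraints (lung
V20Gy < 35%, V5Gy < 60%, MLD < 15 Gy; cord D1cc < 50 Gy as the
maximum-dose surrogate; mean oesophagus dose < 34 Gy) are evaluated with
strict inequalities -- a value exactly on the limit fails, the
conservative reading of a "<" prescription.  Monitor units are a
recorded plan attribute, never computed.

## Gamma analysis

For every reference point $\mathbf r$ above the low-dose threshold,

$$\gamma(\mathbf r) = \min_{\mathbf r'} \sqrt{
  \frac{\delta^2(\mathbf r, \mathbf r')}{\Delta D^2} +
  \frac{|\mathbf r' - \mathbf r|^2}{\Delta d^2}},$$

where $\delta$ is the dose difference between the interpolated
evaluation distribution at $\mathbf r'$ and the reference at $\mathbf r$.
Defaults follow common practice: dose criterion 3% of the global maximum
of the *reference* (the measured film is the reference, so its maximum
normalizes), DTA 3 mm, threshold 10%, search cap $3\Delta d$, search
lattice $\Delta d/10$.  Points below the threshold are excluded from the
map and from both numerator and denominator of the pass rate; $\gamma$
exactly 1 fails the "$\gamma < 1$" criterion.  The lattice minimum is
polished by a local pattern search on the continuously interpolated
evaluation, which matters at steep gradients where any fixed lattice
overestimates $\gamma$ near its zeros.  `gamma_brute_force()` is an
independent exhaustive-lattice implementation (step $\le \Delta d/20$,
vectorized R, guarded to $64^2$ points) used as the test oracle at a
matched lattice; the closed forms (identity, uniform offset, shifted
gradient) pin down the refined path.

## Per-medium error decomposition

Calculated-vs-measured planar doses are compared as the relative
difference $100\,(D_{eval}-D_{ref})/D_{ref}$, with points below 5% of
the reference maximum masked (configurable) to keep near-zero film doses
from blowing up the ratio.  Per plan and per medium (lung, soft tissue,
bone) the mean and sample SD are taken; across a cohort, $M$ is the mean
of per-plan means, $\Sigma$ their sample SD, and $\sigma$ the
root-mean-square of the within-plan SDs.  The RMS definition of
$\sigma$ is a package choice isolated in `decompose_errors()` so a
pooled-SD alternative can be swapped in.  Signed values are reported
throughout.  A one-sample Wilcoxon signed-rank test
(`paired_symmetry_test()`) probes whether per-plan means are symmetric
about zero.

## Cohort statistics

`paired_compare()` applies a Shapiro-Wilk test (gate level 0.05, a
package choice) to the paired differences: normal-looking differences
get a two-tailed paired t-test with its t-based CI, the rest a Wilcoxon
matched-pairs signed-rank test with the Hodges-Lehmann pseudo-median
(computed exactly from the Walsh averages, so swapping the arms negates
the estimate exactly) and its CI.  Zero differences are dropped by the
Wilcoxon branch; ties get average ranks.  No multiple-testing correction
is applied -- raw p-values are reported, matching how such plan
comparisons are usually presented; adjust externally if needed.
Spearman's rho handles the correlation sets, and `rank_by_variant()`
counts, per metric, how often each collimator-angle variant is strictly
best across patients, splitting ties.

## The synthetic data model

The generator exists so every module can be exercised end to end with
inputs whose ground truth is known.  It emulates:

* a thorax-like medium map: an elliptic body cylinder (soft tissue,
  semi-axes 150 x 100 mm), two lung ellipsoids, a posterior vertebral
  column (bone) with a soft-tissue cord inside, and an oesophagus tube;
  default grid 64 x 48 x 40 voxels at 5 mm;
* lobed targets: a principal sphere plus seeded satellite lobes;
  one lobe is near-spherical, more lobes push mask-derived sphericity
  down; the PTV is the Euclidean margin expansion of the CTV (isotropic
  5-10 mm, as used clinically for these targets);
* plans: static plans with 3/4/5 principal fields (sampled with
  probabilities 25/35, 9/35, 1/35, field margins 5 mm transversal and
  8 mm craniocaudal) and a single 356 degree arc starting at gantry
  182 degrees with control points every 4 degrees (89 points; 5 mm
  isotropic margin);
* "film" planes: an axial plane (by default 26 mm caudal to the
  isocentre) carrying per-medium multiplicative offsets, Gaussian noise
  (as % of the plane maximum) and a rigid registration shift.

The dose engine is deliberately crude: a parallel beam per field or
control point, its aperture the penumbra-blurred (Gaussian sigma 5 mm)
beam's-eye-view projection of the PTV plus margins, attenuated
exponentially along the ray through the media (soft tissue 0.0055/mm;
lung, soft, bone at relative factors 0.25, 1.0, 1.6), normalized so the
PTV median equals the prescription.  This reproduces the qualitative
trade-offs the analysis is about -- the arc conforms better but bathes
more lung in low dose; static fields show sharp field edges that a
misregistered film turns into gamma failures -- but it is not a dose
calculation: no scatter, no buildup, no beam divergence, no MLC
geometry.  Collimator angle has no physical meaning in a parallel-beam
model; the variant axis (0, 30, 45, 90 degrees) perturbs only the
penumbra width (up to +6% at 45 degrees, echoing the wider jaw openings
of tilted collimators) and the monitor-unit proxy, purely so the
ranking and Table-style reports are exercised.  Monitor units are
sampled (static about 270, arc about 50 fewer), matching the direction
and size of the advantage such plans show, and prescriptions are drawn
from a palliative-dominated distribution (36 Gy most common).  Cohort
PTV volumes are sampled log-uniformly and kept within 145.2-2686.5 cm^3,
the range such cohorts span.

What passing tests therefore show is that the *analysis* is correct and
that injected effects of realistic size are recovered; they say nothing
about the fidelity of any dose engine to real beams, and cohort-level
numbers from the generator are not predictions of clinical values.

## Numerical choices and problem sizes

* DVH bin width 0.01 Gy by default; all DVH metrics are tested against
  sort/count oracles on grids up to 32^3 within one bin width.
* Gamma search: lattice $\Delta d/10$, cap $3\Delta d$, pattern-search
  refinement down to step/64; oracle equivalence is checked at a matched
  $\Delta d/20$ lattice on 20 seeded 32^2 smooth fields.
* Error-decomposition recovery uses 50 replicate cohorts of 10 plans on
  24^2 planes with per-plan offset jitter of 1% SD -- the scale of the
  plan-to-plan spread such film studies report.
* The end-to-end cohort checks run 10 patients on the default 5 mm grid;
  determinism is asserted by rebuilding the cohort from the same master
  seed.
* Degenerate inputs fail loudly: empty masks, all-zero differences,
  constant correlation inputs and sub-threshold gamma references raise
  errors or flagged degenerate results rather than silent numbers.

## Known limitations

* The DICOM layer reads explicit-VR little-endian RT Dose and RT
  Structure Set objects only -- enough for TPS exports and for its own
  fixture writer; compressed or implicit-VR files are rejected with a
  clear message.
* Rasterization assigns whole voxels by centre membership; no
  partial-volume weighting.  Tolerances in the tests quantify the
  effect.
* The film-to-TPS registration is assumed given; a rigid 2D shift can be
  supplied in the beam specification, but no registration is estimated.
* Surface area (and hence mask-derived sphericity) inherits the biases
  discussed above; at clinical 2-5 mm grids the shell surrogate
  $\tilde\Psi$ is the more stable shape descriptor, which is exactly why
  it exists.
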