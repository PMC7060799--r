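---
title: "Quality-controlled ventricular function analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-controlled ventricular function analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinemetrics)
```

## Scope

`cinemetrics` implements the analysis stages that sit *downstream* of cine
cardiac MRI segmentation: given labelled short-axis (SAX) and 2-/4-chamber
long-axis (LAX) cine stacks, it aligns them, derives biventricular volume
curves and filling/ejection dynamics, computes feature-tracking strain, runs a
battery of post-analysis quality-control (QC) checks, and provides the
statistical machinery for validation studies and normative reference tables.
Segmentation itself, and pre-analysis image-quality classifiers, are outside
the package: segmentations are inputs, and a pluggable `qc1_hook()` lets
external image-quality detectors contribute rules to the verdict.

Because no patient data ships with the package, every stage is validated
against a parametric biventricular phantom with analytic ground truth. The
phantom is first-class, tested code, not a fixture: its defaults encode the
acquisition conditions the pipeline is meant for (UK-Biobank-style cines,
50 frames per cycle, 8 mm slices with 2 mm gap, ~1.8-2 mm in-plane), and its
prescribed physiology uses published cohort-mean volumes (LV EDV 179 ml /
ESV 77 ml, RV EDV 196 ml with the RV stroke volume matched to the LV).

## The phantom

### Geometry

The LV blood pool is a half-ellipsoid: base plane at $z=0$, apex at $z=L$
(default $L = 90$ mm), with circular cross-sections of squared radius
$r^2(z,t) = a^2(t)\,(1 - z^2/L^2)$. Prescribing the pool volume $V(t)$ fixes
the in-plane semi-axis analytically, $a(t) = \sqrt{3V(t)/(2\pi L)}$. The
myocardium is a concentric shell of constant wall volume (default 100 ml,
so LV mass is $105$ g at the 1.05 g/ml tissue density); its epicardial
surface extends `apex_wall` (8 mm) beyond the pool apex so the apex is
covered by wall, and the outer semi-axis is again closed-form from the
conserved shell volume.

The RV is a crescent wrapped around the LV free wall: in every SAX section it
is an annular sector between the epicardium (plus a 2 mm gap) and an outer
arc, spanning 2.4 rad. Rather than clipping two ellipsoids against each other
(which leaves the RV volume without a closed form), the crescent's
cross-sectional *area profile* is prescribed directly,
$A(z,t) = V_{RV}(t)\, w(z)$ with a parabolic $\int w = 1$ profile, and the
outer radius solved per section. This keeps the RV volume curve exactly
analytic, so RV volumetry can be held to the same closed-form oracle as the
LV — which is what makes an RV ejection-fraction recovery check possible at
all without external data.

Labels are rasterized by evaluating these implicit surfaces at voxel centers
of the SAX grid, and *exactly* on the two LAX planes (the 4-chamber plane
$y=0$ contains the RV; the 2-chamber plane $x=0$ shows only the LV, as in
clinical planning). Because in-plane thresholds are scalars per slice and
frame, rasterization is vectorized and a 1 mm, 50-frame study builds in a
few seconds.

### The volume-curve model

Ventricular volume over one cycle is C¹ and piecewise raised-cosine in
$dV/dt$: a monotone ejection from EDV to ESV on $[0, t_{ES}]$, an explicit
diastasis, then E- and A-wave refilling as two localized raised-cosine
pulses. All timings are fractions of the RR interval. A pulse of area $S$
and width $w$ peaks at $2S/w$, so every parameter the pipeline estimates has
a closed form:

* peak ejection rate $\mathrm{PER} = 2\,SV/(t_{ES}\,RR)$,
* peak early filling rate $\mathrm{PEFR} = 2E/(w_E\,RR)$,
* peak atrial filling rate $\mathrm{PAFR} = 2A/(w_A\,RR)$,
* atrial contribution $\mathrm{AC} = A$ (the A-wave volume).

Defaults ($t_{ES}=0.35$, E peak at $0.5$ of width $0.2$, A peak at $0.85$ of
width $0.15$, A wave taking 30% of the stroke volume) give end-systolic and
time-to-peak values in the ranges reported for healthy middle-aged adults.
`wave_widths` are kept as RR fractions rather than seconds so the model is
independent of heart rate; rates are converted to ml/s by the RR interval
where needed.

### Ground-truth deformation

Motion is purely radial about the long axis: at each height the endocardial
and epicardial radii follow their analytic values, points inside the pool
scale proportionally, wall points interpolate linearly between the two
surfaces, and the displacement decays over 15 mm outside the epicardium.
Because the mid-wall point is the endo/epi midpoint and the radial map is
linear across the wall, the mid-wall ring radius — and hence circumferential
strain — is analytic: $\varepsilon_{circ}(t) = r_{mid}(t)/r_{mid}(0) - 1$
(`phantom_ecc_curve()`). Fields are zero at the ED frame by construction
(cycle consistency) and are rasterized per view as in-plane displacement
components along the image row/col axes, in mm.

### What the phantom does not emulate

No MR contrast, noise, bias fields, k-space or motion artifacts; no
papillary muscles, trabeculation, valve-plane motion or longitudinal
shortening (the deformation has no $z$ component, so phantom longitudinal
strain is small and is not used as an accuracy oracle). Passing phantom
tests therefore demonstrates correctness of the *measurement chain* —
geometry, volumetry, derivative estimation, tracking arithmetic, QC logic —
not robustness to real-world image degradation, which is exactly the part
the upstream segmentation network and pre-analysis QC own.

## Alignment

Breath-hold offsets between cine acquisitions are corrected as one in-plane
translation per SAX slice (and per LAX view): the dominant error mode, since
each slice is acquired in a separate breath-hold while rotation and
through-plane errors are comparatively small. The objective for a slice is
the mean absolute distance, along the slice's intersection lines with the
two LAX planes, between LV boundary crossings seen in the SAX slice and in
the LAX view. Only LV labels (pool + myocardium) enter the objective: the
2-chamber view contains no RV, so including RV crossings would make the two
views structurally inconsistent.

Crossings are localized at sub-voxel precision by linearly interpolating the
bilinear-sampled LV indicator to its 0.5 level. The search is coordinate
descent per axis — a 2 mm coarse grid over ±15 mm, a 0.5 mm fine grid around
the coarse optimum, then golden-section refinement — with a small penalty of
0.1 per mm of shift magnitude. The penalty acts as a minimal-motion prior:
the transition-point objective has quantization plateaus, and without the
penalty consistent slices can wander within a plateau. Slices whose section
contains no blood pool (apical cap) keep zero shift: there the wall-boundary
chord changes so fast along the long axis that the objective is biased by
the finite slice spacing. SAX and LAX updates alternate (ED frame only, the
correction applied to all frames) until the largest update falls below
0.1 mm or 10 iterations. On phantoms, injected shifts up to 8 mm are
recovered within one voxel and already-aligned studies are left untouched.

## Volumetry and dynamics

Volumes use Simpson slice summation: label area (voxel count × in-plane
voxel area) times the inter-slice distance (slice thickness + gap). No
partial-voxel or basal/apical correction is applied — coverage problems are
QC's job to *flag*, not volumetry's to silently repair.

Curves are smoothed by periodic Fourier truncation (10 harmonics by
default). The cardiac cycle is periodic, so a spectral representation avoids
endpoint artifacts, and the derivative is exact for the retained harmonics.
Peaks are located by evaluating the truncated series and its derivative on a
512-point refined cycle grid — sampling the derivative only at the 50
acquired frames would bias narrow peaks (the A wave spans ~7 frames) low by
several percent. ED is the argmax and ES the argmin of the smoothed curve
(not frame 0, guarding against acquisitions that do not start exactly at
ED); EDV/ESV are read from the raw curve at those frames. Diastolic dV/dt
maxima below 10% of the diastolic peak are discarded as Gibbs ripple before
the E/A assignment; if only one substantial diastolic peak remains, the E
and A waves are fused and PAFR/AC are reported missing with the reason
`"no A-wave detected"`. AC is defined from the diastasis: the volume gained
between the $|dV/dt|$ minimum (between E and A peaks) and end-of-cycle ED —
one of several conventions in the literature, stated here explicitly because
the quantity is often reported without one. Against the closed forms, peak
rates and AC are recovered within ~2% at 50 frames (the 10-harmonic
truncation dominates the error); EDV/ESV/SV/EF within 1-2% at 1-2 mm
voxels.

## Strain

ED contours are sampled on 3 SAX slices at 25/50/75% of the segmented LV
extent: sub-voxel endo- and epicardial boundaries (marching squares at the
0.5 level of the label indicator), low-passed by Fourier truncation of the
complex contour coordinate (12 harmonics) and resampled to 48 points
uniformly by arc length with a canonical start and orientation. The low-pass
matters: raw marching-squares polygons carry voxel staircase detail that
inflates perimeters, and the bias worsens as contour points are added. The
mid-wall contour is the pointwise endo/epi average; each LAX view
contributes an open mid-myocardial midline (angular sweep of wall pixels
about the pool centroid, base opening excluded).

Tracking is pluggable. The reference path advects contour points through
supplied displacement fields (phantom ground truth, or any external
registrar's output read from 5-D NIfTI) by bilinear interpolation. A
built-in single-level demons-style tracker (iterated intensity-gradient
force with Gaussian fluid/field regularization, frame-to-frame, composed to
ED→t) covers the images-only case; it is a baseline, not a claim to
state-of-the-art registration, and the tested contract is the strain
arithmetic downstream of whichever tracker is used.

Strain is Lagrangian, in percent, relative to ED: circumferential from the
mid-wall perimeter ratio (mean of 3 slices), radial from the mean endo-epi
thickness ratio, longitudinal from the LAX midline arc-length ratio per
view. $\varepsilon(0) = 0$ exactly; peaks are signed extrema (negative for
circumferential/longitudinal, positive for radial) with times-to-peak in ms.
With ground-truth fields the phantom's analytic circumferential strain is
recovered within ~0.15% strain at 1 mm voxels; the residual is the field's
bilinear-interpolation bias, so it saturates rather than decreasing as
contour points are added (the discretization component proper does decrease,
which is what the contour-density property test measures on analytically
deformed elliptical contours).

## Post-analysis QC

Three geometric rules compare the aligned views at ED: (i) the LAX planes
must cross LV labels in both the most basal and most apical LV-bearing SAX
slices; (ii) the SAX LV extent along the long axis must cover ≥ 90% of the
LAX LV extent (missing-slice detection); (iii) the symmetric coverage check,
LAX against SAX. Two plausibility rules inspect the outputs: LV and RV
stroke volumes may differ by at most 10% — of their *mean*, a denominator
the rule must pin down explicitly since "percent difference" alone is
ambiguous — and first/last-phase volumes must close within 10% per chamber.
All thresholds are configurable; 90% coverage is a package default chosen to
catch one missing basal slice of a typical 10-slice stack while tolerating
sub-slice trimming.

Two soft-margin RBF SVMs (C = 1, standardized features, 5-fold CV, seeded)
classify volume and strain curve shapes as good or anomalous. Features are
the curve resampled to 32 points and normalized to unit amplitude, plus
scalar descriptors (relative excursion, closure gap, maximum frame-to-frame
jump, time of extremum). The training corpus is synthetic:
`make_curve_dataset()` jitters the phantom curve family for the good class
and injects four pathology types (cycle non-closure, single-frame spikes,
sign-flipped strain, clipped systolic plateaus) for the bad class, each
labelled. On a held-out draw of the same generator the classifiers exceed
0.90 balanced accuracy; this validates the feature/classifier machinery, not
performance on any clinical corpus, which would require expert-labelled
curves.

The verdict is deliberately monotone and conservative: an exam is flagged
for review iff any rule flags or any SVM votes anomalous; `not_applicable`
rules never flag; any pipeline stage that throws is converted into a flag
naming the stage, so a case report always carries a verdict.

## Validation statistics and reference values

`refstats` collects the estimators a validation study needs: Dice overlap
(defined 1.0 for two empty masks), Bland-Altman bias with
$\mathrm{bias} \pm 1.96\,\mathrm{SD}$ limits of agreement and a paired
t-test of the bias against zero (zero-variance differences are reported as
p = 1 for zero bias, p = 0 for an exact shift), error-detection summaries
(sensitivity, specificity, balanced accuracy = their mean), and paired or
Welch comparisons of mean absolute errors.

Reference values are computed per sex × age-decade stratum (45-54, 55-64,
65-74). Within each stratum and parameter, values beyond 3 interquartile
ranges below Q1 or above Q3 are removed *a priori* — with type-7
(linear-interpolation) quartiles, pinned explicitly because the 3-IQR fence
moves with the quartile convention — and the reference range is the
Gaussian 95% prediction interval
$\bar{x} \pm t_{0.975,\,n-1}\, s \sqrt{1 + 1/n}$, whose empirical coverage
on fresh draws is 93-97% in simulation (1,000 replicates at n = 600). A
percentile-based interval is available behind `pi_method = "percentile"`
for skewed parameters. Age trends are ordinary least squares per sex with
Bonferroni correction over the parameters of that sex's family
(adjusted p = min(1, m·p), significance at 0.05).

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; world coordinates in mm; times in seconds;
  frame 0 is the ED trigger and frames form one closed cycle; the first and
  last frames are distinct acquisitions (the closure QC rule depends on
  this reading).
* Uniform frame timing $t_k = k\,RR/n$ is assumed when per-frame trigger
  times are absent.
* Label convention: 0 background, 1 LV pool, 2 LV myocardium, 3 RV pool; a
  `label_map` in the bundle sidecar remaps other encodings on read.
* NIfTI-1 stores orientation in float32; the bundle sidecar carries the
  affine at full precision and is preferred on read, so round-trips are
  exact to 1e-9.
* Constant curves: amplitude normalization in QC features is guarded;
  prediction intervals of constant strata degenerate to the constant.
* Empty strata are marked unavailable; strata under 20 subjects warn.
* Simulation sizes in the test suite (phantom resolutions of 1-3 mm,
  20-50 frames, 100-phantom QC specificity batch, 1,000-replicate coverage
  runs) were chosen as the smallest sizes at which the measured quantities
  are stable against their tolerances.

## Known limitations

* Alignment corrects translations only; a rotated LAX plan is detected by
  QC (intersection rule) rather than corrected.
* The demons tracker is 2-D per slice and single-level; for clinical images
  an external registrar via the displacement-field path is the intended
  route.
* Phantom longitudinal strain is not an accuracy oracle (no longitudinal
  motion in the deformation model).
* Reference tables from phantom cohorts exercise the *procedure*; the
  numbers themselves are only as meaningful as the cohort fed in.
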