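---
title: "Measuring acetabular orientation from pelvic landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular orientation from pelvic landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetorient)
```

## The measurement problem

The acetabulum opens along a direction — the acetabular axis — that clinical
practice summarizes as an inclination and an anteversion. Murray's taxonomy
distinguishes three coexisting definitions: *anatomical* (the axis against
the body's longitudinal axis and transverse plane), *operative* (the axis
against the sagittal plane, the frame a surgeon sees with the patient in
lateral position), and *radiographic* (the projection geometry of an
anterior–posterior film). All six numbers describe one socket, and none of
the three pairs can be converted exactly into another by the simple formulas
often quoted for the purpose.

Measuring any of them on CT requires a reference frame. Scanner axes are a
poor one: a few degrees of pelvic tilt or rotation on the table move every
angle. This package instead builds patient-specific planes from bony
landmarks, so the measurement is invariant under rigid repositioning — a
property the test suite checks to 1e-9 degrees.

## Geometry

**Acetabular axis.** The rim points of one hip are fitted with the
total-least-squares plane: the plane through the centroid whose normal is
the smallest-variance direction of the centered cloud (smallest right
singular vector). This minimizes the sum of squared orthogonal distances,
and the third singular value gives the rms residual. The socket floor is not
flat, which is why the rim — not the lunate surface — defines the face; a
sphere fit is deliberately out of scope since the rim-plane normal is the
established estimator of the axis and its bias against a sphere-fit axis is
known to be negligible. The normal's sign is resolved by `orient_axis()`:
the axis must point laterally (positive component along the left–right axis
towards the fitted side). An axis with no lateral component is reported as a
hard ambiguity error, never silently resolved, because the sign of
anteversion would be meaningless.

**Reference planes.** The coronal plane is the anterior pelvic plane through
the two ASIS and two pubic tubercles — a supine-position surrogate for the
true coronal plane, fitted by the same total-least-squares criterion since
the four points are generically non-coplanar. The sagittal plane passes
through the ASIS midpoint and the sacral-crest points. Orientation
conventions are fixed and documented: coronal normal anterior (away from the
sacral centroid), sagittal normal to the patient's right, longitudinal axis
cranial, transverse axis from left ASIS towards right.

**The transverse plane** is constructed, not measured: its normal is the
cross product of the coronal and sagittal normals, which makes it exactly
perpendicular to the sagittal plane and perpendicular to the coronal plane
to machine precision. An alternative construction sometimes written down —
crossing the ASIS-to-ASIS vector with the sagittal normal — is geometrically
suspect, because that vector is nearly parallel to the sagittal normal and
the cross product is close to degenerate; for a perfectly symmetric pelvis
it vanishes entirely. Both constructions are implemented
(`transverse_mode = "orthogonal"` / `"literal"`); the orthogonal one is the
default, and the literal one raises a degenerate-geometry error rather than
returning an unreliable direction. The literal mode takes "the ASIS vector"
to mean left-ASIS → right-ASIS, since no other reading is standard.

**Angles.** Every angle reduces to θ = cos⁻¹(u·v/|u||v|) (argument clamped
to [−1, 1], since the formula is numerically fragile near 0° and 180°) and
to point/vector projection onto a plane via the foot-of-perpendicular
formula. Two reporting conventions matter:

* *Inclination folding.* The oriented axis of a normal hip points
  infero-laterally, so the raw angle against the cranial longitudinal axis
  is obtuse — about 140° for a 40° cup. Reported inclinations are folded,
  `min(θ, 180° − θ)`, which lands canonical anatomy in the clinical 30–60°
  range; the raw oriented angles are kept in `AI_raw`/`RI_raw` for
  diagnostics, and folding can be disabled (`fold = FALSE`).
* *Anteversion sign.* Positive means anterior. Retroverted sockets give
  negative values and are reported as such, never clamped.

Degenerate projections (axis within 1e-8 of a plane normal) yield `NA` plus
a flag, never a silent zero. The parallel/zero threshold of 1e-8 is far
below the ~0.1 mm precision of CT landmarks at mm scale.

In frame components (ℓ, a, c) = (lateral, anterior, cranial) of the unit
axis, the whole pipeline collapses to closed forms — AI = cos⁻¹|c|,
AA = sign(a)·cos⁻¹(ℓ/√(ℓ²+a²)), OI = sin⁻¹ℓ, OA = sign(a)·tan⁻¹(|a|/|c|),
RI = tan⁻¹(|ℓ|/|c|), RA = sin⁻¹ a — which the tests use as an independent
oracle against the projection-based implementation (agreement within 1e-9°
on 1000 random axes).

## Conversion-formula residuals

`murray_residuals()` evaluates, exactly as printed in the clinical
literature this package engages with,

* r1 = OA − tan⁻¹(sin RI · cos RA)
* r2 = AA − tan⁻¹(cos OI · cos OA)
* r3 = RA − sin⁻¹(tan OI · cos OA), flagged undefined when the arcsin
  argument leaves [−1, 1].

These are implemented verbatim even though they are not the geometrically
consistent identities (the second and third conversions are even printed
identically in some sources, while the residual forms differ — the residual
forms are what is implemented). On angle sets produced by exact geometry the
residuals are systematically non-zero, e.g. r2 = −45° already at the
all-zero corner; the point of computing them is to show that these published
conversions do not transform one measurement system into another. With
`consistent = TRUE` the geometrically exact identities
OA = tan⁻¹(tan RA / cos RI), AA = tan⁻¹(tan OA / tan RI),
RA = sin⁻¹(sin AA · sin AI) are evaluated alongside; their residuals vanish
on exact geometry, which separates "the formulas are wrong" from "the
geometry is noisy".

## The synthetic-pelvis generator

`generate_pelvis()` emulates the landmark-labelling protocol, not bone
surfaces. In a canonical frame (x left→right, y posterior→anterior,
z caudal→cranial) it lays the ASIS pair (240 mm apart) and pubic tubercles
in the APP, the ASIS midpoint and three sacral points in the midline plane
with the sacrum 90 mm posterior and caudal to the ASIS level, and per hip 30
rim points on a 25-mm circle whose normal realizes the requested anatomical
(AI, AA), leaving a 60° arc empty for the transverse acetabular ligament.
The pelvic dimensions are plausibility values for test realism, not
measurements. Noise is applied last: out-of-plane rim offsets, isotropic
landmark jitter (a stand-in for manual labelling error), and a rigid pose
(tilt/rotation/translation) emulating scanner placement. Noise defaults are
zero — the defaults encode the exact protocol geometry, and each experiment
states its own noise level explicitly. Ground truth (all six angles via the
closed forms, the true axes and planes) records pre-noise values, and all
randomness is seed-threaded with no global state. `perturb_rater()`
re-jitters every landmark to drive the two-rater 2-mm agreement check;
`generate_cohort()` draws per-case true angles, demographics (57% male,
age bins <30/[30,40)/[40,50)/≥50 in proportions 18/8/19/4, ages 18–56) and
poses for a 49-case, 98-hip cohort.

What the generator does **not** emulate bounds what passing tests show. Its
APP coincides with the body's true coronal plane, so inter-system
differences arise purely from the angle definitions; in real cohorts the
APP is additionally tilted relative to the standing coronal plane, which is
a major contributor to the observed anatomical-vs-radiographic divergences
and is deliberately not modelled (no functional-position correction).
Labelling error is isotropic Gaussian, with no reader bias along the rim;
there is no segmentation noise, no osteophyte distortion, and the two hips
of one case share one true orientation. Cohort-level conclusions from the
simulation therefore validate the machinery, not population values.

## Statistics

The sampling unit is the hip: two hips of one case enter as independent
records, and the within-patient correlation this ignores is a documented
limitation of the analysis design rather than something corrected here.
Specific choices:

* Normality uses the Kolmogorov–Smirnov statistic with mean and sd estimated
  from the sample, which requires the Lilliefors correction
  (`nortest::lillie.test`); the uncorrected KS p-value would be drastically
  conservative. Verified type-I error ≈ 0.05–0.06 at n = 98.
* If RI fails normality, parametric comparisons use its Blom rank-normal
  scores Φ⁻¹((rank − 3/8)/(n + ¼)), rescaled to RI's original mean and sd so
  the variable keeps degree units.
* The perpendicularity audit compares plane angles against the constant 90°;
  that is a one-sample t-test (an "unpaired" two-sample test against a
  constant is not a defined procedure, so the one-sample form is used and
  said so).
* Age-group comparisons of a continuous angle by chi-square are
  underspecified; the implementation tests the bins × (above/below cohort
  median) contingency table and reports a one-way ANOVA across bins
  alongside.
* LSD contrasts are Fisher's procedure: pairwise t-tests on the pooled
  within-group mean square with unadjusted p-values — that is what LSD
  means. `adjust = "bonferroni"` is available for modern practice.

## Validation design and problem sizes

The suite validates each layer against an independent oracle: plane fits
against a brute-force search over normal directions (Fibonacci lattice plus
Nelder–Mead refinement, agreement within 1e-3 mm rms on random 10-point
clouds); angle measures against the closed forms above; the full
generate→measure round trip (exact to 1e-6° without noise; median absolute
error under 1.5° per angle at 1 mm jitter over 200 replicates); rigid-motion
invariance over 100 random poses; and test calibration by simulation (1000
null replicates for the KS and vs-90° tests). The three-group
ANOVA-plus-LSD pattern — clearly separated anatomical mean, nearer operative
and radiographic means whose mutual contrast is the weakest — holds in about
91% of simulated cohorts (means 37/45/49, sd 12, n = 98 per group); because
that proportion sits close to the 90% mark, the check estimates it with
2000 replicates rather than 100 so the Monte-Carlo error (≈0.6%) is small
against the margin. Everything runs on a laptop-scale budget: the largest
single computation is the 2000-replicate ANOVA simulation (~5 s).

## Two-rater agreement

Rim and sacral points carry no stable identity between two raters'
labellings, so `rater_agreement()` compares named landmarks directly and
point clouds by the symmetric nearest-neighbour (Hausdorff) maximum — the
symmetric form is used so agreement does not depend on argument order. A
labelling passes when every per-role distance is under 2 mm.

## Known limitations

* The APP is a supine surrogate for the coronal plane; no pelvic-tilt or
  spinopelvic correction is applied.
* The ligament-gap arc is recorded (`arc_coverage_deg`) but its effect on
  the rim centroid is not corrected.
* Cup-prosthesis measurement from 2-D radiographs (ellipse axes), safe-zone
  computation and sphere fitting are out of scope.
* Side-within-patient correlation is ignored in all cohort tests.
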