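---
title: "Single-point superposition of serial arch scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-point superposition of serial arch scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucsalign)
```

## The measurement problem

Serial intraoral scans of the same arch — start of aligner treatment (T0)
and the refinement phase (T1) — arrive as STL triangle meshes in millimetre
coordinates. Tooth displacement between them can only be measured after both
models share a frame. Surface-based best-fit registration (ICP) is the usual
answer, but it requires stable reference surfaces and specialised software;
the single-point protocol implemented here instead relies on two facts:

* intraoral scanner pipelines express both exports in a consistent Cartesian
  orientation (X buccolingual, Y mesiodistal, Z vertical), and
* the anterior palate (palatal suture and second ruga) and the mandibular
  midline mucogingival junction are stable landmarks over treatment.

One reference point per model is constructed as the intersection of a
vertical and a horizontal guide line through those structures; copying the
point's X/Y/Z coordinates from T1 to T0 and translating makes the two models
coincide at the landmark. The transform is translation-only *by design*:

```{r}
lm0 <- intersect_guides(guide_line(c(0, -5, 0), c(0, 45, 0), "vertical"),
                        guide_line(c(-10, 24, 0), c(10, 24, 0), "horizontal"))
lm1 <- lm0; lm1$x <- lm1$x + 2; lm1$y <- lm1$y - 1; lm1$timepoint <- "T1"
ucs_superpose_transform(lm0, lm1)
```

### What the method assumes, and its negative control

Translation-only superposition is exact when the two scans differ by a pure
translation of the scanner pose. If the T1 frame is additionally *rotated*
relative to T0, a single point cannot recover the rotation, and residuals
grow linearly with distance from the landmark: a rigid rotation by angle
$\theta$ about the vertical axis leaves a residual of $2\sin(\theta/2)\,r$
at in-plane distance $r$ from the landmark. A 5° frame rotation therefore
produces millimetre-scale errors at molar distance. The package does not
attempt a correction — a multi-point (Kabsch) alignment is a different
method — but ships this as a regression-tested negative control so the
assumption is visible, not hidden.

## Landmark construction

Guide lines are idealised as infinite straight lines through two picked
points each. Real picks are skew, never exactly intersecting; the landmark
is defined as the midpoint of the mutual-perpendicular segment between the
two lines, and the segment length is reported as `gap_mm`. Choices:

* **Warning tolerance 0.5 mm** on the gap: a miss larger than half a
  millimetre indicates inconsistent picks between the two guide lines and
  deserves operator attention, while sub-half-millimetre gaps are within
  ordinary digitization scatter.
* **Parallel guard**: directions within $10^{-6}$ rad of parallel have no
  well-defined perpendicular and raise a degenerate-geometry error.
* **Snapping (default on)** projects the abstract intersection point onto
  the mesh surface via an exact closest-point-on-triangle query (Ericson's
  algorithm, deterministic lowest-face-index tie-break). Superposition only
  needs coordinates, so snapping is optional; it exists because a landmark
  on the mucosa surface is visually checkable.

## Movement measurement conventions

All measurements operate on digitised tooth points after superposition:
buccal cusps of canines, mesiobuccal cusps of premolars and molars
(translations), canine cusp tips and incisal-edge points (vertical and
rotation).

* Translations are axis projections (X buccolingual, Y mesiodistal), in mm,
  signed. Summary tables report magnitudes alongside, since published
  per-tooth means are non-negative and signs depend on side conventions.
* Vertical movement projects onto the `arch_frame()` gingival direction:
  positive = intrusion, negative = extrusion. The gingival direction depends
  on how the dataset orients the arch (occlusal surfaces up or down) and
  must be set per dataset; the default `+Z` matches the synthetic arches,
  whose cusps point toward `+Z`.
* Rotation is the angle between the T0 and T1 incisal-edge lines *projected
  into the occlusal plane*, treated as undirected lines, so the value lies
  in \[0°, 90°\]. Projection makes the measure insensitive to simultaneous
  intrusion; the undirected convention removes the 180° ambiguity of
  swapped mesial/distal picks. The tooth long axis is not observable from
  two edge points, so rotation about the long axis is approximated by this
  occlusal-plane angle — a documented approximation, not a free choice.
* Arch expansion is the change in antimeric inter-cusp distance, positive
  for widening.

Missing counterpart points yield records with `status = "missing"` rather
than silent omission, so a batch over a full arch always returns one row
per planned measurement.

## Reliability statistics

The agreement toolkit mirrors the two-measurement repeated design used to
validate digital-model protocols (one examiner twice, 15 days apart; a
second examiner once):

* **ICC(2,1)**, two-way random effects, single measurement, absolute
  agreement, from the ANOVA mean squares
  $\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$,
  with the Shrout–Fleiss / McGraw–Wong F-based 95% CI. Zero total variance
  is a typed error — an ICC is undefined there, and returning `NaN` would
  propagate silently into tables.
* **Category bands**: the published bands (0.9–1 excellent, 0.6–0.7 good,
  0.4–0.5 reasonable, <0.4 poor) leave 0.5–0.6 and 0.7–0.9 unnamed. The
  package absorbs each gap into the band below (excellent \[0.9, 1\], good
  \[0.6, 0.9), reasonable \[0.4, 0.6), poor < 0.4), closed on the left:
  total coverage without inventing new categories.
* **Dahlberg's error** uses the classical form $\sqrt{\sum d_i^2 / 2n}$.
* **Systematic-error gates** are inclusive: linear error ≤ 1 mm and angular
  error ≤ 1.5° pass ("should not exceed" reads naturally as an inclusive
  bound).
* **Bland–Altman** uses bias ± 1.96 · SD of differences with the $n-1$
  denominator; per-pair means/differences are kept for plotting
  (`autoplot()`).
* **Paired t-test** is two-sided with $n-1$ df. Identical vectors have zero
  difference variance; by convention the result is flagged and reported as
  $t = 0, p = 1$ (no detectable systematic difference), again avoiding
  `NaN`.

## The synthetic generator

`generate_arch()` places conical teeth along a parabolic arch curve
(defaults: 7 teeth per side, 50 mm wide, 40 mm deep, 8 mm crowns — adult
arch dimensions). Each cone apex *is* the cusp/incisal landmark, so applied
movements are recoverable exactly; incisors and canines carry
incisal-edge points offset ±1.5 mm along the local arch tangent. Guide
lines are emitted intersecting exactly on the base plane.
`apply_movements()` rotates each listed tooth about its own vertical axis,
translates it by its signed X/Y/Z components, then applies a global pose
change to the whole T1 scene. Per-tooth displacements are applied along the
global coordinate axes — the same axes the measurement stage projects onto —
because that is what the shared-frame convention means geometrically; it is
also what makes ground-truth closure an exact identity rather than an
approximation. Default movement magnitudes in examples (0.15–0.55 mm
translations, 5–9° rotations) sit in the range reported for aligner
refinement cases.

What the generator does *not* emulate: real crown morphology, gingiva and
rugae geometry, scanner surface noise, occlusion. Passing recovery tests
therefore demonstrate the correctness of the geometry and statistics
pipeline, not robustness to anatomical landmark ambiguity — on real scans
the dominant error source is operator point placement, which is modelled
separately and statistically by `simulate_digitization()` (isotropic
Gaussian jitter) and `simulate_rater_study()` (additive two-way model, so
the expected ICC is $\sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$).

## Numerical and I/O choices

* All internal geometry is double precision; STL stores float32, and writers
  quantize coordinates to float32 up front so ASCII and binary encodings of
  one mesh are bit-equal after reading.
* STL dialect detection treats a file as ASCII only if it parses fully as
  ASCII — a leading `solid` alone is not trusted, since some binary
  exporters write it.
* On read, soup vertices closer than $10^{-6}$ mm are merged (STL has no
  shared-vertex concept); binary size errors report the byte offset at
  which the file diverges from `84 + 50·n` bytes.
* Angles near 0° and 90° use `atan2` of the cross/dot magnitudes rather
  than `acos`, keeping recovery exact to ~$10^{-13}$ degrees.
* Sidecar points are JSON (canonical) or CSV (spreadsheet convenience,
  decimal point mandatory, offending row named on failure).

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use a 14-tooth arch
(224 faces), 200 random small rater matrices for the ICC cross-check,
n = 500 subjects for ICC parameter recovery, and n = 10,000 draws for the
Bland–Altman coverage and digitization-SD checks — sizes at which
Monte-Carlo error is comfortably below the asserted tolerances while the
whole suite runs in seconds.

## Known limitations

* A relative rotation between the T0 and T1 scanner frames is not corrected
  (see the negative control above); the method presumes a shared Cartesian
  orientation, e.g. exports from the same scanner pipeline.
* Rotation is an occlusal-plane projection, not a long-axis decomposition;
  torque/tip are out of scope.
* Anatomy (suture, rugae, mucogingival junction) is identified by the
  operator; no automatic detection from geometry is attempted.
* Only STL is read; PLY/OBJ, mesh repair and texture attributes are out of
  scope.
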