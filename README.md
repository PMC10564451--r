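# ucsalign

Superimposition of serial 3D dental-arch scans by a **single-point universal
coordinate system (UCS)**, and quantification of orthodontic tooth movement
between time points.

Digital aligner treatment produces intraoral-scanner STL models of the
maxillary and mandibular arches at the start of treatment (T0) and at the
refinement phase (T1). To measure how far each tooth actually moved, the two
models must first be brought into a common frame. `ucsalign` implements the
single-point protocol used in clinical digital-model studies:

1. **Landmark** — on each arch, a vertical guide line (palatal-suture midline
   in the maxilla; midline in the mandible) and a horizontal guide line
   (second palatal ruga; mucogingival junction) are intersected to define one
   stable reference point per model. Operator picks never intersect exactly
   in 3D, so skew guide pairs resolve to the midpoint of their common
   perpendicular, with the miss distance (`gap_mm`) reported and gated.
2. **Superpose** — both scans express coordinates in the same Cartesian
   orientation (X buccolingual, Y mesiodistal, Z vertical), so superposition
   reduces to translating T1 by `point(T0) − point(T1)`; the rotation is the
   identity by construction. The package verifies, and documents with a
   negative control, that this is translation-only: a relative rotation
   between scanner frames is *not* corrected.
3. **Measure** — per-tooth movements from cusp/incisal-edge points:
   * buccolingual translation = X-component of the cusp displacement (mm);
   * mesiodistal translation = Y-component (mm);
   * vertical movement = projection on the gingival direction
     (+ intrusion, − extrusion, mm);
   * rotation = acute angle in \[0°, 90°\] between the T0 and T1
     incisal-edge lines projected into the occlusal plane;
   * arch expansion = change in antimeric inter-cusp width (mm).
4. **Reliability** — the full agreement toolkit used to validate such
   protocols: ICC(2,1) (two-way random effects, single measurement, absolute
   agreement) with its Shrout–Fleiss/McGraw–Wong 95% CI and the category
   bands (≥0.9 excellent, ≥0.6 good, ≥0.4 reasonable, else poor); Dahlberg's
   error `D = sqrt(Σd²/2n)` with the systematic-error gates (linear ≤ 1 mm,
   angular ≤ 1.5°); Bland–Altman bias and limits of agreement; and the
   paired t-test.

A synthetic-arch generator (`generate_arch()`, `apply_movements()`,
`simulate_digitization()`, `simulate_rater_study()`) builds cone-tooth
arches with *exact* cusp landmarks and known ground-truth movements, so the
whole pipeline is verifiable end to end without clinical scans.

## Worked example

Generate a mandibular arch, move one canine 0.4 mm buccally, intrude one
incisor 0.25 mm and rotate it 7°, offset the whole T1 scan by a scanner-pose
shift of (2, −1, 0.5) mm, then recover everything:

```r
library(ucsalign)

arch <- generate_arch(arch_spec("mandible"))
mv <- movement_spec(
  per_tooth = tibble::tibble(tooth_id = c("LR3", "LL1"),
                             buccolingual = c(0.4, 0),
                             vertical     = c(0, 0.25),
                             rotation     = c(0, 7)),
  global_offset = c(2, -1, 0.5))
pair <- apply_movements(arch, mv)

lm0 <- make_arch_landmark(arch$mesh, arch$guides$vertical,
                          arch$guides$horizontal, snap = FALSE,
                          arch = "mandible", timepoint = "T0")
lm1 <- make_arch_landmark(pair$mesh_t1, pair$guides_t1$vertical,
                          pair$guides_t1$horizontal, snap = FALSE,
                          arch = "mandible", timepoint = "T1")
sp <- superpose(pair$mesh_t1, lm1, lm0)
sp$transform
#> <rigid_transform> translation (-2.0000, 1.0000, -0.5000) mm; rotation identity

moves <- measure_arch(arch$points,
                      apply_transform(pair$points_t1, sp$transform))
dplyr::filter(moves, magnitude > 1e-9)
#> # A tibble: 4 × 8
#>   tooth_id movement                 value magnitude units  axis
#> 1 LR3      buccolingual_translation 0.400     0.400 mm     X
#> 2 LL1      vertical                 0.25      0.25  mm     Z
#> 3 LL1      rotation                 7.00      7.00  degrees XY-plane
#> 4 LL3:LR3  arch_expansion          -0.400     0.400 mm     XY-plane
```

The recovered transform is exactly the negated pose offset, and every
applied movement comes back to machine precision. The canine's +0.4 mm
X-shift also shows up as a −0.4 mm arch "expansion" (the right canine moved
toward the left one): signed values are kept throughout, magnitudes are
reported alongside.

Reliability on a simulated repeated-measurement study (26 subjects, two
measurements, operator error SD 0.05 mm):

```r
set.seed(1)
study <- simulate_rater_study(rnorm(26, 0.35, 0.3), sigma_error = 0.05,
                              seed = 1)
icc_2_1(as.data.frame(study))
#> ICC(2,1) absolute agreement: 0.9836  95% CI [0.9642, 0.9926]  (excellent)
#>   n = 26 subjects, k = 2 measurements
```

`bland_altman()` objects have `tidy()`, `glance()` and `autoplot()` methods;
`build_reliability_table()` produces the per-tooth × movement agreement
table (mean/SD per measurement, ICC + CI + category, Dahlberg + gate,
paired-t p, Bland–Altman bias and limits) in one call.

A thin command-line wrapper is installed at `inst/cli/ucs-superpose` with
subcommands `validate`, `landmark`, `superpose`, `measure`, `simulate` and
`reliability`.

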