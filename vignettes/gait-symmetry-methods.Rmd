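---
title: "Measuring gait symmetry from body surface normals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait symmetry from body surface normals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitnormals)
```

## The measurement problem

Gait symmetry — how alike the left and right halves of the body move during
walking — is a clinically useful screening signal for conditions such as
stroke recovery, arthritis, or leg-length discrepancy. `gaitnormals`
estimates a scalar asymmetry index from a sequence of frontal-view depth
maps of a subject walking in place on a treadmill, captured by a single
fixed time-of-flight camera. No markers, no skeleton fitting, no gait-cycle
detection and no inter-frame registration are required: the index is
computed from surface geometry alone and can be evaluated on a window of
arbitrary length covering one or more gait cycles (we recommend at least
two seconds of frames).

## Pipeline

1. **Segmentation.** Body pixels are either supplied as masks (e.g. from a
   sensor SDK's body labeller) or obtained by keeping pixels whose 3D
   reprojection falls inside a fixed 3D box above the treadmill
   (`segment_body()`). A frame with neither a mask nor a box is rejected:
   guessing the body region would silently poison every downstream index.
2. **Reprojection** (`reproject()`). Each masked pixel `(u, v)` with depth
   `d` maps to camera space by the pinhole model
   `x = (u - cx) d / fx`, `y = (cy - v) d / fy`, `z = d`.
   Camera space is right-handed with *x* to the image left, *y* up and *z*
   from the camera toward the subject; because stored rasters count rows
   downward, the row term is negated. Pixel indices are zero-based (the
   half-pixel-center convention would shift results well below the sensor
   noise floor). Depth is metres internally; zero depth is the
   invalid-pixel sentinel and such pixels are dropped before reprojection
   rather than reconstructed at the origin.
3. **Surface normals** (`estimate_normals()`). For each point, the points
   within a 3 cm closed ball (found with a uniform-grid spatial index, the
   query point included) define a neighborhood; the normal is the unit
   eigenvector with the smallest eigenvalue of the neighborhood's
   population covariance. All normals are oriented toward the camera
   (non-positive *z* component): every surface the depth camera sees faces
   it. Normals are translation invariant, so the subject's position on the
   treadmill does not matter.
4. **Region accumulation** (`split_regions()`). The tight bounding box of
   the body silhouette is split at its midlines into a 2×2 grid —
   top/bottom × image-left/right, the coarse decomposition clinicians use
   to localize (upper/lower body, left/right side) — and the valid normals
   are summed per cell into four vectors `{vTL, vTR, vBL, vBR}`. Summing
   over large regions averages out per-point noise, which is why a small
   3 cm neighborhood suffices upstream and no depth-map enhancement is
   performed at all.
5. **Plane angles** (`angle_transverse()`, `angle_sagittal()`,
   `angle_coronal()`). Left and right accumulated vectors are projected
   onto each anatomical plane and compared; on the transverse and coronal
   planes the right vector is first mirrored (about +z and +y
   respectively) so that a perfectly symmetric posture gives a zero angle;
   on the sagittal plane the projections of a symmetric pair already
   coincide and no reflection is needed. The per-posture index on a plane
   is the sum of the top-pair and bottom-pair angles (`basic_index()`),
   in radians; the lower-body variant keeps only the bottom term.

## Two temporal schemes and the weighted combination

With per-frame region vectors $v_1..v_n$:

* **frame-based** (`frame_index()`): average of per-frame indices,
  $I_f = \frac1n \sum_i I(v_i)$;
* **segment-based** (`segment_index()`): index of the mean posture,
  $I_s = I(\frac1n \sum_i v_i)$.

The distinction matters. During a *symmetric* walk the two legs are in
antiphase, so any single frame is strongly left-right asymmetric and $I_f$
stays large for everyone; in the time-averaged posture those periodic
differences cancel and $I_s$ is near zero for symmetric gait only. On the
bundled benchmark the segment scheme separates normal from abnormal far
better on the sagittal and coronal planes (the frame-based sagittal score
is actually *anti*-correlated with abnormality, because asymmetric gaits
swing less and so have smaller instantaneous angles). Because angles are
scale invariant, dividing the summed vectors by $n$ or not is immaterial;
the mean form is implemented literally.

`combined_index()` forms $I = w_t I_t + w_s I_s + w_c I_c$.
`fit_weights()` sets each weight to the *population variance* of that
plane's index over normal-gait training sequences — variance as a measure
of how much information the plane carries. Abnormal sequences must not be
used for fitting (the combination would be biased toward the particular
anomalies seen in training), and the weights are used unnormalized: AUC is
invariant to positive rescaling of scores, so a normalization would be
consequence-free. Pairwise combinations are zero-weight special cases.
Score polarity is uniform: larger = more asymmetric, for every plane and
scheme; the plain mean is used for the sagittal frame-based score as for
the others.

## Numerical and degenerate-case policy

* `acos` arguments are clamped to $[-1, 1]$; zero-angle configurations sit
  at the `acos` precision floor of about $2\times10^{-8}$ rad.
* A point whose neighborhood has fewer than 3 points, or whose two
  smallest covariance eigenvalues agree to within a relative gap of
  $10^{-9}$ (direction unidentifiable), gets no normal and contributes
  nothing downstream — degenerate points are skipped, never zero-filled.
* A region vector whose projection onto the requested plane has norm below
  $10^{-12}$ raises a degenerate-feature error; in sequence aggregation
  such frames are dropped with a warning, because a fabricated zero angle
  would spuriously signal symmetry.
* Grid cells are half-open: a pixel exactly on a midline goes to the
  left/top cell. Note this means a silhouette of odd pixel width is never
  split into exact mirror halves — the midline column belongs wholly to
  the left cell — so exact mirror-null tests use even-width fixtures.
* Box segmentation uses half-open inclusion `[min, max)` per axis for
  deterministic boundary behavior.
* "Left" and "right" are image-side labels (the image left is the
  subject's right in a frontal view). Every comparison is left-vs-right
  under one fixed convention, so the indices do not depend on which
  anatomical side the label denotes.

## The synthetic walking renderer

No public dataset ships with the package, so `simulate_walk()` renders
labelled sequences end to end: an articulated body — ellipsoid torso and
pelvis, sphere head, cylinder limbs with hands and feet — viewed by a
Kinect-2-like pinhole camera (512×424, 13 fps, camera 1.7 m above the
ground, subject 2.3 m away, optical axis parallel to the ground). Legs
swing sinusoidally about the hips at the configured cadence with the
contralateral arm in antiphase; surfaces are point-sampled in proportion
to their projected area, z-buffered per pixel (nearest wins; ties go to
the first-rendered primitive, torso first), and perturbed by i.i.d.
Gaussian depth noise (default sd 5 mm, a time-of-flight-like figure; the
true noise law of any given sensor is a config knob, not a claim). The
mask equals the rendered pixels, so segmentation is exact by construction
— the method under study begins after segmentation. With this camera
geometry the field of view cuts off roughly below the knees, as it does
in the physical setup being emulated.

Two abnormality families mirror how asymmetric gaits are produced in
treadmill studies:

* **lateral tilt** (`tilt_deg`): the whole body rolls about the depth
  axis, as when a sole is padded under one foot;
* **leg asymmetry** (`leg_asym = s`): one leg's swing amplitude is scaled
  by $1-|s|$, its phase delayed by $|s|\pi/8$, and its swing center
  shifted backward by $0.5|s|$ rad. The displacement term is essential:
  amplitude and phase changes alone are zero-mean, leave the mean posture
  unchanged, and would make the segment-based index provably blind to
  this family, whereas an ankle weight in reality produces unequal
  left/right displacement.

Design choices made once and kept: default swing amplitudes
(legs 0.25 rad, arms 0.18 rad) are typical of comfortable treadmill
walking; cylinder end caps are not sampled because a cap's normals have a
zero *z* component, which the camera-facing orientation rule cannot
disambiguate — their arbitrary signs destabilized the coronal feature;
the pelvis ellipsoid both closes the inter-thigh gap and gives the lower
grid cells enough stable lateral normal mass for the coronal angle to be
well conditioned. Sampling is mirror-symmetrized (each left/right
primitive pair shares one mirrored sample set), so the zero-asymmetry
body is exactly left-right symmetric in continuous space.

What the renderer does *not* emulate: clothing (which deforms real depth
maps; snug clothing is assumed), soft tissue, knee articulation, true
sensor noise statistics, or the treadmill/background (masks are perfect,
real segmentation is not). Passing tests on synthetic data therefore
demonstrate internal correctness and the expected orderings, not clinical
performance on any particular sensor.

A per-frame caveat worth stating: under perspective projection a
forward-swung leg (nearer the camera) renders larger than the backward
leg, so individual mid-swing silhouettes of a symmetric walk mismatch
their mirror image by up to ~20% at realistic amplitudes. The mismatch is
zero at the phase-aligned frames and cancels in the cycle average — which
is precisely the segment scheme's argument.

## Benchmark and evaluation

`make_benchmark()` builds 9 pseudo-subjects (stature 1.56–1.84 m, cadence
0.85–1.10 strides/s and swing amplitudes randomized per subject) × 9
gaits: 1 normal + lateral tilt at ±4°/±8° + leg asymmetry at ±0.2/±0.4,
200 frames per sequence with 5 mm depth noise — matching the
9-subjects × 9-gaits structure of published treadmill protocols. It
returns sequence *configurations*; `evaluate_all()` materializes each
with `simulate_walk()` on demand, so the 81-sequence benchmark runs in
ordinary memory. The benchmark camera is a 2×-binned 256×212 variant of
the full sensor, a problem size chosen so a complete evaluation runs in a
few minutes on one core; `walk_config()`'s full-resolution default is
used everywhere a single sequence is analyzed.

`roc_auc()` is the normalized Mann–Whitney statistic with midrank ties
(abnormal positive, higher score = more abnormal). `evaluate_all()`
reports, for all 12 variants {frame, segment} × {transverse, sagittal,
coronal} × {full, lower} plus the segment-based weighted combinations:

* **pooled AUC** over all sequences (raw index values pooled across
  subjects, no per-subject normalization);
* **leave-one-subject-out AUC**: combination weights are fitted on the
  *other* subjects' normal sequences only, and the held-out subject's own
  1-normal-vs-8-abnormal AUC is computed; the mean over subjects is
  reported. With a single normal sequence per subject these per-subject
  AUCs are high-variance by construction, which is flagged rather than
  hidden.

On the default benchmark the expected orderings emerge: segment-based
beats frame-based (dramatically so on the sagittal plane), the sagittal
plane separates best, and full-body beats lower-body — the upper body
carries usable information (arm swing, trunk tilt).

## Known limitations

* The 2×2 grid is deliberately coarse; finer grids or per-limb
  decompositions are out of scope.
* The index is a single scalar per window; no time-series structure
  (cycle segmentation, event demarcation) is extracted.
* Real-sensor concerns — clothing, segmentation errors, lens distortion,
  multi-path artifacts — are outside the synthetic benchmark's reach.
* The bounding-box segmenter assumes a fixed camera–treadmill geometry.
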