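# gaitnormals

Gait symmetry indices from body surface normals in frontal-view depth maps.

## What it does, and for whom

For clinicians and movement scientists screening for asymmetric gait
(stroke recovery, arthritis, leg-length discrepancy, post-surgery
follow-up), `gaitnormals` turns a sequence of depth maps of a person
walking on a treadmill — captured by a single fixed depth camera facing
the subject — into a scalar **gait asymmetry index**. Higher means more
asymmetric. The method needs no body markers, no skeleton fitting, no
gait-cycle detection and no frame registration.

Per frame, body pixels are reprojected to a 3D point cloud by the pinhole
model (x = (u−cx)d/fx, y = (cy−v)d/fy, z = d, metres, y up), a
camera-facing unit surface normal is estimated for every point from the
eigen-structure of its 3 cm-neighborhood covariance, and the normals are
summed over a 2×2 grid on the silhouette bounding box into four region
vectors {vTL, vTR, vBL, vBR}. Left and right vectors are compared as
angles on the three anatomical planes (transverse, sagittal, coronal),
mirroring the right side where the plane requires it so that a symmetric
posture scores zero; the per-posture index on a plane is the top-pair
angle plus the bottom-pair angle.

Two sequence-level schemes:

* **frame-based** `I_f = mean_i I(v_i)` — average of per-frame indices;
* **segment-based** `I_s = I(mean_i v_i)` — index of the *mean posture*,
  which lets the antiphase left/right motion of normal walking cancel
  before the angle is taken. This is the better detector.

A weighted combination `w_t I_t + w_s I_s + w_c I_c` uses per-plane
variances of normal-gait training indices as weights.

Because no dataset is bundled, the package includes a synthetic
articulated-body depth renderer (`simulate_walk()`, `make_benchmark()`)
emulating a Kinect-2 treadmill setup, with two controllable abnormality
families (lateral body tilt; unequal leg swing), plus an ROC/AUC
evaluation harness (`evaluate_all()`) with pooled and
leave-one-subject-out schemes.

## Worked example

```r
library(gaitnormals)

# two gait cycles with a 5-degree lateral tilt (as from a padded sole)
cfg  <- walk_config(n_frames = 26, tilt_deg = 5, noise_sd = 0.005, seed = 42)
seq  <- simulate_walk(cfg)
seq
#> <gait_sequence> 26 frames, abnormal (tilt 5 deg, leg_asym 0)

feats <- extract_features(seq)        # reproject -> normals -> 2x2 regions
segment_index(feats, "transverse")
#> [1] 0.1784206
segment_index(feats, "sagittal")
#> [1] 0.02727654
segment_index(feats, "coronal")
#> [1] 0.2759419

# the same subject walking symmetrically scores an order of magnitude lower
normal <- extract_features(simulate_walk(walk_config(seed = 42)))
segment_index(normal, "transverse")
#> [1] 0.01153436
```

The indices are radians: the tilted walk's mean posture differs between
left and right by ~0.18 rad on the transverse plane and ~0.28 rad on the
coronal plane (the two planes a lateral tilt disturbs most), against
~0.01 rad for the symmetric walk. For a full study, score many sequences
and feed the indices to `roc_auc()` / `evaluate_all()`.

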