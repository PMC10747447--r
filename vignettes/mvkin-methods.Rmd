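---
title: "Validating markerless multi-view kinematics: models and methods"
author: "mvkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless multi-view kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvkin)
```

`mvkin` quantifies how well a markerless multi-camera motion-analysis
pipeline agrees with a reference motion-capture system on joint-angle
trajectories. This vignette documents the models, conventions and numerical
choices behind each stage, and what the synthetic test bed does and does
not establish about real recordings.

## The measurement model

A ring of `n` calibrated pinhole cameras observes a moving subject. Camera
`i` has focal lengths `(fx, fy)` and principal point `(cx, cy)` in pixels,
a world-to-camera rotation `R` and translation `t`; a world point `X`
projects to the dehomogenised `K [R | t] X`. Pixel origin is the top-left
corner, x right, y down. The world frame is right handed with Z up, the
floor is the plane `Z = 0`, and lengths are in metres. No lens distortion
is modelled — calibrated, undistorted pixel coordinates are the interface,
and `camera_model()` leaves a natural extension point if distortion
coefficients are ever needed.

### Triangulation

`triangulate_point()` uses the direct linear transform. Each view
contributes the two rows `x_n P3 − P1` and `y_n P3 − P2` of a homogeneous
system in the unknown point, where `(x_n, y_n)` are the pixel coordinates
shifted by the principal point and scaled by the focal length and `P` is
the normalised projection `[R | t]`. Working in these normalised
coordinates plays the role of Hartley's centring-and-scaling for the
single-point problem: all rows are of comparable magnitude regardless of
image resolution, which keeps the SVD well conditioned. The solution is
the right singular vector of the smallest singular value; the RMS
reprojection residual over the contributing views is attached to every
point. When the two smallest singular values are within 10% of each other
(ratio > 0.9) the solution direction is ambiguous — near-parallel rays —
and the point is flagged degenerate but still returned. Keypoints seen by
fewer than `min_views` (default 2) cameras are propagated as missing; no
temporal inpainting is performed at this stage.

The linear solution is not the maximum-likelihood one under pixel noise,
but at the noise levels of interest (≈1 px over a 3 m ring) its
reprojection RMS is verified in the test suite to sit within 5% of a
nonlinear least-squares minimiser of the summed squared reprojection error
on 100 random instances.

## Joint angles

All angles derive from seven tracked keypoints: neck, both shoulders, both
hips, right knee, right ankle. The torso frame anchors at the right hip
(the hip named in the keypoint set): `Z` is the unit vector from that hip
to the neck and `X` is the unit normal of the plane spanned by the two
shoulders and the hip, taken as `unit((shoulder_L − hip) × (shoulder_R −
hip))`; `Y = Z × X` completes a right-handed triad. The cross-product
order is a convention — it makes `X` point anteriorly for an upright
subject — and is pinned down by the mirror-antisymmetry property test. `X`
is re-orthogonalised against `Z` (one Gram–Schmidt step) so the triad is
orthonormal to 1e-9 even for noisy triangulated keypoints; for a
symmetric upright pose this step changes nothing.

- **Hip flexion/extension** is the angle between `−Z` and the femur axis
  (hip → knee): 0° in neutral stance, 180° fully raised, by construction
  insensitive to the plane the thigh moves in. The Y-balance reach is
  reported with this same unsigned formula; task metadata, not a sign,
  records that it is extension.
- **Knee flexion** is the angle between femur and tibia axes, 0° =
  extended.
- **Trunk side-bending** is the elevation of the shoulder line (right →
  left shoulder) over the floor plane, `atan2(−Δz, √(Δx² + Δy²))`,
  positive when the left shoulder is lower (left side bend). The floor,
  not a per-frame pelvis frame, is the horizontal reference.

Angles are computed per frame independently, with no temporal smoothing.
Numerically, angles between vectors are evaluated as
`atan2(|a × b|, a·b)` — identical in exact arithmetic to the arccos of the
clamped dot product, but retaining full precision near 0° and 180°, where
plain `acos` loses half the significant digits (enough to break a 1e-9°
round-trip contract). Dot products are still clamped to [−1, 1] so no
rounding can produce `NaN`.

## Temporal alignment

The two systems sample at different rates and are started by hand, so
trials are compared on a normalised time grid. For each trial the section
between the global maximum and global minimum of a representative
indicator is cut (ties broken toward the earliest frame, spanning the two
extremes in time order regardless of which comes first), and the section
is linearly resampled onto 100 evenly spaced points of normalised time.
Linear interpolation is used deliberately: it preserves monotone segments,
its error for the smooth profiles involved is quadratic in the source
step, and the downstream ICC is insensitive to the interpolant. The first
and last samples are preserved exactly, interior missing samples are
bridged linearly with a warning, and resampling is idempotent at the
target length.

By default the **test trace is the single representative indicator**: its
window, expressed as fractions of normalised time, is applied to both
recordings (`pair_traces(window_from = "test")`). This is valid whenever
the two systems record the same trial span, as simultaneously started and
stopped devices do. The alternative `window_from = "each"` cuts each
recording at its own extremes, for archives without a shared time base; in
that mode, when sensor noise relocates a global extremum between a trial's
flat start and end so that one window runs minimum→maximum and the other
maximum→minimum, the reference section is reversed in time so that like
extremes are paired. The shared-window default was chosen because with
per-trace windows the extremum *location* is ill-determined wherever the
trace is flat (the hold plateau, the near-zero tails): independent noise
then hands the two systems windows covering different phases of the
movement, and the agreement statistics measure the window lottery rather
than the instruments. With the shared window that failure mode is absent
by construction.

Sign conventions are harmonised before windowing: if the reference system
reports the mirrored sign convention (right-positive), its trace is
negated and retagged; unsigned traces pass through unchanged, and pairing
traces from different task families is an error.

## Agreement statistics

Each aligned pair yields a 100 × 2 ratings table: the *subjects* of the
ICC model are the 100 normalised frames and the *raters* are the two
systems. This is the only reading under which a per-trial ICC with a
tight CI is computable from a single repetition, and it matches the
shape of per-participant reporting in concurrent-validity studies. The
two-way, one-observation-per-cell decomposition (`two_way_mean_squares()`)
is computed exactly from row, column and grand means; the test suite
checks it against `stats::aov` and verifies SS conservation.

From mean squares MSR (rows), MSC (columns) and MSE:

- `ICC(2,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))` —
  two-way random effects, absolute agreement, single score; sensitive to a
  constant offset between systems. This is the default report form.
- `ICC(3,1) = (MSR − MSE) / (MSR + (k−1) MSE)` — consistency, single
  score.
- `ICC(3,k) = (MSR − MSE) / MSR` — consistency of the k-system average.

95% confidence intervals use the exact F-distribution bounds; the
ICC(2,1) interval uses the standard Satterthwaite-style approximate
denominator degrees of freedom. A table with no between-subject variance
raises an explicit undefined-ICC error rather than returning 0. Estimates
and intervals are verified to 1e-9 against an independently coded oracle
(and the estimates against `pingouin.intraclass_corr`) on 200 random
tables.

The absolute-error battery: the method-error CV relates the SD of the
paired differences to the grand mean; the default *Dahlberg* variant
divides the difference SD by √2 because each difference carries the error
of two measurements. `SEM = SD·√(1−ICC)` and `MDC95 = 1.96·√2·SEM` use
the standard rooted forms; *literal* unrooted variants of both (and of the
CV) are available behind flags for audits of legacy spreadsheets that
omitted the radicals, but are never the default. ICC bands default to the
reporting scheme `<0.4` poor, `0.4–0.6` normal, `0.6–0.75` good, `≥0.75`
very good (boundaries to the upper band); a conventional clinical scheme
(`<0.5 / 0.75 / 0.9`) is available as an option. Report rows pool the
2 × 100 values of both systems for M and SD (a per-system option exists).

## The synthetic test bed

`simulate_paired_session()` stands in for human sessions. Its defaults
*are* the package's study conditions: a raised-cosine rise–hold–return
profile (peak 40°, 5 s, hold fraction 0.2) sampled at 12 Hz, a
four-camera ring of radius 3 m at height 1.2 m with 900 px focal length
and 1920×1080 images, 1 px Gaussian keypoint noise, and a 100 Hz
reference equal to ground truth plus 1° Gaussian noise and an optional
constant offset, five repetitions. These magnitudes mirror a low-rate
RGB ring validated against a 100 Hz optical reference: sub-pixel to
1 px keypoint jitter is typical of pose estimators at 3 m, and 1° is a
realistic inter-system noise floor for trunk/hip angles. The skeleton is a
minimal 7-point model (torso 0.50 m, shoulder half-width 0.20 m, femur
0.45 m, tibia 0.43 m, hip half-width 0.10 m); the left hip completes the
seven tracked keypoints and the camera count is configurable (four by
default, five available). All randomness derives from one master seed
through a deterministic sub-seed scheme (per repetition, per camera), so
sessions are bit-reproducible and repetitions differ only in noise.

The generator is deliberately idealised. It emulates: perspective
projection, per-view observation noise, out-of-frame and behind-camera
missingness, rate mismatch, sign-convention mismatch, and a constant
inter-system offset. It does **not** emulate: 2D pose-estimator bias and
outliers (keypoints are unbiased Gaussian around the true projection),
soft-tissue artifact, occlusion correlated with pose, calibration error,
rolling shutter, or timing jitter between systems. Green tests on this
bed therefore certify the *pipeline mathematics* — triangulation, angle
conventions, alignment, statistics — not the behaviour of any particular
pose estimator on video.

Forward kinematics is constructed to be angle-consistent with the
extraction: the shoulder line tilts about the anterior axis by exactly the
side-bend angle, and the femur tilts in the torso sagittal plane by
exactly the hip angle, so the noiseless pipeline must return the
generating trace to numerical precision (the round-trip contract, enforced
at 1e-9°).

## Numerical and design notes

- Degenerate inputs fail loudly with specific messages: coincident
  neck/hip, collinear shoulder plane, vertical shoulder line, constant
  (no-motion) traces, single-view triangulation, flat ratings tables.
- The raised-cosine profile is exactly 0 at both endpoints and exactly
  `peak` on the hold, so window logic has well-defined extremes in the
  noiseless limit; `which.max`/`which.min` tie-breaking (earliest index)
  fixes the rest.
- Sub-seeds are generated by a small multiplicative-congruential step kept
  inside the 32-bit integer range.
- Problem sizes in the shipped tests were chosen to keep the whole suite
  around half a minute while still exercising every contract: 1000 random
  noiseless triangulations, 100 noisy oracle comparisons, 200 random ICC
  tables, 5-repetition sessions of 61 + 501 frames.

## Known limitations

- Only the three scalar angles above are implemented — no full ISB
  joint-coordinate-system Euler decomposition, and no ankle or shoulder
  angles.
- Camera calibration is an input, never estimated; there is no bundle
  adjustment.
- The alignment assumes a single dominant movement cycle per trial; it
  does not segment repeated cycles, and no cross-correlation or
  dynamic-time-warping registration is attempted.
- ICC confidence intervals assume the usual normal-theory two-way model;
  frames of a smooth movement are serially correlated, so per-trial CIs
  should be read as descriptive rather than strictly nominal — a caveat
  shared by any per-trial ICC on time-normalised traces.
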