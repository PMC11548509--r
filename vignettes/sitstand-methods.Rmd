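---
title: "Distance-based representation of sit-stand transitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based representation of sit-stand transitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitstand)
```

## The measurement model

A scanning proximity sensor is mounted at height `lse` (default 700 mm,
thigh height of a standing adult) and sweeps a fan of beams from −90°
(straight down) to +90° across the sagittal plane of a person facing it.
The world frame puts the origin on the ground below the sensor, `x`
horizontal toward the person, `y` up. Every sweep yields ranges `d_m` at
angles `alpha_m`, converted to points
`(d_m cos alpha_m, lse + d_m sin alpha_m)`.

The body is a three-bar linkage — shank, thigh, trunk — hinged at ankle,
knee and hip. Only sagittal motion is modelled: the feet do not translate
and there is no surging or swaying. Angle conventions:

* `theta_a`: signed shank deviation from vertical, positive when the knee is
  forward of the ankle (toward the sensor). Standing ≈ 0°.
* `theta_k`, `theta_h`: *bend* angles, 180° minus the interior angle at the
  joint. The raw between-line angle is ambiguous between two supplementary
  readings; storing the bend makes standing exactly 0° and ideal sitting
  exactly 90°, which is what the static phase tests need. Knee flexion
  rotates the thigh so the hip moves backward (away from the sensor); hip
  flexion brings the trunk back toward upright.

With these conventions forward kinematics is a plain rotation chain and its
inverse uses the inner-product (here `atan2`) formula; the round trip is
exact to well below 1e−6 degrees across the whole anatomical range (this is
a property test in the suite).

## The distance trajectory model

During a transition the thigh rotates about the knee; the tracked point on
the body surface at beam height moves horizontally by `Sx = Sy tan(theta)`
(`Sy` = vertical knee-to-beam distance), so the beam distance runs from the
standing value `lsa` to the sitting value `lsi`. Because people accelerate
gently at the start of a transition and decelerate at the end, the fan angle
is modelled on an exponential clock, which gives the Gudermannian-type
sigmoid

$$l_{ts}(t) = \tfrac{2}{\pi}(l_{si}-l_{sa})\,\arctan(e^{-k_i t + b_i}) + l_{sa}$$

for standing up, and the mirrored exponent for sitting down. `ki` (1/s) is
the motion speed, `bi/ki` the midpoint time. The two branches satisfy
`standing(t) + sitting(t) = lsa + lsi` pointwise (an `arctan` reflection
identity), which the tests verify numerically.

`fit_lts()` estimates `(ki, bi)` by Levenberg–Marquardt least squares
(`minpack.lm`). The observed extremes only *initialise* `lsa`/`lsi`: a
finite series never attains the asymptotes, so fixing them at the extremes
biases `ki` by far more than the sub-1e−4 self-consistency the package
guarantees on noiseless data. Unless the caller fixes them, the asymptotes
are therefore refined as free parameters. A series must span at least half
of the standing–sitting range to be fittable; constant series are rejected.

## Surface extraction

Per frame, missed beams are dropped, the first sustained rise (two
consecutive points more than 30 mm above the first, downward-most return)
marks the toe front, and the surface is clipped at the first inter-point gap
larger than `lsout` = 150 mm (Euclidean; the choice between Euclidean and
along-ray distance is immaterial at these geometries). The ankle is placed
`lax` = 120 mm behind the toe front at ground height; the last retained
point is taken as the shoulder. `lax` and `lsout` are empirical: 120 mm is
a typical adult toe-to-ankle offset, 150 mm comfortably exceeds the beam
spacing on grazing surfaces (~90 mm worst case at 1° resolution) while
rejecting the body-to-background jump. Requiring *two* consecutive rising
points rejects single noisy floor returns (a 3-sigma spike at the default
10 mm noise is ~30 mm).

## Joint identification

Joints are curvature maxima of the surface. The bend angle at a point is
the turning angle between the chords reaching `span` = 8 samples backward
and forward, on a polyline pre-smoothed with a 5-sample rolling mean. The
long chord is essential: with adjacent-sample chords (~12 mm), 10 mm range
noise produces turning angles of tens of degrees on a perfectly straight
shin, swamping any threshold. With ~100 mm chords the noise floor drops to
a few degrees while true corners keep their full magnitude.

Candidates below 300 mm height are excluded — the instep corner of the foot
is a genuine curvature maximum but never a knee (the knee sits at
ankle height + shank length ≈ 535 mm for the default body), and long chords
near the foot would otherwise pick up its bend.

The knee/hip pair is chosen among the top 15 candidates by bend angle,
knee before hip in scan order, first pair whose implied segment lengths all
fall within ±20% of the anthropometric targets. Two details matter:

* the ankle estimate sits at *ground* height, so the shank target is
  `lak + ankle_height`;
* estimated joints lie on the *front* surface, biased toward the sensor by
  the flesh thickness; each accepted joint is retracted 50 mm along the
  local inward normal. The residual mitre error at a 90° corner (~20 mm)
  is the main contributor to the few-degree bias of the recovered sitting
  hip angle.

When the surface is straight the maxima are meaningless. Two triggers hand
over to the ratio fallback, which places the knee and hip at the 0.35 and
0.70 cumulative fractions of the ankle–shoulder axis (Japanese
body-proportion reference ratios 0.35/0.35/0.30): either every candidate
bend angle is below 10°, or the candidate region deviates less than 30 mm
from its end-to-end chord. The second, geometric test is the noise-robust
one — on a straight noisy surface individual bend angles can reach 40°
while the chord deviation stays at the smoothed noise level (~15 mm). The
price is that very shallow knee bends (below ~10°) are reported as 0°,
which is within the static-pose tolerance anyway.

## Phase determination

Per frame the cascade sees the angle changes `(dtheta_a, dtheta_k,
dtheta_h)` since the previous frame, the current bend angles and `lts`.
Rules, first match wins: all-static (with `lts` disambiguating standing,
sitting, or a mid-transition `HOLD`); knee fixed + hip flexing → `Sa_I`;
shank moving + knee extending + hip moving → `Sa_II`; shank moving + knee
flexing → `Si_I`; knee fixed + hip extending → `Si_II`; otherwise `FALL`.
The four dynamic rules are pairwise disjoint by construction (they differ
in the sign of the knee or hip change), which the tests verify by
enumerating sign patterns.

Zero-band semantics required a design decision. The `= 0` / `> 0` / `< 0`
tests use a band of `eps_delta` = 0.5°/frame (at 10 Hz): below typical
dynamic knee/hip changes (2–7°/frame), above residual static jitter of
smoothed estimates. The `!= 0` tests on the shank and hip are *literal*
(anything beyond numerical zero): the shank sweep spans only ~±7° against
the knee's 90°, so its per-frame change sits below any band that also
suppresses jitter, and a banded "nonzero" test would starve the `Sa_II`
rule for whole stretches of a normal rise, emitting `FALL`. Literal
inequality matches the rule's wording and, on real (noisy) streams, is
almost always satisfied during motion and exactly unsatisfied on frozen
poses.

Static tolerances: the distance tolerance is `tol_d` = 20 mm; the standing
angle tolerance is derived from it as `asin(tol_d / lkh)` ≈ 2.5°, so the
angle and distance criteria become true together as the pose settles —
otherwise a `HOLD` gap appears between `Sa_II` and `Sa_III`. The sitting
angle tolerance is looser (10°) because the front-surface hip bias is
several degrees while `lts` is insensitive to it near sitting (the thigh is
rotated fully toward the beam).

`run_spd()` optionally smooths the input streams (5 frames) and debounces
the label stream with a centred rolling mode over 5 frames, ties keeping
the previous output. Five frames, not three: where one angle's change
crosses the band a frame before the others (e.g. the hip decelerating into
standing while the knee still moves), up to two consecutive frames can
mislabel, and a 3-frame mode cannot outvote them. `HOLD` is reported as its
own label carrying the phase it interrupts (`carried`); collapsing it onto
that phase reproduces the behaviour of systems that log a pause as a
prolonged dynamic phase, but keeping it explicit is strictly more
informative. The first frame has no predecessor and is classified by the
static test alone.

## The simulator

`motion_script()` drives overall progress with the same Gudermannian
sigmoid as the distance model (`k_speed` maps to `ki`), so scripted motions
accelerate and decelerate realistically and the measured `lts` follows the
model family. Within that progress the angles are piecewise linear:
standing up spends the first quarter of progress on torso flexion
(`theta_h` 90° → 115°, knee fixed), then extends everything to zero;
sitting down folds for three quarters, then straightens the torso
(115° → 90°). The shank sweeps 0 → +7° → 0 during the extension/folding
phase. Pauses freeze the pose by stopping the progress clock.

Defaults are the package's study conditions, chosen once: 10 Hz frames and
181 beams (1° steps — the sensor class leaves resolution open), 10 mm range
noise (consistent with bench accuracy of this sensor class at these
distances), 8 s duration, `k_speed` = 2.5/s, torso lean 25°, shank sweep 7°
(reported joint-excursion ranges for adult sit–stand motions). `k_speed`
matters for label cleanliness: per frame the sigmoid decays the remaining
excursion by `1 − exp(−k/rate)`; with `k` = 2.5 at 10 Hz that fraction
(0.22) exceeds `eps_delta / tol_theta`, so by the time the angle deltas
drop inside the zero-band the pose is already inside the static tolerance
and no spurious `HOLD` separates the last dynamic phase from the static
one.

Ground-truth labels are derived from the script's own per-frame angle
changes (pause frames are `HOLD`; all-static frames take the adjacent
static label; otherwise the progress segment decides), so simulator truth
and rule semantics agree by construction.

What the simulator does **not** emulate: clothing drape and hem movement,
arms (assumed crossed or at the sides), back-surface returns, occluding
obstacles, multi-person scenes, out-of-sagittal motion, and foot
translation. Passing tests therefore demonstrate correctness of the
geometry, the estimators and the rule logic under the stated noise model —
not robustness to garments or scene clutter, which real deployments must
add on top.

## Numerical choices and degenerate inputs

* Degrees at every interface; radians only inside trigonometric kernels.
* Interior angles via `atan2(|cross|, dot)`, which keeps precision near 0°
  and 180° where `acos` loses it.
* Ties in bend angle break toward the lower scan index (closer to the
  feet), making estimation deterministic; identical frames give identical
  poses.
* Coincident joint points, empty frames, all-floor scans, sub-4-point
  surfaces and non-converging fits raise classed conditions
  (`sitstand_*`); the per-frame pipeline converts them to a `status` column
  and skips the frame rather than aborting a session.
* Estimation failures in a stream are bridged by linear interpolation
  before phase determination.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale: single frames of 181 beams, sessions of 81–100 frames
(8–10 s at 10 Hz), a 625-pose kinematic grid and a 125-pattern rule
enumeration. The full suite completes in well under a minute on one CPU.

## Known limitations

* The hip angle is the least accurate output (median error ~4° at 10 mm
  noise, worst frames ~13°): the hip corner is the farthest from the
  sensor, seen at grazing incidence, and carries the largest retraction
  error. This mirrors the accuracy ordering reported for comparable
  range-scan systems.
* Shallow knee bends (< ~10°) are flattened to 0° by the straightness
  fallback.
* `theta_h` is unsigned; torso flexion beyond vertical in standing is not
  distinguished.
* The phase cascade assumes one person, time-ordered frames and a single
  transition per session; it is not an activity recogniser.
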