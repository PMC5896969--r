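---
title: "Estimating and validating hip joint contact forces with hipload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and validating hip joint contact forces with hipload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipload)
```

## The problem

Preoperative planning of total hip arthroplasty benefits from knowing the
magnitude and orientation of the hip joint contact force (HJF) for the
activities that load the implant most: one-leg stance and level walking.
Musculoskeletal models estimate the HJF from motion-capture markers and
force-plate recordings, but their output depends on modeling choices that are
rarely validated against in vivo measurements. `hipload` implements a
desk-scale version of that whole workflow — a simplified patient-specific
lower-limb model, the two-step simulation (kinematic parameter optimization,
then inverse dynamics with muscle recruitment), and the complete validation
metric suite against instrumented-prosthesis style recordings — together with
a synthetic trial generator that provides ground truth, so every stage is
testable without any proprietary data.

Four modeling parameters are treated as the experimental factors:

* **Hip joint width (HJW)** — the distance between the hip centers — either
  estimated from the skin markers during the kinematic optimization
  (`C3D` mode) or frozen to a CT-measured value (`CT` mode);
* **muscle strength** σ in N/cm², with 40 and 90 as the factorial levels;
* **recruitment criterion** — third-power polynomial (`PN`) versus strict
  min/max (`MM`);
* **muscle model** — constant-strength (`simple`) versus Hill-type (`hill`).

## The model

The skeleton is a pelvis with a rigid head-arms-trunk lump and two
five-segment chains (spherical hips; revolute knees and ankles). Segment
masses are fixed anthropometric fractions of body mass (HAT lump 0.678,
thigh 0.100, shank 0.0465, foot 0.0145 per side, summing to exactly 1), and
segment lengths are proportions of body height (thigh 0.245 H, shank
0.246 H). Six hip-spanning muscle groups per leg (gluteus medius anterior
and posterior, gluteus maximus, iliopsoas, an adductor equivalent, and a
rectus-femoris group that includes a tensor-fasciae-latae-like lateral
portion) stand in for the dozens of fascicles of a full cadaver-based model.

Each group is built as a *fiber fan* of three sub-fascicles: a superficial
fiber with the nominal attachments, an intermediate and a deep fiber whose
attachments are contracted toward the hip center (moment arms about 0.62 and
0.35 of the superficial ones). The deep fibers carry PCSA that the
six-group reduction would otherwise discard with the small deep muscles
(gluteus minimus, pectineus, the short rotators), and they matter for one
specific phenomenon: when muscle strength is reduced, recruitment saturates
*gradually*, shifting load onto shorter-arm fibers at a force penalty,
instead of jumping from "feasible" to "infeasible" within a hair of strength.

**Scaling.** The kinematic optimizer scales thigh and shank lengths (and the
HJW in `C3D` mode) per subject. Perpendicular dimensions follow a
mass-and-height law: the cross-section scale `k = sqrt((m/75 kg)/(h/1.75 m))`
multiplies every PCSA, and perpendicular attachment coordinates scale with
`sqrt(k)`. Any monotone law would serve; this one is dimensionally sensible
(strength grows with body mass at fixed stature) and is exercised by the
tests.

**Hill model.** The Hill-type option modulates each fascicle's instantaneous
strength by a Gaussian force-length curve (width 0.45 of optimal length), a
hyperbolic force-velocity curve (zero at 8 optimal lengths/s shortening,
saturating at 1.5 eccentric), and adds a quadratic passive force above
optimal length. The optimal length is the attachment distance in the neutral
pose, the tendon is rigid, and there are no activation dynamics — the curves
are simply evaluated at the kinematics-derived length and velocity, which is
all the downstream comparison needs.

## Step 1 — kinematics

Twenty-five markers (four pelvis, three trunk, nine per leg) drive the pose
reconstruction. Each frame is solved hierarchically in closed form: a
weighted Kabsch fit of the pelvis+trunk body, a rotation-only Kabsch fit of
each thigh about its hip center, and closed-form revolute angles at knee and
ankle, followed by two block-coordinate sweeps that re-fit the hip rotation
against *all* leg markers with the distal angles held. The sweeps matter:
they let the thigh tilt absorb hip-center placement errors the way a joint
least-squares fit would, which is what allows pelvic soft-tissue artifacts to
inflate the marker-estimated HJW (the phenomenon the `C3D`/`CT` comparison is
about) instead of being fought by the shank markers.

The outer parameter optimization minimizes the summed weighted squared
marker residual over the segment scales (bounded L-BFGS, scale bounds
0.7–1.3, on an evenly strided subset of frames — 15 by default). Marker
weighting follows `w = 1/(1 + (r/r0)^2)` with `r0 = 20` mm, recomputed once
after an unweighted first pass; invalid markers get weight zero, and the
soft-tissue-prone proximal thigh markers (greater trochanter and thigh
cluster) carry a structural prior weight of 0.2 so the bony pelvis and knee
landmarks dominate the scale estimate. Velocities and accelerations come
from central differences after a zero-phase 2nd-order low-pass at 6 Hz —
standard gait practice.

In `CT` mode the HJW is frozen: the optimizer simply has one parameter
fewer, and the model width equals the CT value exactly, whatever the markers
say.

## Step 2 — dynamics

Net hip loads follow from bottom-up Newton–Euler over the instrumented leg
(foot, shank, thigh): gravitational and ground-reaction terms are exact,
inertial terms use the filtered accelerations and finite-rotation angular
velocities. The muscles must reproduce the net hip moment about the two
axes orthogonal to the femur long axis (flexion-extension and
ab/adduction). The small axial-rotation component is carried by an ideal
torque provider: the reduced fascicle set has no hamstrings or deep rotator
group, and forcing exact 3-axis equilibrium through it produces
co-contraction cascades (activations beyond 1 at 90 N/cm² in swing) that the
omitted muscles would trivially absorb in reality. The residual axial
torque is reported per frame so its size can always be inspected.

**Recruitment.** With more fascicles than equations, a criterion picks the
distribution. The polynomial criterion minimizes `sum((f_i/N_i)^3)` subject
to `C f = d, f >= 0`; it is solved exactly through its smooth dual (the
activations are an explicit function of the 2-vector of moment multipliers),
by BFGS warm start plus damped Newton, to an equilibrium residual below
`1e-9 |d|`. By default no hard caps are applied: overload shows up as
activations above 1, and the solution is invariant under a uniform rescaling
of all strengths — which is exactly why the 40 versus 90 N/cm² factor
barely matters in the factorial. The strict min/max criterion minimizes the
largest activation, lexicographically: a linear program finds the minimax
ceiling, the fascicles that cannot be below it are fixed there, and the
procedure recurses — producing the broad co-activation characteristic of
min/max recruitment. For min/max, strength is a hard ceiling (activation 1),
so a demand beyond capacity makes the program infeasible: that is the
package's one failure mode, a failed frame fails the trial, and failed
trials are excluded from aggregation. The linear programs are solved by a
small two-phase dense simplex with Bland's anti-cycling rule written for
this package; the tests check both solvers against dense grid-search oracles.

In the strength sweep the polynomial criterion runs *with* the caps enforced
— the saturation behavior is the quantity under study there.

The hip reaction is the intersegmental force minus the vector sum of the
fascicle pulls, expressed in a femur-fixed frame (ML axis pointing right for
both sides, PA anterior, IS proximal), then rotated into the OrthoLoad-style
reporting frame, mirrored for left-side trials so that positive ML is medial
for everyone, and normalized to percent body weight (`100 F / (m g)`,
g = 9.81 m/s²) on a 101-point cycle grid.

## The synthetic cohort

The generator emulates the study's recordings for the ten-subject reference
cohort (masses 77.5–122 kg, heights 1.62–1.81 m, CT hip widths 157–186 mm).
For each subject it builds the true model (CT width, per-subject true thigh
and shank scales drawn within ±5%), prescribes smooth pose paths, and
derives everything else:

* **One-leg stance** (2.5 s at 24 Hz): weight transfer onto the stance leg
  (support ramps from half to full body weight), a single-support plateau
  over 30–70% of the cycle, and release. The center of pressure migrates
  medially with the trunk shift; its offset is calibrated by a secant
  iteration so the ground-truth resultant plateau equals the requested
  259 %BW.
* **Level walking** (one cycle, 1.25 s at 48 Hz): a double-hump vertical
  ground reaction over the stance phase (taper 0–12% and 50–60%) whose hump
  gains are secant-calibrated so the ground-truth resultant peaks at the
  requested 255 and 230 %BW near 15% and 45% of the cycle; the contralateral
  toe-off event sits at the first peak phase. The force vector points from
  the center of pressure toward the body mass center (inverted-pendulum
  direction), which keeps the joint moments physiological; the plate is
  silent during swing.

The ground-truth force is produced *by the package's own dynamics* under the
designated true combination (CT, 90 N/cm², polynomial, simple) on the true
poses — not by curve templates — so the validation metrics have a known-zero
reference: a zero-noise trial pushed through the full pipeline reproduces
its own truth almost exactly. Simple parametric curve templates are exposed
separately (`template_curve()`) for metric unit tests.

Measurement imperfections are explicit and seeded: isotropic marker noise
(2 mm default), a pelvic soft-tissue artifact that displaces the four pelvis
markers laterally by `scale * max(0, BMI - 25)` mm plus a slow drift (the
mechanism by which marker-based HJW overestimates CT), and pseudo in vivo
series built as truth plus smooth correlated noise (3 %BW per component, the
accuracy scale of instrumented-implant telemetry) plus a small fixed frame
misalignment (2°, at most 5°). All generators are pure functions of their
seed.

What the generator does *not* emulate: real soft-tissue motion over the
thigh, trial-to-trial variability of the same subject, telemetry dropouts,
arm swing, and — most importantly — any discrepancy between the model family
and reality: the synthetic "in vivo" data are produced by the same model
class that analyzes them. Passing the end-to-end tests therefore
demonstrates internal consistency and correct implementation of every stage,
not clinical accuracy on real patients.

## Validation metrics

All comparisons run in the OrthoLoad-style frame on the common cycle grid:

* **Peak force phase (PFP)**: for stance, the cycle is restricted to its
  central 25–75% (omitting lifting and lowering of the leg) and the window is
  the longest run with resultant at or above 75% of the central maximum; for
  walking, the local resultant maximum nearest the contralateral toe-off
  event ±2.5% of the cycle. The window is detected on the in vivo series.
* **PD/MAPE**: the percentage deviation of window-averaged resultants, one
  value per subject, and the cohort mean of absolute deviations.
* **MAD**: angles between the window-mean force vectors, in 3D and projected
  into the sagittal (FE), frontal (AA) and transverse (IE) planes. Window
  means, not means of per-sample angles — the window has one direction.
* **RMSE** per component and resultant over the full cycle; **r²** with the
  two-sided test of zero correlation and the regression of simulated on
  in vivo; **Bland–Altman** with nonparametric limits of agreement
  `median ± 1.45 IQR` (quartiles by linear interpolation of order statistics,
  the default convention — checked against the worked example d = 1…5 →
  LOA (0.1, 5.9)); Kolmogorov–Smirnov against the fitted normal and the
  two-sided Mann–Whitney U test at α = 0.05.
* Cohort RMSE/r²/Bland–Altman pool all subjects' 101-point cycles;
  MAPE and MAD aggregate per-subject values (mean ± SD). Both conventions
  appear in the sweep tables.

## The factorial study and the strength sweep

`factorial_sweep()` runs all 16 parameter combinations for every subject and
both activities — 320 runs for the default design — reusing the kinematic
solution per (subject, activity, HJW mode), and aggregates per combination
over the successful runs only. On the default synthetic cohort the
qualitative structure of the real study emerges without any tuning knob
pointed at it: polynomial + simple recruitment tracks the (polynomial-
generated) truth closely; min/max overestimates the force through its broad
co-activation; CT mode beats C3D mode slightly (the soft-tissue artifact
inflates the marker-based width); the strength factor is nearly inert; and
the only runs that can fail are min/max runs, because min/max is the only
bounded criterion.

`strength_sweep()` reduces σ gradually for CT + polynomial + simple with the
caps enforced (grid 20, 25, 30, 45, 60, 90 N/cm², bracketing the model's
saturation region). Above the saturation level — the largest σ at which any
fascicle reaches its cap — the solution is σ-invariant and the resultant
error is exactly flat; below it, recruitment shifts to short-arm fibers, the
force inflates, the error over the surviving runs rises, and eventually the
demand exceeds capacity entirely.

## Numerical choices and problem sizes

Tolerances: recruitment equilibrium `1e-9 |d|` (asserted at `1e-6` in the
contracts), LP pivot tolerance `1e-9`, kinematic scale optimization L-BFGS
with `factr = 1e6` and 15 frames (scale parameters are recovered to about
`1e-3` relative on noise-free data, far below the anthropometric signal),
ties in the simplex broken by Bland's rule, degenerate residual demands
(below `1e-9 |d|`) short-circuited to zero force. Trials are 61 frames
(2.5 s stance at 24 Hz, 1.25 s gait at 48 Hz); cycles are resampled to 101
points. The default cohort study — 40 kinematic solves and a few hundred
dynamics runs — completes in minutes on one core; these sizes are the
package's chosen study conditions, stated here so the reported numbers are
reproducible.

## Known limitations

* The axial-rotation moment is not muscle-borne (see above); MAD_IE is still
  reported from the force directions, but axial co-contraction effects on
  the contact force are absent.
* The fiber-fan reduction reproduces the *mechanisms* of redundancy
  (co-activation, gradual saturation, min/max infeasibility), not the
  quantitative margins of a 159-fascicle cadaver-based model; absolute
  failure thresholds and error magnitudes are model-specific.
* The hierarchical pose solver is a block-coordinate approximation of the
  joint least-squares fit; with heavy dropout it interpolates flagged frames
  linearly.
* Ground-truth and analysis share the model family, so validation against
  the synthetic cohort bounds implementation error, not model error; the
  headline in vivo deviations of the real study are not reproducible here
  and are not claimed.
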