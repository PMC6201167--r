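---
title: "Removing periodic soft tissue artifact from planar multi-link marker data"
author: "stafree"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stafree)
```

## The problem

Optical motion capture records skin-mounted markers, not bones. During
movement the skin, muscle and other soft tissue shift over the skeleton, so
each marker wanders around the anatomical landmark it is supposed to
represent. This soft tissue artifact (STA) is the dominant error source when
marker data are assimilated into a rigid-multi-link model: link lengths
appear to change over the cycle, joint centres disagree between adjacent
segments, and joint angles and inverse-dynamics torques inherit the error.

`stafree` implements an assimilation method for *periodic* movements (gait
being the canonical case) built on one empirical premise: during a periodic
movement the STA profile of each marker is itself periodic with the movement
period. Under that premise the STA can be identified from a single cycle of
marker data and removed exactly, using nothing beyond the rigid-link model's
own pin-joint constraints — no calibration trials, no artifact database, no
task-specific tuning.

## Model and frames

The model is planar: rigid links connected by ideal pin joints, two markers
per link (the minimum that fixes a planar pose). Everything is expressed
through three families of frames, all built by the same rule — origin at the
midpoint of two points, x-axis along the vector from the first to the
second:

* the **marker frame** of a link, built from the two captured markers; it is
  observable but, because of STA, *not* rigidly fixed to the bone;
* the **landmark frame**, built from the (unobservable) artifact-free
  landmark markers; it is rigidly link-fixed;
* the **link frame**, the conventional CoM-anchored reporting frame, a fixed
  rigid transform away from the landmark frame.

For the pin joint between links $a$ and $b$, the joint's local coordinates
in each landmark frame are constants, and the joint constraint requires both
links to predict the same global joint point at every sample. On clean data
two samples with different relative rotation suffice to solve those locals
exactly (`solve_joint_two_instants()`); an all-sample least-squares
generalisation (`solve_joint_lsq()`) is used everywhere in practice.

### The uncorrected baseline

`sta_assimilate(..., method = "naive")` treats the marker frames as if they
were link-fixed and fits, per joint, the constant pair of locals minimising
the summed squared joint gap. With STA present no constant pair closes the
gap; the residual gap is the baseline's irreducible inconsistency, and the
reported joint trajectory is the midpoint of the two links' predictions.
The baseline removes nothing — it is both the comparison standard and the
initialisation of the periodic method. Its cost is written in the
literature as a sum of unsquared gap norms; it is minimised here as a sum of
squares so the problem is exactly linear least squares, and both cost
readings are reported in the fit's solver block.

## The periodic method

Each marker's STA is expanded in its link's landmark frame as a truncated
Fourier series of order $K$ (default 4) with *no* constant term: a constant
offset is indistinguishable from a shifted landmark, so it is absorbed into
the landmark definition. The identification proceeds in two stages.

**Stage 1 — shape from the distance.** The squared distance between a
link's two markers is frame-independent and observable. Writing $\xi_x,
\xi_y$ for the difference between the two markers' coefficient vectors and
$C$ for the inter-landmark distance, the model predicts

$$ d^2[n] \;=\; \big(C + P[n]\,\xi_x\big)^2 + \big(P[n]\,\xi_y\big)^2 $$

where $P[n]$ is the Fourier basis row. Squaring doubles the bandwidth, so
$d^2$ is band-limited to order $2K$; equating its Fourier coefficients with
those of the observed squared distance gives $4K+1$ polynomial equations in
the $4K+1$ unknowns $(C, \xi_x, \xi_y)$ (`shape_residual()`). The equations
are solved by Levenberg–Marquardt (`solve_shape()`), initialised from the
baseline: the mean inter-marker distance seeds $C$, a Fourier fit of the
distance variation seeds $\xi_x$. The tilt of the marker frame relative to
the landmark frame then follows in closed form,
$\theta[n] = \operatorname{atan2}(P\xi_y,\; C + P\xi_x)$, the two-argument
arctangent keeping the branch safe.

**Stage 2 — everything else is linear.** With the per-link tilts known, the
joint-constraint cost becomes *linear* in the remaining unknowns — each
link's first-marker coefficients ($4K$ per link) and the constant joint
locals (2 per link–joint incidence). One global least-squares system over
all joints and samples (`assemble_solve()`; for the seven-link gait model,
$7\times16 + 12\times2 = 136$ unknowns against $12N$ equations) is solved
by singular-value decomposition with a minimum-norm solution, a rank and
condition report, and a per-joint RMS gap. Reconstruction then yields the
landmark frames, the artifact-free landmark markers, joint trajectories
(averaged across the two adjacent links), joint angles and link lengths.

## Identifiability, and what the joint constraint must decide

The distance identity is deliberately blind to several transformations, and
the implementation treats each explicitly:

* **Gauge copies.** $(-C, -\xi_x)$ gives the same distance; it is removed
  by convention ($C > 0$). $\xi_y \to -\xi_y$ also gives the same distance:
  this *sign branch* reflects the marker-frame tilt and must be resolved
  per link.
* **Spurious roots.** Writing $z = (C + P\xi_x) + i\,(P\xi_y)$, the data
  constrain only $|z|^2$. A band-limited $|z|^2$ factors through the zeros
  of an associated degree-$4K$ polynomial, whose $2K$ conjugate-reciprocal
  zero pairs can each be flipped: up to $2^{2K}$ *exact* roots of the
  $4K+1$-equation system exist per link (256 for $K=4$), all satisfying the
  distance data perfectly. `enumerate_shape_roots()` constructs all of them
  by polynomial rooting. No per-link quantity can tell them apart — only
  the joint constraint, which couples links, identifies the physical root.

The pipeline therefore validates every shape solution against the joint
constraint. Sign branches are resolved joint-wise: for each pin, all four
sign combinations of the two flanking links are scored on the joint's own
sub-system, and only the physical pair closes it exactly (the jointly
mirrored pair is close, but measurably inconsistent — the margin is what
makes the decision reliable). If, after assembly, any joint's RMS gap
exceeds `gap_tol` (default $10^{-8}$ m, far above round-off and far below
any genuine inconsistency), a repair pass replaces suspect links' roots by
enumerated alternatives. Replacements are accepted only when the *full*
system cost decreases, best candidate first: a swap onto the physical root
collapses the cost by many orders of magnitude, while a swap that corrupts
a sound link barely moves it, so the search cannot trade a correct link
away. When the two links flanking a bad joint are both on spurious roots,
candidate *pairs* for that joint are ranked by the joint sub-system cost
(the physical pair closes it exactly) and the leaders are verified the same
way. The accepted configuration, the per-joint gaps, the rank of the linear
stage and the identity of any repaired link are all reported in the fit.

Two further numerical decisions matter in the small-artifact limit.
Because $\xi_y$ enters the distance only through its square, (i) the
baseline initialisation necessarily starts it at zero — a singular point of
the equations — so the solver uses a deterministic warm start whose norm is
estimated from the unexplained constant power of the distance spectrum; and
(ii) floor-level noise $\varepsilon$ in the spectrum would be amplified to
$\sqrt{\varepsilon}$-scale coefficients by the root solve, so when the
identity already holds with $\xi_y = 0$ within tolerance the parsimonious
root is kept. The latter is what makes the artifact-free case return the
input kinematics to machine precision rather than to $10^{-7}$.

## The synthetic gait fixture

The evaluation surface is a sagittal-plane seven-link walking model (HAT,
thighs, shanks, feet) with a standard anthropometric parameter set
(`gait_params()`: masses 40.5/6.9/3.2/0.7 kg, lengths 0.536/0.420/0.379/
0.122 m, CoM–joint offsets and segment inertias to match). Rather than
simulating walking dynamics, the fixture *prescribes* smooth band-limited
periodic joint-angle trajectories with gait-like ranges (hip ±0.35 rad,
knee 0–1.1 rad, ankle ±0.3 rad, HAT tilt ±0.05 rad, legs half a cycle out
of phase) and a purely periodic HAT translation — a treadmill-style frame,
so the cycle closes exactly and spectral differentiation is exact. The
assimilation algorithm consumes only kinematics, so nothing in the
evaluation depends on the motion being dynamically consistent; the same
synthetic ground reaction force is supplied to both sides of every torque
comparison, which removes it from the differences whenever the compared
kinematics agree.

Landmark placements are declared, not anatomically derived: thigh and shank
landmark pairs sit at the joint centres (so the recovered inter-landmark
distances equal the segment lengths, which is what the link-length
evaluation checks), HAT and foot landmarks at fixed offsets along each
link. Artifact profiles are seeded draws: per marker and axis, order-4
coefficients uniform in ±10 mm with a $1/k$ harmonic decay — the
centimeter scale and red-shifted spectrum reported for skin markers in
gait. Seven seed presets stand in for a seven-subject panel. At these
settings (N = 200 samples, K = 4) the periodic method recovers the true
joint angles, joint torques, and segment lengths to better than $10^{-9}$
of their units on every seed, while the baseline errs by $10^{-1}$ rad at
the ankle — the short foot marker base amplifies a given artifact amplitude
into the largest frame-tilt error, and the error propagates up the leg's
torque recursion.

## Inverse dynamics

Torques come from standard planar recursive Newton–Euler per leg, foot →
shank → thigh, with per-foot force and centre of pressure as the external
load, gravity 9.81 m s⁻² in $-y$, and accelerations by spectral
differentiation (Fourier-fit, differentiate analytically, re-evaluate —
exact for the band-limited fixture, and the reason the fixture avoids net
progression). Torques are reported clockwise-positive to match the joint
angle convention, and the two legs' recursions are kept independent (left
and right hip torques are reported separately; no residual redistribution
into the HAT). For assimilated motions the link CoM positions are rebuilt
from the estimated frames and the model's CoM-in-landmark-frame geometry —
CoM location relative to landmarks is treated as model knowledge, as it
would come from anthropometric tables in practice.

## What the tests do and do not show

The fixture's artifact is *exactly* periodic and *exactly* band-limited to
the expansion order — the regime in which the method's recovery is exact,
and the suite verifies that exactness at machine precision. Real data break
the premise in graded ways the fixture deliberately does not emulate:
cycle-to-cycle STA variability, harmonic content above $K$, measurement
noise, marker occlusion, and non-pin joints. Against those, the method
degrades with the size of the premise violation rather than failing
abruptly (the cost and gap diagnostics expose the misfit), but nothing in
this package's tests quantifies that degradation. Out of scope entirely:
3-D motion (three markers per link and a richer distance system), soft
constraints, and fusion with Kalman-type estimators.

## Default settings

| quantity | default | note |
|---|---|---|
| expansion order $K$ | 4 | artifact bandwidth; $N \ge 8K+2$ required |
| samples per cycle $N$ | 200 | fixture default; one full cycle, endpoint not duplicated |
| artifact amplitude | 0.01 m | fixture draw scale, $1/k$ decay |
| shape residual tolerance | $10^{-9}\,\gamma$ | relative to the spectrum's constant term |
| joint-gap repair threshold | $10^{-8}$ m RMS | separates round-off from inconsistency by ~5 orders |
| rank tolerance | $10^{-10}\,\sigma_{\max}$ | null space beyond it is warned about, never hidden |
| pin-solve condition bound | $10^{8}$ | two-instant solve degeneracy guard |

All randomness flows through explicit integer seeds; identical seeds give
bit-identical fixtures and fits.
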