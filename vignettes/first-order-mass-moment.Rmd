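---
title: "Measuring first-order body segment mass moments by rotation on a reaction board"
author: "segmoment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring first-order body segment mass moments by rotation on a reaction board}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmoment)
```

## The measurement problem

Body segment inertial parameters — the mass, centre-of-mass location and
moments of inertia of limbs — underpin every inverse-dynamics calculation in
biomechanics, yet they are hard to measure on living subjects. Most values
in use come from regression models or imaging-based estimates. The method
implemented here measures one of these parameters *directly*: the
first-order mass moment

$$ M^{(1)} = M_1 L, $$

the product of a segment's mass $M_1$ and the distance $L$ from its axis of
rotation to its centre of mass, in kg·cm. This single number is exactly the
quantity that enters static torque balances (and posture-error corrections
for in-orbit body-mass measurement), and it can be checked against any
indirect estimate of $M_1$ and $L$.

## The estimator

The subject (or a rigid dummy) lies on a horizontal board resting on three
non-collinear support points. Weighing each support gives the whole-system
centre of mass by the reaction-board identity

$$ \mathrm{CoM} \;=\; \frac{P_1 M_{P1} + P_2 M_{P2} + P_3 M_{P3}}
        {M_{P1} + M_{P2} + M_{P3}}, $$

where $P_i$ are the support positions and $M_{Pi}$ the scale readings
(`compute_com()`). The segment under test is then rotated in the horizontal
plane by a known angle $\theta$ about a fixed centre of rotation (taken as
the coordinate origin), and the whole-system CoM is measured again. Writing
$\alpha$ and $\beta$ for the two postures, the decomposition
$\mathrm{CoM}\,M = \mathrm{CoM}_1 M_1 + \mathrm{CoM}_2 M_2$ of the system
into the rotated segment ($S_1$) and everything static ($S_2$, including
the board itself) gives, after subtraction,

$$ (\mathrm{CoM}_\alpha - \mathrm{CoM}_\beta)\, M
   \;=\; (I - R(\theta))\, \mathrm{CoM}_{1,\alpha} M_1 , $$

with $R(\theta)$ the 2×2 rotation matrix. Everything static cancels in the
difference — that is the whole trick. Solving the 2×2 system
(`estimate_moment()`) and taking the norm yields

$$ M^{(1)}_1 \;=\; \bigl| (I - R(\theta))^{-1}
   (\mathrm{CoM}_\alpha - \mathrm{CoM}_\beta) \bigr|\; M , $$

which requires only the measured total mass $M$, never the segment mass
itself. Because $I - R(\theta)$ is a scaled rotation with both singular
values equal to the *chord gain* $2\sin(\theta/2)$, the solve has the
closed scalar form

$$ M^{(1)}_1 = \frac{M\,|\Delta \mathrm{CoM}|}{2\sin(\theta/2)} $$

(`estimate_moment_scalar()`), which also exposes the estimator's noise
amplification: CoM noise is divided by $2\sin(\theta/2)$, so small rotation
angles are noisy and $\theta = 180^\circ$ is optimal. Angles within 1° of
0 or 360° (configurable) are rejected outright.

Conventions. Angles are accepted in degrees everywhere and are positive
counter-clockwise in the top-down view; the moment is invariant under the
opposite convention (only the sign of the solved vector changes), which the
test suite asserts. The solved vector returned in `com1_alpha` is the
mass-scaled segment CoM $\mathrm{CoM}_{1,\alpha} M_1 / M$; its norm times
the total mass is the moment. The total mass $M$ is taken as the mean of
the two postures' summed readings; a disagreement beyond a tolerance
(default ≈ 11 g, a 3σ band for six independent readings at the scale's
1.5 g precision) raises an inconsistent-session error. A stricter band at
3 × 1.5 g would flag roughly a fifth of perfectly clean sessions under the
same instrument model, which is why the 3σ form was chosen.

## What the simulator emulates

`simulate_session()` is the exact forward model: a rigid segment
(`rigid_segment()`), a static remainder and a static carrier
(`rigid_body_model()`) resting on three supports. Support loads are the
barycentric coordinates of the system CoM times the total mass
(`forward_loads()`); a CoM outside the support triangle means a negative
support load, i.e. the board tips, and raises a classed error. The model
constructor already rejects configurations whose segment-CoM circle leaves
the triangle at any angle.

The noise model (`noise_model()`) emulates the instruments of the original
bench protocol:

| source | default | unit | rationale |
|---|---|---|---|
| `scale_sigma_g` | 1.5 | g | stated precision of the weighing scale |
| `scale_quantum_g` | 0.1 | g | stated reading resolution (applied after the Gaussian noise) |
| `angle_sigma_deg` | 0.5 | deg | manual protractor reading of overlapped photo prints |
| `position_sigma_cm` | 0.2 | cm | manual straightedge digitisation of support positions |
| `drift_sigma_cm` | 0 | cm | posture drift between the three sequential single-scale weighings |

Two structural choices deserve emphasis. First, the support positions are
digitised **once per measurement set and shared between the two postures**:
both postures appear on one overlapped print and the supports do not move.
This makes position error enter only through the (small) change in
barycentric load weights between postures, rather than at full strength —
had each posture received independent position noise, that source alone
would dominate everything else by an order of magnitude. Second, posture
drift models the sequential single-scale protocol (the subject must hold
still while three supports are weighed in turn); it perturbs the true CoM
independently per support reading and defaults to zero, appropriate for a
rigid dummy.

The preset `dummy_bar_model()` reproduces the calibration bench: a uniform
aluminium bar of 3.013 kg and 77.2 cm pivoted at its end (lever arm
38.6 cm, calibrated moment 116.3018 kg·cm), a 52.066 kg block as static
remainder and an 11.627 kg board as carrier. `human_leg_model()` emulates
the leg session (subject 63.460 kg on a 15.569 kg frame, rotation 48.8°)
with the segment tuned so its true moment equals the session mean of
388.8 kg·cm and a leg mass of 16 % of body mass, a standard anthropometric
fraction; it is meant for qualitative noise studies, since the subject's
true leg parameters are unknown.

The support layout was not reported for either experiment. The presets use
the standard tripod: supports at 120° spacing on a 75 cm circle around the
static load centre. An equilateral layout gives the support positions an
isotropic second moment, so reading noise maps into CoM noise equally in
every direction and the single-set SD follows the inverse chord-gain law
$\propto 1/(2\sin(\theta/2))$ cleanly; a lopsided triangle would make the
precision depend on the direction of the CoM displacement. Remainder and
carrier CoM placements (near the board centre) are likewise plausible bench
values. Every noise figure obtained from the presets is conditional on this
geometry.

What the simulator does *not* emulate: camera perspective distortion
(negligible at the ~2.4 m camera distance of the original setup), errors in
locating the centre of rotation (they cancel exactly in the CoM difference,
so they cannot affect this estimator — on real anatomy they would instead
bias the *interpretation* of the lever arm), and any non-rigidity of the
segment itself. Passing tests therefore demonstrate correctness of the
estimator and plausibility of the error budget, not the field accuracy of
the protocol on human subjects.

## Uncertainty machinery

`monte_carlo()` repeats simulate→estimate at one angle (default 2000
replicates — enough to pin a ~1 %-scale relative SD to a few parts in a
hundred while staying interactive) and reports the mean, SD and relative SD
against the true moment; replicates that tip the board are dropped and
counted, and the run aborts if more than 1 % tip. With `breakdown = TRUE`
one-factor-at-a-time runs attribute the variance to the scale, angle and
position sources.

`analytic_sd()` is the first-order delta-method companion through the
scalar form: reading noise (Gaussian plus a $q^2/12$ quantisation term) is
propagated through the reaction-board weights of each posture and projected
on the CoM-difference direction; shared position noise enters through the
between-posture weight change; angle noise through
$\partial M^{(1)}/\partial\theta = -M|\Delta\mathrm{CoM}|\cos(\theta/2)/(4\sin^2(\theta/2))$.
The three variances add in quadrature. It tracks the Monte Carlo within a
few percent at the default noise level; posture drift is Monte Carlo only.

Under the default noise model the dummy-bar preset gives a single-set
relative SD of about 0.5 % at $\theta = 90^\circ$ (the angle term
dominates, roughly three quarters of the variance). The bench experiments
reported 1.4–1.7 %; the gap is expected, since the real sessions contained
noise sources with unquantified magnitudes (protractor technique on a
640×480 print, residual posture shifts, scale placement) that the
documented defaults deliberately do not inflate to match. The estimator is
slightly biased upward at high noise — the norm of a noisy vector
over-estimates the norm of its mean — and the package quantifies rather
than corrects this bias, which is far below the noise floor in any
realistic regime.

## Numerical choices and degenerate inputs

* Sample SD uses the $n-1$ denominator (metrological convention); both
  published precision figures are insensitive to the choice at their
  printed precision. Relative figures are rounded to one decimal in rendered
  reports; JSON reports keep full precision.
* The singularity guard defaults to 1°; within the admissible range the
  2×2 solve is perfectly conditioned (both singular values equal).
* Collinear supports, zero total load, negative readings, missing support
  rows and unknown posture labels all raise classed errors
  (`segmoment_degenerate_geometry`, `segmoment_empty_load`,
  `segmoment_parse_error`, ...), so pipelines can distinguish bad data from
  bad configurations.
* Simulated sessions are byte-reproducible for a fixed `seed`.

## Problem sizes used in the test suite

The suite exercises 1000-instance property sweeps for the exact identities
(statics round trip, chord-form equivalence), Monte Carlo runs of 1200–5000
replicates for the stochastic scalings, and 30-set end-to-end sessions
mirroring the bench protocol; the complete suite runs in well under a
minute on a laptop-class machine.

## Known limitations

* The estimator needs the rotation to happen in the horizontal plane about
  a fixed axis; out-of-plane motion and moving rotation centres are outside
  the model.
* Second-order moments (moments of inertia) cannot be recovered from two
  static postures.
* The human-leg preset's segment parameters are a calibrated stand-in, not
  subject truth; only its total masses and rotation angle are measured
  quantities.
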