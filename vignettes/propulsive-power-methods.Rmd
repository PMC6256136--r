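---
title: "Estimating propulsive power from wearable sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating propulsive power from wearable sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipower)
```

## The power-balance model

skipower estimates the propulsive power $P_{prop}$ a (roller-)skier
generates, from body-worn GNSS and inertial sensors, using the power-balance
principle: the athlete's propulsive output either changes the mechanical
energy of the system or is dissipated to the environment,

$$P_{prop} \;=\; \dot E_{mech} + \dot W_{env}
  \;=\; (m\dot{\mathbf v} - \mathbf F_g - \mathbf F_d - \mathbf F_f)\cdot\mathbf v.$$

The skier and equipment are modeled as a point mass $m$ at the center of
mass, so $E_{mech} = \tfrac12 m |\mathbf v|^2 + m g z$ with $g =
9.81\,\mathrm{m\,s^{-2}}$. The propulsive force is $F_{prop} =
P_{prop}/|\mathbf v|$. Both are reported per kilogram. The assumptions that
matter:

* **Point mass.** Work done moving limbs relative to the center of mass is
  not counted; $P_{prop}$ is a lower bound on total mechanical output.
* **Aerodynamic drag** follows the drag equation
  $\mathbf F_d = -\tfrac12 \rho |\mathbf v_f|^2 A C_D(\mathrm{Re})\,
  \hat{\mathbf v}_f$ with $\mathbf v_f$ the velocity relative to the air.
  Both the frontal area $A$ (posture) and the drag coefficient $C_D$
  (Reynolds number) vary along the course.
* **Rolling resistance** is Coulomb-like,
  $\dot W_f = C_{rr}\,|\mathbf N_g + \mathbf F_c|\,|\mathbf v|$, where the
  centripetal load $\mathbf F_c = m|\mathbf v|^2\mathbf K$ of turns is added
  vectorially to the surface-normal gravity load $\mathbf N_g$ (the course
  is assumed level in the mediolateral direction; no banking input exists).
* **Tuck.** In the crouched downhill position the athlete generates no
  propulsion; $P_{prop}$ is defined to be zero there. Tuck is detected from
  gyroscope energy, not assumed from speed (except in the sensor-free
  fallback `tuck_from_speed()`).

## Trajectory processing

Vertical position is the accuracy bottleneck: a standalone receiver's height
error of meters converts directly into potential-energy rate errors of
$\sim 1\,\mathrm{W\,kg^{-1}}$. The pipeline therefore maps the athlete's
horizontal positions onto a precisely surveyed reference centerline of the
course and takes the height from the reference.

* **Reference track.** The survey is resampled to 1 m arc-length spacing and
  smoothed with cubic smoothing splines per coordinate
  (`penalized_spline()`), minimizing
  $p\sum_i w_i (y_i - f(x_i))^2 + (1-p)\int f''^2$ with $p = 0.02$ and arc
  length in meters. Points whose carrier-phase ambiguities were only
  float-resolved get weight 0.01 against 1.0 for fixed points (both
  configurable; the published description states the weighting but not the
  values). $p = 1$ interpolates and $p \to 0$ tends to the weighted
  least-squares line, which the tests verify.
* **Athlete stream.** 10 Hz positions are filtered with a second-order
  bidirectional (zero-phase) Butterworth low-pass at 0.3 Hz, which removes
  antenna sway that cannot be center-of-mass motion. The series is
  mirror-padded generously before `signal::filtfilt` so filter start-up
  transients stay out of the data; the first and last ~10 s are still the
  least reliable part of any recording and the recovery tests trim them.
* **Map matching.** Each sample is projected to the nearest point of the
  reference (linear interpolation between grid points; ties go to the
  smaller arc length). Because the course is lapped and self-crossing, the
  search is restricted to a ±200 m arc-length window advanced monotonically
  from the previous match; the first sample searches globally. Samples
  farther than 20 m from the reference are flagged unmapped, and more than
  10% unmapped aborts with a diagnostic.
* **Kinematics at 1 Hz.** After filtering and mapping, the series is
  decimated to 1 Hz (the 0.3 Hz filter already bounds the bandwidth) and
  differentiated with five-point stencils, one-sided at the edges, exact
  for quartics. Curvature is
  $\mathbf K = -\mathbf v\times(\mathbf v\times\dot{\mathbf v})/|\mathbf v|^4$.
  Below a 0.5 m/s speed floor, curvature and $F_{prop}$ are not evaluated
  ($1/v$ blow-up). Sampling gaps are flagged, never interpolated.

## Posture from the IMUs

Torso and thigh IMUs (100 Hz) are first rotated into a gravity-aligned frame
using a static standing pose: one rotation cancels lateral tilt, a second
cancels forward tilt, leaving the mean specific force at $(0,0,+1g)$. Pitch
is then $\theta = \operatorname{atan2}(a_y, a_z)$ of the accelerometer
smoothed with a 2 s bidirectional moving average (two boxcar passes — a
triangular kernel), clamped to $[-\pi/2,\pi/2]$ so $\cos\theta$ in the area
model keeps a defined sign. The frontal area follows

$$A = A_0\,(\beta_0 + \beta_1\cos\theta_{torso} + \beta_2\cos\theta_{thigh})
  + A_{equip},$$

with the athlete's standing area $A_0$, equipment constant
$A_{equip} = 0.045\,\mathrm{m^2}$, and regression coefficients
$\beta = (0.27, 0.32, 0.38)$.

Tuck detection thresholds the smoothed squared gyro magnitude: the athlete
is tucked when **both** sensors show
$\mathrm{smooth}(|\omega|^2) < 5{,}000\,^\circ{}^2\mathrm{s}^{-2}$ (strict
inequality). The order — square first, then smooth — is a deliberate,
configurable choice; smoothing first would cancel oscillatory rotation and
misclassify vigorous poling as stillness. Gyro units are degrees per second
internally because the threshold is printed in degree units. Posture joins
the 1 Hz kinematics by averaging each channel over the surrounding second
and re-applying the threshold to the bin means.

## Aerodynamics

Air density comes from the ideal gas law
($R_{specific} = 287.058\,\mathrm{J\,kg^{-1}K^{-1}}$) and viscosity from
Sutherland's formula with the standard-air constants
($\mu_{ref} = 1.716\times10^{-5}$ Pa s, $T_{ref} = 273.15$ K, $S = 110.4$ K;
the source the published method cites does not print its constants, so the
standard set is used and configurable). The Reynolds number
$\mathrm{Re} = \rho L v_f / \mu$ uses the speed relative to the air and the
athlete's characteristic width $L$ (default 0.30 m).

$C_D(\mathrm{Re})$ is a logistic drag-crisis curve fitted to blunt-body
data, rescaled so that $C_D(\mathrm{Re}_{ref}) = 0.872$ exactly at the
reference condition measured on speed skaters;
$\mathrm{Re}_{ref} = 2.4\times10^5$ by default (12 m/s, $L = 0.30$ m,
$\nu = 1.5\times10^{-5}$), configurable because the exact value is not
printed. Validity is restricted to $\mathrm{Re}\in[4\times10^4,
5\times10^5]$ (≈ 2–25 m/s); outside, Re is clamped with a warning.

Both the $C_D$ curve and the allometric area model
$A(v)/m^{2/3} = \gamma_1 - \gamma_2/(1+e^{-(\cdot)})$ share one canonical
logistic, $f(x) = \mathrm{high} - \mathrm{amplitude}/(1 + e^{-(x -
\mathrm{mid})/\mathrm{width}})$. Two parameter mappings are provided because
the published rate/offset pairing does not reproduce the published figures
under a literal reading: evaluated literally, the printed exponent places
the area transition near 16 m/s, while the figures (and the tuck behavior)
put it at ~9 m/s. The default `"calibrated"` mode keeps the printed plateau
levels but anchors the midpoints at the figure locations — 9.2 m/s for the
area transition, $\mathrm{Re} = 1.7\times10^5$ for the drag crisis, with a
width of $2.5\times10^4$ in Re chosen so the drop spans roughly
$10^5$–$2.5\times10^5$ as drawn. `"literal"` evaluates the printed exponent
as written. Plateau limits, monotonicity and the anchor constraint are
identical in both modes and are what the worked numbers depend on.

Wind is one horizontal vector per evaluation: the hourly 10 m speed is
brought to athlete height (1 m) with the log wind profile
$u(z) = u_{10}\ln(z/z_0)/\ln(10/z_0)$, $z_0 = 0.1$ m (factor exactly 0.5),
and the meteorological direction is converted to a flow vector.

## Power assembly and summaries

Per kilogram at 1 Hz:
$P_{prop}/m = \dot{\mathbf v}\cdot\mathbf v + g v_z - (\mathbf F_d\cdot
\mathbf v)/m + \dot W_f/m$. The raw series is smoothed with a 5 s
bidirectional moving average and tuck samples are then set to zero — zeroing
after smoothing, so tucked samples are exactly zero as defined (the reverse
order is available). Negative values are retained and flagged: they are
genuine braking or measurement error, and clipping them would bias means.

`fit_power_regression()` regresses $P_{prop}$ on speed and along-track
acceleration over non-tuck samples. Two estimator details matter and are
defaults here: the predictors are smoothed with the same 5 s window as the
response (a filtered response against raw predictors attenuates the
acceleration coefficient and misattributes it to speed), and non-tuck
samples within half a smoothing window of a tuck transition are excluded,
because there the smoothed power mixes active propulsion with defined zeros
and reflects the filter, not the athlete. On simulated races these two
choices are the difference between recovering the generating policy's speed
coefficient (−0.54 N/kg) and biasing it to ≈ −0.62.

`steady_state_speed()` returns the positive real root of the cubic obtained
by substituting the linear policy into the power balance at $\dot v = 0$.
When that root exceeds the tuck-entry speed the athlete would coast, and
the zero-power equilibrium applies — but only if that equilibrium itself
lies above the tuck-exit speed; otherwise neither branch is
self-consistent (a hysteresis regime) and the policy root is returned.

## Monte Carlo uncertainty and sensitivity

The error sources propagated are those that act on the force models — wind,
frontal area, drag-coefficient parameters, reference drag coefficient, and
$C_{rr}$ — with 2,500 samples per race:

* wind speed Rayleigh with expectation equal to the hourly mean at athlete
  height (scale $= \mathrm{mean}\sqrt{2/\pi}$); direction normal with
  SD 25°; one draw per sample, constant over the race (the wind field is
  hourly; gusts are acknowledged as unmodeled);
* frontal-area residual $\mathcal N(0, \sigma_{resid}^2)$, drawn once per
  sample and applied as a persistent offset (model error does not average
  out within a run); per-step redraw is available. $\sigma_{resid}$ of the
  area fit is not published; the default 0.02 m² is a synthetic stand-in
  and should be set from calibration data when available;
* $C_D$ parameters multivariate normal — when no fit covariance is
  supplied, a diagonal covariance is built from the published 95% CIs as
  $(\mathrm{CI}/1.96)^2$. In calibrated mode only the plateau parameters
  act on the curve; the transition anchors are fixed geometry;
* $C_{D,ref} \sim \mathcal N(0.872, 0.079^2)$ and
  $C_{rr} \sim \mathcal N(\hat C_{rr}, (2.3\times10^{-3})^2)$.

GNSS position error is deliberately **not** in the Monte Carlo: the
published uncertainty model treats it separately (via the
standalone-vs-reference comparison), and so does this package
(`build_kinematics(..., ref = NULL)` is the degraded pathway).

Because the perturbed inputs do not touch the trajectory stage, each sample
re-evaluates only the force models and the power inversion on the fixed
kinematics — exact, and fast enough that 2,500 samples take seconds. Each
sample uses a seed-derived substream, so results are independent of
evaluation order and bit-reproducible. Accuracy is the pooled SD
(root-mean-square of per-step SDs over non-tuck samples; pooling weights
are not published, RMS is the standard choice). The sensitivity analysis
compares that accuracy against the inter-athlete or lap-to-lap SD of
$F_{prop}$ at integer-meter positions (tuck excluded) and applies the
90%-of-positions rule.

## The synthetic-data generator

The generator exists so every stage is testable without field data; its
defaults are the study conditions, not tuning knobs.

* **Course:** closed loop of 4.5 km (three laps), height difference 51 m,
  total climb 166 m per lap. The horizontal layout is a smoothly perturbed
  loop scaled to the lap length; the elevation mixes a slow undulation with
  faster harmonics, and the mix is solved at build time so realized climb
  and range match the spec within 2%. Grades reach ≈ ±20%, which is what a
  World-Cup-like profile with these statistics requires. Five short
  sections are flagged float to emulate degraded survey quality.
* **Skier:** the policy $P(v,\dot v) = -0.54 v - 0.71\dot v + 7.26$ W/kg
  with a power floor at zero, tuck entry above 9 m/s and exit below 8 m/s.
  The along-track equation of motion is integrated with RK4 at
  $dt = 0.1$ s; the $\dot v$-dependence of the policy is solved in closed
  form inside the derivative. Course geometry (position, tangent, grade,
  curvature) is evaluated from C2 periodic splines of arc length whose
  analytic derivatives keep gravity exactly consistent with the elevation —
  that is what makes the per-lap energy audit close to < 0.1% and a
  step-halving check agree to millimeters per second.
* **Sensors:** GNSS is truth plus i.i.d. Gaussian noise (defaults 1 m
  horizontal, 2 m vertical — the 2:1 ratio mirrors the standalone
  receivers' weaker vertical accuracy). IMU pitch follows a piecewise
  posture schedule (moderate lean when active, deep crouch in the tuck);
  the gyro has phase-staggered sinusoids (230°/s per axis at 0.9 Hz,
  poling cadence) during activity and only noise (8°/s) in the tuck. The
  activity envelope goes quiet 1.3 s before tuck entry and resumes 1.3 s
  after exit: athletes stop large segment rotations before crouching, and
  with the 2 s smoothing and the 5,000°²/s² threshold this lead makes the
  detected boundary an approximately unbiased estimate of the true one.
* **Not emulated:** limb kinematics and cycle-by-cycle poling, wind gusts,
  GNSS multipath and dropouts, surface-quality variation of $C_{rr}$.
  Passing the end-to-end tests therefore demonstrates that the pipeline
  inverts its own physics faithfully (no self-inconsistency), not that
  field data of arbitrary quality will reach the same accuracy.

Problem sizes in the shipped tests: the full three-lap, 13.5 km race at
$dt = 0.1$ s (~22,000 integration steps, ~2,250 s of 1 Hz output) is
simulated once and shared across tests; cheaper properties use a 1.2 km
single-lap course and flat constant-speed scenarios. Monte Carlo checks use
625–2,500 samples.

## Known limitations

* The calibrated-vs-literal ambiguity of the logistic exponents is resolved
  by figure anchors, not by refitting the original data (which are not
  available). Quantities that depend on the transition location (drag area
  between ~8 and ~12 m/s) differ between the modes; everything anchored at
  plateaus or at the reference Reynolds number does not.
* Smoothing-window edge transients make the first/last ~10 s of a recording
  less reliable; summaries include them, recovery tests trim them.
* The regression estimator's transition-margin exclusion discards a few
  percent of samples near tuck boundaries; on real data those samples mix
  filter behavior with genuine power tapering, and no unbiased treatment
  exists at 1 Hz.
* $F_{prop}$ is undefined below 0.5 m/s; near-standstill starts are flagged
  missing rather than extrapolated.
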