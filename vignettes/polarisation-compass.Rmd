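---
title: "The polarisation compass model: assumptions, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The polarisation compass model: assumptions, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcompass)
```

`polcompass` simulates how an insect can extract a stable, geocentric
heading from the polarisation pattern of the sky. This vignette is the
package's methodological record: the model and its assumptions, the
parameters that matter and their defaults, the numerical choices, and what
the simulations can and cannot say about real skies and real brains.

## The sky model

Skylight polarisation arises from atmospheric scattering. The package uses
the single-scattering Rayleigh description, which captures the two features
the compass relies on:

* the **degree of linear polarisation** depends only on the angular
  distance $\gamma$ from the sun,
  $d(\gamma) = d_{\max}\,\sin^2\gamma/(1+\cos^2\gamma)$, rising from 0 in
  the sun's direction to its maximum exactly 90° away;
* the **e-vector orientation** is perpendicular to the great circle through
  the sun and the view point, so the e-vectors form concentric rings about
  the sun.

$d_{\max}$ defaults to 0.75: multiple scattering, aerosols and ground
albedo keep real clear skies well below the Rayleigh limit of 1, and 0.75
is a typical zenith-distance-90° clear-sky value. Luminance is modelled
only up to a positive factor (the Rayleigh phase function
$1+\cos^2\gamma$): the polarisation-opponent stage divides it out exactly,
and a property test asserts that scaling luminance by any positive constant
leaves every response unchanged.

What this stand-in omits: neutral points (Arago, Babinet), wavelength
dependence, clouds and horizon haze. Disturbance by clouds or occlusion is
modelled downstream, as a fraction $\eta$ of sensor units that fail (see
below), not as a radiative phenomenon.

Sun positions come either from quasi-uniform hemisphere sampling (a
Fibonacci lattice, rotated about the zenith by a seeded angle so that
different seeds give different but equally homogeneous ensembles) or from
an NOAA-style solar ephemeris given date, time and location. The ephemeris
is geometric (no refraction); its error is far below a degree for modern
dates, verified in the test suite against an independently derived
almanac algorithm. The default site is Seville, Spain, and the default
date mid-September, which puts the 10 am sun at an azimuth of about 104°
— the condition the behavioural experiments emulate. (No single date
reproduces both that azimuth and a 76-minute azimuth drift above 20°;
at 10 am the true drift is about 14.7° per 76 min, which is what the
long-run simulations use.)

## The sensor array

The dorsal rim array is cyclopic: $n = 60$ point-sampling units within a
spherical cap of radius 28° (receptive field $\omega = 56°$) about the
sensor zenith. The layout is deterministic: rings spaced per the
homogeneous-packing expectation for the cap, unit counts proportional to
ring circumference, alternate rings staggered by half a spacing. Each
unit's polariser axis is tangential to its ring, $\alpha_j = \phi_j - 90°$
— the fan-like arrangement of the ant dorsal rim. The acceptance angle
$\rho = 5.4°$ is metadata only: it is far below the angular scale over
which the sky pattern varies, so units point-sample along their optical
axis.

One representation detail is load-bearing. The polariser axis is
physically axial (a filter at $\alpha$ and $\alpha + 180°$ is the same
filter), but the synaptic weights of the compass use the *directed* value
$\phi_j - 90°$ in $[0°, 360°)$. Wrapping it axially makes the weights
blind to which side of the array a unit sits on, collapses the code to a
180°-ambiguous one, and destroys the model's full-circle heading estimate.
The optics use only $\cos 2(\chi-\alpha)$ and are unaffected.

Each unit sees Malus-law photoreceptor stimuli
$s_{\parallel,\perp} = Y\,[1 \pm d\cos 2(\chi-\alpha)]/2$, passes them
through a square-root transform (which compresses bright-sky skew and is
defined at zero) and an opponent stage
$r = (\sqrt{s_\parallel}-\sqrt{s_\perp})/(\sqrt{s_\parallel}+\sqrt{s_\perp})
\in [-1, 1]$. Disturbance masks exactly $\operatorname{round}(\eta n)$
units, chosen uniformly; failed units report 0, equivalent to zero weight
downstream. In the evaluation protocols a fresh mask is drawn per
prediction; in the behavioural trials one mask persists per foraging run,
because the disturbances it stands for (clouds, occlusion) persist over
minutes — this matters, since a persistent mask produces a systematic
heading bias that largely cancels between the outward and inward legs.

## The compass

The solar layer projects the POL population onto $n_{SOL} = 8$ neurons
with sinusoidal weights,
$r_\xi = \sum_j \frac{n_{SOL}}{n_{POL}} \sin(\alpha_j - \phi_\xi)\, g_j\,
r_j$, and the decoder takes the discrete Fourier fundamental: azimuth from
the phase, confidence $\tau$ from the magnitude. Because every term is a
sinusoid of the same frequency in $\phi_\xi$, the layer's response is a
pure first harmonic. Two exact consequences, both asserted as property
tests:

* the decoded angle is **independent of the population sizes** for any
  $n_{SOL}, n_{TCL} \ge 3$ (the fundamental is fully determined by three
  samples) — larger populations change nothing, and there is no aliasing
  penalty for small ones in this linear chain;
* the decoder's index phase contributes a fixed offset (+45° for 8
  neurons). The package absorbs it into a single calibration constant,
  fixed once per compass/array pair by requiring zero mean error on
  clear-sky untilted reference scenes at 30° solar elevation. This is a
  pure convention: it is one global rotation, identical for all sun
  positions.

Why the code reads the **sun's** azimuth rather than a 180°-ambiguous
polarisation axis: the weighted sum effectively measures where around the
array the polarisation signal is strongest. The most polarised sky band is
90° from the sun, so the population phase locks to the cross-solar
direction, which differs from the solar azimuth by a constant. On a clear
untilted sky the decoded azimuth is accurate to hundredths of a degree.

Confidence maps to an uncertainty $\sigma = 4°/\tau^2$. The printed form
of this relation is typographically ambiguous; the reciprocal-square
reading is the only monotone-decreasing one and is adopted throughout.
Confidence also drives the elevation estimate
$\theta' = 75° + 26°\,[\arcsin(2.855-3.5\tau)/90° - 1]$ with $\tau$
clamped to $[0.53, 1.1]$ (out-of-range confidences give the boundary
elevations; the formula's own endpoint values, 75° and ≈24.7°, are used
rather than any narrower nominal range, which is inconsistent with those
endpoints).

### Tilt gating

Under head tilt the array samples the wrong sky ring and azimuthal
geometry distorts. The gating function down-weights units by a Gaussian
ring, $g_j = \exp[-u_j^2/(2\sigma_g^2)]$ with
$u_j = \cos(\theta_g+\theta_j)\sin\theta_t -
\sin(\theta_g+\theta_j)\cos\theta_t\cos(\phi_t-\phi_j)$. Numerical
choices:

* $u$ is a dimensionless sine of an angular offset, so $\sigma_g$
  (printed in degrees, default 13°) is converted to radians before the
  division; treating it as dimensionless makes the gate inert.
* $(\theta_t, \phi_t)$ is the position of the **sky zenith in sensor
  coordinates** (for a zero-roll tilt towards world azimuth $\psi$ this is
  elevation $\theta_t$ at sensor azimuth $\psi + 180° -$ yaw). With this
  reading the $u=0$ locus coincides, at moderate tilt, with the circle of
  world zenith distance $\theta_g$ — the gate focuses the units that
  currently view the most informative sky band. The alternative reading
  (the tilt azimuth itself) selects the opposite side of the array and is
  measurably worse at every tilt.
* $\theta_j$ is the unit's elevation (a zenith-pointing unit has
  $\theta_j = 90°$); the zenith-distance reading moves the untilted ring
  off 40° and is rejected by the untilted geometry.

With the default protocol (untilted + eight 30°-tilted + eight 60°-tilted
poses, 500 suns each) the gate improves the error at every tilt level
(e.g. from about 93° to 68° at 60° tilt, and 0.06° to 0.007° untilted).

**Known limitation.** The ring gate's improvement under tilt is real but
bounded. The whole POL→SOL→decode chain is algebraically a single complex
readout $Z = \sum_j g_j r_j e^{i\alpha_j}$, so the gate can only choose
*non-negative amplitudes* for fixed anatomical phases. Fitting the best
possible non-negative amplitude profile at 60° tilt (a convex bound on
everything the Gaussian ring family can do, at any $\theta_g, \sigma_g$)
still leaves a mean error of roughly 40°, whereas allowing signed
amplitudes — equivalently, letting mirror-paired units contribute with
opposite sign, which no positive gate can emulate — brings it below 10°.
A markedly better tilted compass in this architecture therefore needs
either signed (inhibitory) gating or a tilt-dependent re-phasing of the
weights, not a better ring. The gating-parameter grid search reflects
this: the error surface over $(\theta_g, \sigma_g)$ is shallow, so its
argmin wanders across neighbouring cells between seeds.

### Time compensation

The true-compass layer copies the solar layer through cosine weights; its
preferred angles advance clockwise at the ephemeris rate
$d\phi/dt = \exp[(\theta'-36°)/10°] + 9$ °/h computed from the
confidence-derived elevation, whenever $\tau \ge 0.53$ (below that floor
the elevation inversion is undefined and the update is skipped). Shifting
all preferred angles by $\Delta$ shifts the decoded angle by $-\Delta$, so
as the sun drifts the decoded heading stays put — the layer implements an
ephemeris function without a clock.

## Evaluation protocols and problem sizes

The objective is the mean absolute wrapped azimuth error
$J = \langle |((\phi - \phi' + 180°) \bmod 360°) - 180°| \rangle$ with its
standard error (sample SD / $\sqrt{N}$). Default ensembles: 17 tilt poses
× 500 suns (8 500 predictions) for tilt studies; 1 000 untilted suns for
clear-sky accuracy; 20 mask seeds × 200 suns per disturbance level; 17 ×
100 suns per cell for the parameter sweeps. These sizes put the standard
errors well below the effect sizes of interest while keeping every
protocol in the seconds-to-a-minute range; the vectorised pipeline
evaluates all units × all suns as matrix products. Binning uniformly
sampled suns by elevation induces the hemisphere measure (more suns at low
elevation), which is the natural weighting for an animal under a real sky.

All randomness flows from one master seed through named sub-streams
(`sun`, `mask`, `terrain`, `route`, …), so changing one stream's draws
leaves the others untouched and identical seeds give byte-identical
records.

## The behavioural simulation

The agent walks a synthetic outward route — a correlated random walk to a
feeder 7 m from the nest (heading noise SD = tortuosity × 90° per step),
standing in for recorded ant foraging paths — while a home-vector
integrator accumulates (estimated heading, distance) from the 8
sinusoidally tuned TCL neurons, the same interface an anatomical
central-complex model consumes. Homing steers with a bounded turn rate to
align the compass reading with the home vector; when the vector is
consumed the agent spirals in a systematic search. Terrain is a smoothed
Gaussian random height field; the smoothing length (default 1.7 m on a
20 m arena) was calibrated once so that an altitude SD of 0.8 m yields
maximum tilts near 47°, and both knobs are exposed. Long runs scale the
route by 100 (≈700 m feeder distance, ≈76 min at 0.3 m/s), during which
the sun's azimuth drifts ≈14.7°: with time compensation the
path-integration endpoint lands within the scaled search zone; without it
the endpoint misses by roughly twice that distance. Because the tilted
compass error in this sky is tens of degrees (see the gating limitation
above), homing on steep terrain degrades noticeably beyond $\eta \approx
0.4$ disturbance rather than only at extreme levels.

## Simulated electrophysiology

The classic bench stimulus — uniform light through a rotating linear
polariser — is modelled as full polarisation ($d = 1$, maximising contrast
as on a bench), identical e-vector angle at every unit, constant
luminance. The natural-sky condition rotates a 30°-elevation sun a full
circle around the sensor. The same model yields 180°-periodic tuning
curves under the polariser (the stimulus carries only an axial cue; the
symmetric array responds identically at $\beta$ and $\beta+180°$, exactly)
and 360°-periodic tuning under the sky, whose polarisation gradient breaks
the axial symmetry. Preferred directions are response-weighted circular
means (angles doubled when axial) with a Rayleigh significance test, and a
circular-linear grid fit of preferred direction against neuron index
yields ≈22.5°/column under the polariser versus ≈45°/column under the sky.
Under the polariser with no disturbance the symmetric array's responses
cancel almost exactly; the tuning that emerges at $\eta > 0$ is carried by
the random surviving subset, so the preferred angles (and which of the two
axial peaks wins) vary across trials — trial-to-trial variability comes
from unit failure alone, with no added response noise.

## Degenerate inputs and edge cases

Darkness ($s_\parallel = s_\perp = 0$) marks a unit failed rather than
dividing by zero. A vanishing population fundamental (uniform responses,
or all units failed) flags the decode as undefined with $\tau = 0$, and
downstream confidence collapses as required. Views exactly at the sun have
undefined e-vector orientation; they carry $d = 0$, so the reported
orientation (0 by convention) has no effect. Night (sun below the
horizon) is flagged, not an error. Angles are wrapped with floating-point
guards so axial values stay in $[0°, 180°)$.

## What passing tests do and do not show

The test suite verifies the model's internal mathematics (closed-form
stages against hand computation, property tests of symmetry, luminance
invariance, population-size invariance, reproducibility) and the
qualitative phenomena: full-circle disambiguation, monotone degradation
with disturbance, gating benefit at every tilt, ephemeris compensation on
long runs, and the polariser/sky tuning reconciliation. Absolute error
magnitudes depend on the Rayleigh stand-in sky; a sky model with neutral
points, realistic horizon behaviour or spectral structure would shift
them, most visibly for the tilted and heavily disturbed conditions.
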