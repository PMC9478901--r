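---
title: "Refraction-corrected backscatter tensor imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refraction-corrected backscatter tensor imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Backscatter tensor imaging (BTI) estimates the in-plane orientation of
fibrous microstructure — here myocardial fibers — from the way the spatial
coherence of backscattered ultrasound varies as a linear array is rotated
about the imaging axis. Coherence is highest when the array is parallel to
the fibers and lowest when it is perpendicular, so the coherence at a fixed
depth traces a 180°-periodic curve in the rotation angle θ whose phase is
the fiber angle.

In benchtop and in-vivo geometries the tissue rarely touches the array: a
fluid standoff (saline, in the configuration this package models) with a
slower sound speed separates them. Beamforming with a single assumed speed
then mis-times every channel, and the transmitted and received wavefronts
additionally refract at the fluid–tissue interface. `btikit` implements
delay-and-sum coherent plane-wave compounding with exact two-layer delays
(Snell/Fermat interface crossings), time-of-flight estimation of both sound
speeds, coherence mapping over the rotational scan, and cosine-fit
extraction of the transmural fiber-angle profile — plus a seeded RF channel
simulator so the entire chain is testable without hardware.

# Delay model

The array lies on the line $z = 0$; $z$ grows into the medium. Layer 1
(fluid, speed $c_1$) occupies $z < z_1$ and layer 2 (tissue, $c_2$) lies
below. Two propagation legs are modeled separately:

* **Transmit** — a steered plane wave with angle $\alpha$ from the $z$ axis.
  Above the interface its phase delay at $(x, z)$ is
  $(x\sin\alpha + z\cos\alpha)/c_1$. Below, the wave refracts; the vertical
  slowness in layer 2 is $\sqrt{1/c_2^2 - \sin^2\alpha/c_1^2}$, which is
  $\cos\alpha'/c_2$ with $\sin\alpha'/c_2=\sin\alpha/c_1$ (Snell). The
  transmit model is a pure plane wave: no diffraction of the transmitted
  field is simulated, matching the compounding assumption.
* **Receive** — a spherically spreading echo from $(x, z)$ to the element at
  $(x_0, 0)$. For $z > z_1$ the ray refracts at a crossing point $x_1$ that
  satisfies Snell's law, equivalently minimizes the two-segment travel time
  (Fermat). The crossing is found by bisection on the signed Snell residual
  $\frac{x_1-x_0}{c_1\sqrt{z_1^2+(x_0-x_1)^2}}-\frac{x-x_1}{c_2\sqrt{(z-z_1)^2+(x-x_1)^2}}$,
  which is strictly increasing in $x_1$ on $[\min(x_0,x), \max(x_0,x)]$, so
  the bracket never fails and 72 halvings put the crossing far below a
  nanometre. The equivalent quartic formulation has up to four roots and
  poor conditioning near vertical rays; the monotone-residual route needs no
  root selection at all. Tests pin the result against a dense-grid Fermat
  search and a residual bound of $10^{-9}$ of the slowness scale.

The delay-and-sum delay is the sum of the two legs. With $c_1 = c_2$ both
reduce to the usual single-speed compounding delays to better than
$10^{-12}$ relative — the refraction-corrected beamformer degrades
gracefully into the textbook one.

# Beamforming and the coherence factor

`das_focus()` delays and compounds all transmits but keeps the per-element
signals $s(x_k, t)$ in a short window around each pixel's focal time,
because the spatial coherence factor needs them *before* the aperture sum:

$$C = \frac{\sum_{T_1}^{T_2}\big|\sum_{k=1}^N s(x_k,t)\big|^2}
            {N\sum_{T_1}^{T_2}\sum_{k=1}^N |s(x_k,t)|^2}.$$

$C$ is 1 for perfectly aligned channels, $1/N$ for a single active channel
and $\approx 1/N$ in expectation for incoherent noise. The window defaults
to 0.19 µs (about 3.4 cycles at 18 MHz); the focal time is the on-axis
round trip computed with the same medium model used for the delays.
Sub-sample delays are linearly interpolated (adequate at 62.5 MHz sampling
of an 18 MHz pulse, and documented as swappable); samples outside the
record contribute zero and are counted, with a pixel flagged invalid when
more than half its contributions fall outside. Receive weighting is uniform
— the coherence factor is defined with unweighted sums — and the receive
aperture follows an f-number rule (elements within $z_c/2f_\#$ of the strip
center, $f_\# = 1$ by default, evaluated at the median pixel depth so that
one aperture serves the whole strip), with `"full"`/`"fixed"`/explicit
overrides. $C$ is averaged in a moving window of 1.5 mm × 0.25 mm centered
on the imaging axis; the average is taken over per-pixel coherence values
(not over channel data), the reading of the averaging step adopted here.

# Orientation extraction

At each depth the coherence-versus-rotation curve is fit with
$C \approx A_0 + A_1\cos[2(\theta-\theta_{fib})]$, linear in the basis
$(1, \cos 2\theta, \sin 2\theta)$, so the least-squares problem is solved
exactly with no iteration, weighting or starting values. $A_1 \ge 0$ by
construction; $\theta_{fib} = \tfrac12\,\mathrm{atan2}(\hat c,\hat b)$ is
mapped to $[0°, 180°)$, reflecting the axial (period-180°) character of
fiber orientation. When $A_1$ sits at the numerical noise floor the angle
is reported as undefined rather than fabricated, and $R^2$ is reported as
undefined (not 0 or 1) when the total sum of squares vanishes; downstream
averages skip flagged entries and report how many were skipped. The
fractional anisotropy $FA = A_1/\sqrt{(A_0^2+A_1^2)/2}$ summarizes the
modulation depth; $A_0$, $R^2$ and $FA$ together grade beamforming quality
and orientation sensitivity. Validation against a programmed profile uses
period-180° wrapped differences, with the truth interpolated on the
unwrapped axial circle; circular statistics for axial data use angle
doubling (mean $\tfrac12\,\mathrm{atan2}$ of doubled-angle resultants,
circular SD $\tfrac12\sqrt{-2\ln\bar R}$).

# Time-of-flight sound speeds

The fluid speed comes from a single unsteered transmit over two flat
reflectors a caliper-measured $L = 6.34$ mm apart: $c_1 = 2L/(t_0 - t_A)$,
evaluated on all near/far pairs from two symmetric lateral element groups
(the groups are parameterized as fractions of the half-aperture so reduced
arrays scale sensibly), with optional median ± 3 MAD outlier rejection and
the retained pair count reported. With the tissue in place, the upper and
lower surface times $t_B$, $t_C$ (25% of the window-local envelope maximum)
and the through-tissue reflector time $t_D$ (50%) are read from A-lines at
$x = 0$ beamformed at a fixed nominal 1540 m/s, averaged over all rotation
angles; then $c_2 = c_1(1 + (t_A - t_D)/(t_C - t_B))$,
$h = (c_2/2)(t_C - t_B)$ and $z_1 = c_1 t_B/2$.

Three detection choices matter and are deliberate:

* **Rise-offset correction.** A threshold crossing precedes the envelope
  peak by the pulse's own rise time, identical for every echo that shares
  the pulse shape. Time *differences* are unbiased either way, but absolute
  $t_B$ (hence $z_1$) would carry the offset, so when the pulse is known
  (always, in simulation) the crossing is corrected by the clean pulse's
  rise offset at the same threshold.
* **Peak-edge detection.** With few compounded transmits, imperfectly
  cancelled off-axis energy leaves a low pedestal ahead of strong echoes.
  The crossing is therefore located by walking backward from the window
  maximum to the rising edge of the dominant echo, instead of taking the
  earliest crossing in the window.
* **Near-normal transmits and dynamic aperture for timing.** A steered
  plane wave maps a flat specular interface to an apparently shallower
  depth, so compounding steered transmits smears the leading edge of
  surface and reflector echoes. Timing A-lines therefore use only
  transmits within 4.5° of normal and a depth-dependent f-number-limited
  aperture. The orientation pipeline is unaffected; this applies to echo
  timing only.

Gate placement mirrors benchtop practice (windows placed "around" the
expected surfaces); for simulated scans the gates are derived from the
generator's ground truth, standing in for the manual inspection step.
Estimates are robust to the nominal A-line beamforming speed across
1500–1560 m/s, and recovery on randomized phantoms achieves median errors
below 1% ($c_1$, $c_2$, $z_1$) and 2% ($h$); both are locked in by tests.

# The synthetic-data generator

The simulator produces per-rotation, per-transmit, per-element RF for a
two-layer scene with full ground truth. Its travel times intentionally do
not share code with the beamformer: receive times come from a separate
golden-section Fermat minimizer (C++, interval tolerance 30 nm, i.e. time
error below $10^{-15}$ s at the stationary point), transmit phases from the
refracted-plane-wave accumulation, and reflector echoes recorded through
the tissue slab from a horizontal-slowness shooting solve of the
fluid/tissue/fluid path — so end-to-end agreement is a physics check, not
an inverse crime. Echo wavelets are evaluated from a 64× oversampled pulse
table at the exact arrival time of each (scatterer, element, transmit)
triple; amplitudes carry spherical spreading per element. Scenes rotate
rigidly about the z axis (the array frame is fixed); elements are points at
$y = 0$, so elevation enters only through path lengths.

The fibrous phantom arranges point scatterers along parallel fiber lines in
horizontal strata whose direction follows a programmable depth profile
(default: linear twist +60° → −60° across a 2 mm slab). The defaults were
set by what the coherence physics demands of a fiber-like microstructure at
18 MHz (wavelength ≈ 85 µm in tissue), and each encodes a lesson from
building the generator:

* `scatterer_spacing = 40 µm` — sub-wavelength along the fiber, so a fiber
  scatters as a continuous line; coarser sampling turns fibers into rows of
  resolvable points with almost no orientation signal.
* `fiber_spacing = 0.12 mm` with per-fiber random offsets up to a quarter
  spacing — a few wavelengths apart, de-grated so the lattice does not act
  as a diffraction grating.
* `amp_sd = 1.0` — strong per-fiber amplitude heterogeneity (scatterers in
  one fiber share an amplitude, with 10% point-to-point variation). This is
  the dominant driver of the coherence anisotropy; with homogeneous fibers
  the along/across contrast nearly vanishes.
* `fiber_z_sd = 15 µm`, `jitter_z = 2 µm` — each fiber gets its own small
  axial offset so a stratum is a thin band, not a specular sheet (sheets
  smear axially under steered transmits and bias the fitted angles toward
  shallower depths), while scatterers within a fiber stay phase-coherent.
* the footprint is a **disk** (radius `extent = 1.3 mm`); a square
  footprint imprints a lab-frame angular modulation on $C(\theta)$ that
  corrupts fits whenever fibers align with the lab axes.
* tissue surfaces are dense scatterer disks with 3 µm axial roughness
  (λ/28): bright enough for timing, flat enough to keep a clean envelope
  edge; the aluminum/POM reference reflectors stay perfectly specular.
* `noise_std = 3` (≈ 20 dB per-channel SNR against the default phantom's
  RF rms) stands in for attenuation-limited SNR at 18 MHz; attenuation
  itself is out of the simulator's scope.

# Reduced study scale

The default configuration is a desk-scale reduction of the acquisition the
package targets: 64 elements (0.10 mm pitch), 11 plane waves from −20° to
+20° in 4° steps, rotation in 15° steps over 360°, a 2 mm slab under 4 mm
of fluid, with the acquisition-scale constants (128 elements, 41 transmits
in 1° steps, 5° rotation steps) available via `default_config(full_scale =
TRUE)`. The per-depth profile is reported on a 5%-of-thickness grid, and
depth-averaged metrics exclude one axial averaging window at each boundary
(plus an optional epicardial exclusion band). Profile depths map to percent
thickness through the focal-time axis using $t_B$ and $t_C$, so the
two-layer and baseline modes are compared at identical tissue locations.

# What passing tests do and do not show

The generator reproduces the geometry, timing and first-order coherence
physics of a rotational two-layer scan: refraction, speed mismatch,
fiber-direction-dependent spatial coherence, specular surfaces, additive
noise. It does not model attenuation, dispersion, multiple scattering,
reverberation clutter, element directivity (available only as a config
flag) or an elevation lens. Consequences observed and locked into the test
suite:

* Refraction-corrected two-layer beamforming beats the homogeneous
  1540 m/s baseline in mean coherence $A_0$ on every phantom seed, and
  recovers the programmed transmural twist with RMSE well under 5° —
  comparable to the accuracy reported for BTI against histology.
* The $R^2$ and $FA$ orderings between the two modes, reported as
  increased by refraction correction on measured tissue data, **reverse**
  in this simulation class: the speed-mismatch aberration is a smooth
  delay screen across the aperture, which lowers total coherent gain but
  barely decorrelates short-range speckle coherence, while its blur
  enlarges the resolution cell and thereby *raises* the relative
  along/across modulation. Reproducing the measured $R^2$/$FA$ direction
  evidently requires physics outside this generator's scope (clutter and
  reverberation floors, depth-dependent SNR, non-smooth aberration). The
  corresponding acceptance assertions are stated in the measured-data
  direction and left failing rather than weakened; treat them as a known
  limitation of the synthetic physics, not of the beamformer.

Numerical conventions throughout: angles are radians internally and degrees
at interfaces; lengths and times are SI; undefined quantities propagate as
flags, never as fabricated values; every random draw is seeded and every
container write is deterministic, so identical configurations reproduce
byte-identical artifacts.
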