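---
title: "panoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panoscan)
```

panoscan is a virtual instrument for economical stepper-driven pan-tilt
terrestrial LiDAR scanners. It covers the full computational stack of such a
device: planning a scan from motor and gearing parameters, tracking the
laser orientation by dead reckoning over commanded stepper movements,
reconstructing Cartesian point clouds from the raw per-pulse records
(including the off-axis mount correction), simulating whole scans of
synthetic forest scenes, and deriving the standard vegetation-structure
products (ground classification, DTM, height normalization, CHM, tree
heights). This vignette explains the models, the tunable parameters, and
the design choices, in that order.

## Scan kinematics

The instrument takes one distance measurement per pan microstep, so all
scan-plan figures follow from four quantities per axis: full motor steps
per revolution $S$ (200 for the NEMA 17 class), the microstepping
denominator $m \in \{1, 2, 4, 8, 16\}$ (A4988-class drivers), the output
gear ratio $G$ (3:1 belt drive on the pan axis, direct drive on tilt), and
the step interval $\tau$. The angular resolution of an axis is

$$\Delta\theta = \frac{360^\circ}{S \, m \, G},$$

the head performs $N_{rev} = S\,m_{pan}\,G_{pan}$ measurements per
revolution in time $N_{rev}\tau$, and a tilt sweep from $t_0$ to $t_1$
requires $\lceil (t_1 - t_0)/\Delta\theta_{tilt} \rceil$ revolutions. With
the reference settings ($m_{pan} = m_{tilt} = 1/4$, $\tau$ = 3.3 ms, sweep
$-40^\circ$ to $+90^\circ$) this gives 0.15° pan spacing, 2400 points per
7.92 s revolution, 289 revolutions, 693,600 points and a scan of about 38
minutes:

```{r}
unlist(scan_plan(default_scanner_config()))
```

Two numerical conventions matter here. First, the revolution count rounds
*up* (288.9 becomes 289): the sweep must be covered, and the final
revolution may overshoot the end tilt by less than one tilt step; exact
integer quotients are kept as-is. Second, the step interval is a free
parameter rather than being hard-wired to $1/f_{max}$: the 300 Hz sensor
cap is conventionally quoted as a 3.3 ms interval (its one-decimal
display), and the configuration validator accepts steps within half a
display unit of the exact bound so both the 3.3 ms literal and exact
$1/f$ values are usable.

## Orientation by dead reckoning

Stepper motors move in exact discrete increments, so the laser orientation
at any pulse is the initial orientation plus (signed integer step tally)
$\times$ (per-step resolution) — no inertial sensor, no drift. The package
computes schedule bearings in closed form from the step index rather than
by floating-point accumulation, and `backtrack()` reduces any recorded
step-event history the same way; the orientation is therefore independent
of the order of events, and a million-step schedule agrees with the
integer-tally path to better than $10^{-9}$ degrees (verified in the test
suite). Bearings live in $[0, 360)$ clockwise from north; tilt uses the
horizontal convention (zenith $+90^\circ$, horizon $0^\circ$, nadir
$-90^\circ$); the Cartesian frame is east-north-up. All interfaces use
degrees; radians appear only internally.

## Off-axis mount correction

The laser aperture sits off the pan axis (a weight-balancing choice in the
hardware), so the beam origin traces a circle as the head spins. With mount
offsets $(\ell, f, v)$ — lateral, forward, vertical in the head frame — and
trim angles $(\beta, \gamma)$ for residual software alignment, a record
$(b, t, d)$ maps to

$$p = R_z(b + \beta)\,(\ell, f, v)^T + d\,\hat u(b + \beta,\, t + \gamma),$$

where $R_z$ is the clockwise yaw rotation and $\hat u$ the beam unit
vector. With all offsets zero this reduces *exactly* (bit-identically) to
the plain spherical-to-Cartesian conversion. Offsets are per-unit
calibration values; the bundled device file ships zeros and documents that
real builds must measure their own.

## The scan simulator

`simulate_scan()` casts one ray per schedule entry from the offset-corrected
laser origin. Intersections are computed per scene primitive:

* **Terrain** — planar terrain uses the closed-form line-plane solution;
  undulating terrain (sum of Gaussian hills) is intersected by bounded ray
  marching (default coarse step 0.25 m, restricted to the parameter
  interval where the ray is inside the terrain elevation band) followed by
  bisection to below 0.1 mm. On planar terrain the marching path agrees
  with the closed form to under 1 mm (tested); the coarse step is safe for
  the broad hills the generator produces and is a parameter for sharper
  terrain.
* **Trunks** — finite vertical cylinders, closed form, opaque.
* **Crowns** — ellipsoids of revolution or downward-opening cones. A crown
  may be *opaque* (the ray returns from the surface; the default for
  `tree_primitive()`) or *porous*: foliage attenuates the ray along its
  chord with a Beer-Lambert law, $P(\text{pass}) = e^{-kL}$, and a
  registered return is drawn from the corresponding exponential depth.
  Porosity is the realistic regime — a solid opaque crown would make the
  tree apex strictly invisible to a ground scanner at shallow viewing
  angles, which is an artifact of over-idealized geometry rather than a
  property of real canopies. The draws use a counter-based hash RNG keyed
  on (seed, pulse index, tree index), so results are reproducible and
  independent of evaluation order.

The measurement error model applies a range-dependent Gaussian (the
datasheet accuracy figures read as 1-sigma values: 5 cm below 2 m, 2.5 cm
beyond) followed by quantization to the 1 cm distance resolution, rounding
half up. Pulses with no return within the 40 m range are dropped from the
raw record — the raw text format has no no-return convention — but a flag
retains them with a $-1$ sentinel for diagnostics, and hits plus misses
always equal the scheduled pulse count. Beam divergence (8 mrad) is *not*
mixed into returns; the footprint diameter is exposed as a pure helper for
reporting.

## The synthetic demonstration scene

`make_demo_scene()` emulates the structure of a small wooded plot with
irregular ground and no understorey: six broad Gaussian hills with net
amplitude under 1 m, and trees with ellipsoid crowns placed with a minimum
5 m spacing, a 4 m clearing at the plot center for the tripod, heights
uniform on 6-14 m, and near-isometric crown allometry (crown depth
0.35-0.5 of height, crown radius 0.15-0.22 of height, foliage extinction
0.7 m$^{-1}$). The ground-truth tree table rides along as an attribute.

What the generator does *not* emulate — and hence what passing tests do
not show about field data: branch and twig structure, understorey and
litter, wind motion between pulses, multiple returns per pulse, mixed
pixels from the 8 mrad footprint, registration error between scans (merges
assume known rigid transforms; the real workflow aligns scans in external
software), and GPS georeferencing. Field figures such as a specific
merged-cloud size or a tree-height error measured against a handheld
rangefinder depend on those realities and are not desk-reproducible;
the package instead demonstrates that the *chain* recovers known synthetic
truth.

## The product chain

`classify_ground()` is a deterministic grid-based filter, used here in
place of the cloth-simulation filter found in full LiDAR suites (that
algorithm belongs to an external package ecosystem; the product chain only
needs a dependable classifier to feed the DTM). It seeds a candidate
surface from per-cell minima (default 0.5 m cells), fills empty cells by
neighbor interpolation, erodes the surface under a slope constraint
(default 30°, i.e. neighboring cells may drop at most
$\tan(30^\circ) \times$ cell size) until convergence — which removes
minima resting on vegetation, e.g. cells that only ever saw crown returns —
and finally labels every point within the height tolerance (default
0.15 m) of the interpolated surface as ground. The tolerance covers the
sensor noise (2.5 cm, 1-sigma) plus the low bias of per-cell minima under
that noise. On simulated surveys the filter reaches recall and precision
above 0.99 against the simulator's per-pulse truth.

`build_dtm()` Delaunay-triangulates the ground points and linearly
interpolates each cell center on its containing triangle (cells outside
the hull are nodata). Two numerical choices: (1) inputs are jittered by a
deterministic sub-micron hash (±10⁻⁷ m) before triangulation to break the
cocircular degeneracies of gridded points — far below every stated
tolerance; (2) by default the input is thinned to the lowest point per
output cell first, which bounds the triangulation size on
multi-hundred-thousand-point clouds without changing the surface at the
raster scale (disable with `thin = FALSE`). TIN linearity is exact: any
globally linear surface is reproduced to 10⁻⁶ m at all in-hull cells.

`normalize_height()` subtracts the bilinearly interpolated DTM from every
point (nodata-aware, with a nearest-valid fallback at hull edges; points
outside the interpolated area are dropped and counted). `build_chm()`
keeps the highest point per cell, triangulates those apex points and
interpolates — so empty cells inside the canopy hull are filled. Pit-free
CHM variants are out of scope. `estimate_tree_heights()` reads the CHM
maximum within a search radius (default 2 m) of each known stem position;
automatic stem detection is deliberately not included, since the recovery
experiments have true positions. Height recovery on simulated surveys is
slightly negative (typically $-0.1$ to $-0.3$ m mean error): the highest
*sampled* return sits below the true apex by the angular sampling gap and
the foliage-penetration geometry — the same direction of bias reported for
field measurements of this class of scanner.

Default raster cells are 0.25 m for DTM/CHM and 0.5 m for the ground
filter; with point spacings of a few centimeters at 10 m range these are
comfortable, and both are parameters.

## Density over the scan sphere and the adaptive plan

A fixed pan microstepping puts the same number of points on every
revolution ring, but a ring at tilt $t$ subtends solid angle
$2\pi\left(\sin(t + \tfrac{\Delta}{2}) - \sin(t - \tfrac{\Delta}{2})\right)
\approx 2\pi \Delta \cos t$, so density grows as $1/\cos t$ toward zenith
and nadir. (Descriptions of this effect sometimes say "azimuth and nadir";
on the solid-angle argument the dense poles are zenith and nadir, and the
package documents it that way.) `density_profile()` reports exact per-band
counts and densities. `uniform_density_plan()` picks, per revolution, the
hardware denominator $m \in \{1,2,4,8,16\}$ (capped at the configured one)
whose ring count best matches $N_{horizon}\cos t$, ties resolved toward
the denser option. Over the reference sweep this cuts the density
coefficient of variation by roughly a factor of six and the scan time by
about a quarter, never adding a point to any ring. `scan_window()`
restricts the panorama to a bearing/tilt window, sweeping the bearing
window back and forth (steppers run equally well in both directions; the
turnaround is modeled as instantaneous) with per-step timing and spacing
unchanged; a window of $w$ degrees takes $w/\Delta\theta$ points per
revolution when divisible, else one more to cover the remainder, and
`bearing_min == bearing_max` means the full circle.

## Problem sizes and reproducibility

The simulated survey used by the tests and the acceptance script is four
scans on a 5 m × 5 m grid at 1/2 pan and 1/2 tilt microstepping (about
174,000 pulses per scan, ~250,000 merged returns) — dense enough that the
product-chain metrics are stable across seeds while a full run stays in
the tens of seconds. Every random element (terrain, trees, sensor noise,
foliage draws) descends from explicit integer seeds; repeating any
simulation with the same configuration and seed reproduces the output
byte-for-byte.

## Known limitations

Single-return, single-ray optics; no radiometry or intensity; no motor
dynamics (step-skipping under load is a hardware failure the planning
model assumes away); registration between scans must be supplied, not
estimated; the ground filter is a pragmatic substitute, not a cloth
simulation; LAS support is the minimal 1.2 / point-format-1 subset needed
for interchange (1 mm coordinate scale, GPS-time carrying the pulse time).
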