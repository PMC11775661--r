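---
title: "Simulating light availability in photobioreactors with pbrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating light availability in photobioreactors with pbrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsim)
```

## The problem

Illumination is one of the most energy-intensive aspects of cultivating
photosynthetic microalgae, and the hardest to measure inside a large vessel.
`pbrsim` estimates the spectral light field inside virtual cylindrical
photobioreactors so that designs -- an externally lit glass vessel versus a
steel vessel with internal rod lamps, at laboratory (10 l) through prototype
industrial scale (100 l, 1000 l) -- can be compared before anything is
built. The pipeline has four stages:

1. **Slab inversion** (`invert_spectrum`): recover per-waveband absorption
   and scattering coefficients of the suspension from measured (or
   emulated) reflectance/transmittance pairs, using a Monte Carlo model of
   a cuvette in an integrating-sphere configuration.
2. **Procedural geometry** (`glass_reactor_dims`, `steel_reactor_dims`,
   `build_cylinder_mesh`): construct reactors of matched working volume and
   matched lamp area from closed-form and root-solved dimension rules.
3. **Rendering** (`render_cube`): band-by-band volumetric path tracing of
   the scene into a hyperspectral cube (ENVI-serializable).
4. **Analysis** (`well_lit_fraction`, `region_mean_spectrum`,
   `decay_curve`, `false_colour`): the light-availability metrics.

## The medium model and its assumptions

The suspension is a homogeneous volume of absorbing and scattering
particles: per waveband it is described by an absorption coefficient
$\sigma_a$ (1/m), a scattering coefficient $\sigma_s$ (1/m), and a
Henyey--Greenstein (HG) phase function with a single global anisotropy $g$.
Free paths are exponential in $\sigma_t = \sigma_a + \sigma_s$; at each
collision a photon is absorbed with probability $\sigma_a/\sigma_t$ and
otherwise deflected by the HG inverse CDF. Microalgae scatter strongly
forward -- roughly 90% of scattered light stays within a 20 degree
half-angle cone -- and the default $g$ is **calibrated** from exactly that
property by solving $1 - F_{HG}(\cos 20^\circ; g) = 0.9$ with the
closed-form HG CDF (`hg_default_g()`, about 0.9593). It is computed at
first use, not hard-coded.

### The port-loss convention, deliberately kept

In the emulated integrating-sphere measurement, scattered light that
misses the sphere's ports is attributed to absorption. The slab simulation
replicates this bias on purpose: photons leaving the virtual cuvette
through its sides count as absorbed, not scattered. Inverted coefficients
therefore *overestimate* absorption, and downstream renders compensate by
diluting the medium with a density multiplier (default 1/4, configurable in
`render_settings`). This mirrors the measurement/simulation convention the
package emulates rather than "fixing" it; separating true scattering from
absorption would require a different measurement model and is out of scope.

## The inversion

Per band there are two unknowns ($\sigma_a d$, $\sigma_s d$, with the
cuvette path length $d$ = 10 mm) and two targets $(r, t)$, so the inversion
is well-posed with $g$ held fixed. The forward map is monotone:
$\hat t$ decreases in $\sigma_a d$ at fixed $\sigma_s d$, and $\hat r$
increases in $\sigma_s d$ once $\sigma_a d$ is matched to $t$. `invert_band`
exploits this with a nested bisection rather than a general optimizer: it is
derivative-free, robust to the Monte Carlo jitter of the objective (all
evaluations share one photon budget and seed -- common random numbers), and
needs no starting guess. With strongly forward scattering, small scattering
depths are nearly unobservable in $(\hat r, \hat t)$; when the target
reflectance is indistinguishable from zero the solver returns the
least-scattering medium consistent with the data. Reflectance targets above
the ceiling reachable at the fixed anisotropy (multiple forward scattering
cannot backscatter arbitrarily much) come back flagged `converged = FALSE`.

### The iterative surrogate

Optimizing every band is the slow path. `train_surrogate` replaces it with
a smooth regression surface over the $(r, t)$ plane, trained by a widening
iteration: targets are first confined to $|r - t| \le 0.25$ (the regime
where symmetric-guess training is known to work), then the admissible band
widens through 0.5 and 0.75 to 1.0, each iteration pruning every point
whose achieved simulation error in $r$ or $t$ exceeds 2% and refitting.
Later iterations use the current surface's prediction as a shortcut: if the
predicted coefficients already reproduce the target, the inversion is a
single forward check. Design choices the training scheme leaves open and
how this package resolved them:

* **Schedule** `0.25, 0.5, 0.75, 1.0` over four iterations; only the first
  and last bounds are externally prescribed, the interior steps are an even
  split.
* **Annulus-weighted sampling**: each widening iteration draws two thirds
  of its targets from the newly admitted $|r-t|$ annulus (where the surface
  is least constrained) and refreshes the remaining third over the full
  widened domain, so regions covered early -- notably the deep-absorption
  corner at small $|r-t|$ -- keep accumulating support.
* **Model family**: two thin-plate regression splines (`mgcv::gam`, REML)
  for $\log(\sigma_a d + \delta)$ and $\log(\sigma_s d + \delta)$ as
  functions of $(\log(r + 0.01), \log(t + 0.01))$. The log-compressed
  coordinates matter: the absorption depth behaves like $-\log t$, which is
  nearly linear in these coordinates, so a moderate spline basis
  (k up to 100) interpolates reliably even near the deep-absorption corner.
  Any smooth regressor with the same held-out fidelity would do; a small
  neural network is an acceptable substitute.
* **Fidelity envelope**: in the microalgae regime ($t \ge r$, low
  reflectance) predictions forward-simulate to within 5% of the target
  across the whole $|r - t|$ range. On the varying-$r$ side (reflectance
  far above transmittance) accuracy degrades beyond $|r-t| \approx 0.5$ --
  an inherited limitation of the target set: those targets are largely
  infeasible for a forward-scattering medium and are pruned during
  training.

## Synthetic data

The package is self-contained: `synth_chlorella_targets` emulates measured
*Chlorella vulgaris* spectra rather than shipping them.
Transmittance follows $t(\lambda) = (1 - r(\lambda))\,
e^{-c\,A(\lambda)}$, where $A$ is a fixed absorption template -- a flat
green baseline (0.08) plus Gaussian troughs at 460 nm (amplitude 1.30,
width 25 nm), 490 nm (0.50, 15 nm) and 675 nm (1.00, 12 nm) -- and
$c$ = density / 1.912e7 cells/ml scales linearly with cell density, so the
reference validation-culture density corresponds to $c = 1$. Reflectance is
a low, slowly varying curve, at most 0.075, declining with density.
Consequences, all tested: dilute through dense cultures transmit at least
60% in the green (500--650 nm); the blue trough deepens faster than the red
with increasing density; $r + t \le 1$ holds per band by construction
(writing $t \propto (1-r)$ resolves the corner case at density zero, where
a fractional reflectance plus unit transmittance would otherwise break
energy conservation). `synth_growlight_spectrum` emulates a dual-peak
horticultural LED: a narrow blue lobe peaking at 450 nm (width 20 nm) above
a broader red lobe at 640 nm (width 45 nm), blue peak higher than red.

What the generator does *not* emulate: instrument noise and response,
Fresnel interactions of the cuvette walls, NIR bands, and the
density-dependent fine structure of real pigment spectra. Tests passing on
synthetic targets therefore validate the inversion and rendering machinery,
not the biology of any particular culture.

## Geometry

The reactor aspect ratio is locked to $h = 2r$, so a glass vessel satisfies
$V = 2\pi r^3$ and $r = (V/2\pi)^{1/3}$ in closed form; its whole lateral
wall ($A_l = 4\pi r^2$) is the light sheet. The steel vessel embeds $n$
full-height rod lamps whose total lateral area must equal $A_l$ while the
suspension (working) volume must still equal $V$ -- enlarging the vessel to
make room for the rods also lengthens the rods, so the system is coupled.
Eliminating the rod radius $r_l = A_l/(4\pi n r)$ reduces it to
$2\pi r^3 - A_l^2/(8\pi n r) = V$, which has a unique positive root
(bracketed `uniroot`; re-substitution reproduces the working volume and
lamp area to machine precision, and the package's unit tests pin the
solved dimensions for 10/100/1000 l at the reference precision).

Rod lamps are placed on one ring at the equal-area radius $r/\sqrt{2}$ --
the circle splitting the cross-section into equal inner and outer areas,
so neither the core nor the wall annulus is left far from a lamp (a ring
at $r/2$ leaves a wide dark annulus along the wall at the 100 l scale) --
when adjacent centres clear one lamp diameter, otherwise split across
equal-area rings at $\sqrt{1/3}\,r$ and $\sqrt{2/3}\,r$; single lamps sit
on the axis. Meshes for export (`OBJ`/`PLY`) are generated
procedurally with shared rim vertices, smooth lateral vertex normals (flat
shading of curved surfaces is a classic source of specular artefacts) and
watertight caps.

## Rendering

`render_cube` performs backward path tracing from a pinhole camera with
next-event estimation toward the emitter surfaces, one greyscale image per
band, stacked into a hyperspectral cube. Numerical choices:

* **Analytic primitives.** The renderer intersects analytic cylinders,
  discs and rectangles-with-aperture rather than triangle meshes -- exact
  silhouettes, no BVH, and tractable desk-scale runtimes in an R package;
  the mesh generator serves export and validation. The scene model does not
  preclude other shapes (flat panels are rectangles).
* **Materials.** Lamp: diffuse (optionally cone-restricted) emitter, scaled
  by the light spectrum and the per-area power. Steel: glossy with flat
  reflectance 0.6 (configurable; no value is externally prescribed), split
  evenly between a mirror lobe and a diffuse lobe -- rough industrial
  steel is not a mirror, and the diffuse lobe is what lets the wall
  redistribute rod light and even out the field (it is also what
  next-event estimation can sample). Glass: thin dielectric, refractive
  index 1.5, exact Fresnel reflect-or-pass. Matte black (albedo 0)
  absorbs.
* **Glass reactor light sheet.** The wall itself is the inward-emitting
  cylindrical sheet (LEDs pressed against the wall); the suspension column
  is inset by a 2 mm wall thickness, which also keeps next-event
  connections from degenerating at zero distance.
* **Termination.** Russian roulette from bounce 8, max 64 bounces;
  per-(band, pixel, sample) random streams are derived from the master
  seed with a counter-based hash, so cubes are bitwise reproducible and
  adding bands never reshuffles other bands' noise.
* **Desk scale.** Default 128 x 128 px at 200 rays/pixel; the full-scale
  512 x 512 at 5000 rays/pixel of a GPU production run is a configuration,
  not the default. The test suite renders two-band 100 l reactor pairs and
  a three-band dense glass reactor at desk scale.
* **Units and exposure.** Radiometric units are arbitrary-linear (the
  emulated imager is uncalibrated). `expose_cubes` meters a set of cubes
  the way a photographer meters a subject: one common linear factor maps
  the median of the suspension-surface pixels (pooled over the cubes and
  bands being compared) to mid-grey, 18% of a 10000-count full scale. The
  suspension is then "sufficiently illuminated" while the near-lamp
  highlights -- whose next-event-estimation values are singular and would
  otherwise dictate the scale -- are allowed to overexpose, a deliberately
  small number of pixels. The well-lit threshold of 1000 counts sits just
  below mid-grey. Orderings between commonly exposed cubes are invariant
  to the factor, which is why comparative claims (steel at or above glass
  at matched volume, density and per-area power) are asserted as
  orderings, never as absolute percentages.
* **Macro pixels for area metrics.** The upward radiance of a deep,
  forward-scattering suspension is estimated from rare turning events, so
  individual pixel estimates are heavy-tailed at desk-scale sample counts.
  `downsample_cube`/`downsample_mask` aggregate 4 x 4 blocks before
  thresholding, pooling ~20k samples per macro pixel so that the well-lit
  fraction responds to the light level rather than to sampling spikes; the
  comparison fixtures render 64 x 64 at 1200 rays/pixel for the same
  reason.

## Validation scene

`build_validation_scene` is the digital-twin counterpart of a desk
experiment: an open-top cylinder of suspension (thin-walled bottle) inside
a matte-black box, a spot lamp outside shining through one aperture onto
the suspension surface, the camera imaging through a second aperture
(512 x 512 px, 31 degree field of view by default). With the apertures
closed the render is identically zero -- a structural light-tightness test.

## Known limitations

* Scattering misattributed to absorption (the port-loss convention) makes
  green-band attenuation too strong; the density multiplier compensates
  globally, not per band. Blue/red channels -- the photosynthetically
  decisive ones -- are the reliable outputs.
* The medium is homogeneous; no flow, growth kinetics, heat, or biofilm.
* One medium region per scene; nested or heterogeneous media are out of
  scope.
* Absolute radiometry is undefined; only relative and ordering statements
  are meaningful.

## Problem sizes used by the test suite

Unit and acceptance tests run the full algorithms at reduced scale, chosen
as the smallest sizes at which every claim is still a strict test of the
mechanism: slab checks at 2e4--5e4 photons against a 10x-photon independent
R oracle; surrogate training at 120 targets per iteration and 6000 photons
per evaluation; the 31-band inversion at 2e4 photons per evaluation;
renders at 128 x 128 px and 200 rays per pixel on two- and three-band
grids. The printed dimension tables are pinned exactly (they are
closed-form or one-dimensional root finds and cost milliseconds).
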