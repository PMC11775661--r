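# pbrsim

Light availability is the limiting, and most energy-expensive, resource in
microalgae cultivation, and it is nearly impossible to measure throughout a
large vessel. `pbrsim` simulates the spectral light field inside virtual
cylindrical photobioreactors so that designs can be compared before they are
built: an externally lit glass vessel against a steel vessel with internal
rod lamps, from a 10-litre bench unit to 100 and 1000-litre prototypes.

The package covers the full pipeline:

* **Inverse optics.** Per-waveband absorption and scattering coefficients
  (σ<sub>a</sub>, σ<sub>s</sub>, 1/m) of a suspension are recovered from
  reflectance/transmittance pairs (r, t) by fitting a Monte Carlo *slab*
  model of a 10 mm cuvette in an integrating-sphere configuration, with a
  Henyey–Greenstein phase function whose anisotropy g ≈ 0.959 is calibrated
  from the forward-scattering property of microalgae (90% of scattered
  light within a 20° cone). An iteratively trained smooth surrogate
  (widening |r − t| schedule 0.25 → 1.0, 2% pruning) replaces the per-band
  search with a function evaluation.
* **Procedural geometry.** With the aspect ratio locked to h = 2r, a glass
  vessel obeys V = 2πr³, so r = (V/2π)^(1/3) and its wall doubles as the
  lamp sheet (A<sub>l</sub> = 4πr²). The matched steel vessel solves the
  coupled working-volume / lamp-area system
  2πr³ − A<sub>l</sub>²/(8πnr) = V for the vessel radius and
  r<sub>l</sub> = A<sub>l</sub>/(4πnr) for the rod-lamp radius.
* **Rendering.** A band-wise volumetric path tracer (Rcpp) with next-event
  estimation renders each waveband to a greyscale image and stacks them
  into an ENVI-serializable hyperspectral cube; renders are bitwise
  reproducible from a master seed.
* **Analysis.** False-colour blue/red composites, region mean spectra,
  upward-scatter decay curves, and the well-lit pixel percentage over the
  suspension-surface mask.

Synthetic generators (`synth_chlorella_targets`, `synth_growlight_spectrum`)
emulate dense *Chlorella vulgaris* target spectra and a dual-peak (450 nm /
640 nm) grow light, so the whole pipeline runs without external data.

## Worked example

```r
library(pbrsim)

# 1. a 31-band PAR grid and a synthetic dense culture (1.9e7 cells/ml)
grid   <- band_grid(400, 700, 10)
target <- synth_chlorella_targets(grid, 1.912e7)

# 2. invert the suspension optics band by band
fit <- invert_spectrum(target, n_photons = 20000, seed = 19,
                       density_multiplier = 0.25)
fit
#> <slab_fit> 400-700/10 nm, 31 bands (optimize)
#>   RMSE: reflectance 0.0022, transmittance 0.0047; 31/31 bands converged

# 3. matched 100 l reactors: same working volume, same lamp area
glass <- glass_reactor_dims(0.1)
glass
#> <glass reactor> volume 100 l: radius 25.15 cm, height 50.31 cm, lamp area 0.7951 m^2
steel <- steel_reactor_dims(0.1, n_lamps = 12, lamp_area = glass$lamp_area)
steel
#> <steel reactor> volume 100 l: radius 25.82 cm, height 51.63 cm, 12 lamps of radius 2.04 cm, lamp area 0.7951 m^2

# 4. render the steel reactor on the 450/640 nm channels and score it
med  <- fit$medium
keep <- match(c(450, 640), med$grid$wavelengths)
med2 <- medium_spectrum(band_grid(450, 640, 190), med$sigma_a[keep],
                        med$sigma_s[keep], med$g, med$density_multiplier)
light <- synth_growlight_spectrum(med2$grid)
scene <- build_reactor_scene(steel, med2, light, power_per_area = 10)
scene$camera$width <- scene$camera$height <- 64L
cube  <- render_cube(scene, render_settings(rays_per_pixel = 1200, seed = 1))
mask  <- render_surface_mask(scene)
agg   <- downsample_cube(cube, 4)          # 4x4 macro pixels
aggm  <- downsample_mask(mask, 4)
ex    <- expose_cubes(list(agg), masks = list(aggm))[[1]]
well_lit_fraction(ex, 450, aggm, threshold = 1000)
#> [1] 25.71429
well_lit_fraction(ex, 640, aggm, threshold = 1000)
#> [1] 88.57143
```

The fit RMSEs say the virtual suspension reproduces the target spectra to
well under 1% per band; the reactor printouts are the closed-form and
root-solved dimensions (radius, height, rod radius) at matched lamp area.
The final numbers are the percentage of suspension-surface macro pixels
whose intensity exceeds 1000 counts after metering the suspension to
mid-grey on a 10000-count scale: most of the surface receives red light,
while the strongly absorbed blue reaches only about a quarter of it even
with the lamps inside the vessel. Rendering the matched glass reactor the
same way and exposing both cubes together ranks the steel design at or
above the glass design on both channels — the central comparison the
simulator exists to make (the test suite asserts it on a dense culture).

A YAML-driven command-line front-end wrapping the same pipeline
(`invert`, `design`, `render`, `analyze`, `selftest`) ships in
`inst/scripts/pbrsim.R`.

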