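Package: pbrsim
Title: Procedural Photobioreactor Design and Hyperspectral Light-Propagation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing photobioreactor designs by simulated light
    availability. Per-waveband absorption and scattering properties of a
    microalgae suspension are inverted from reflectance-transmittance target
    spectra with a Monte Carlo slab model (optionally accelerated by an
    iteratively trained surrogate), glass and steel cylinder reactors are
    built procedurally at matched working volume and lamp area, scenes are
    rendered band-by-band with a volumetric path tracer into hyperspectral
    cubes (ENVI-serializable), and light-availability metrics such as the
    well-lit pixel fraction, region mean spectra and upward-scatter decay
    curves are computed from the cubes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
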