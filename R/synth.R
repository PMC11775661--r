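#' Reflectance/transmittance target pair
#'
#' Couples a reflectance and a transmittance spectrum measured (or emulated)
#' on the same band grid. These pairs are the inputs to the slab inversion.
#' Per band, `r + t <= 1` is enforced (energy conservation of a passive
#' sample).
#'
#' @param reflectance,transmittance fractional [spectrum()] objects on the
#'   same grid.
#' @param cell_density optional suspension density in cells/ml (metadata).
#' @return An object of class `target_spectrum`.
#' @export
target_spectrum <- function(reflectance, transmittance, cell_density = NA_real_) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(transmittance, "spectrum"))
  if (!same_grid(reflectance$grid, transmittance$grid))
    stop("reflectance and transmittance must share one band grid")
  r <- reflectance$values; t <- transmittance$values
  if (any(r < -1e-12) || any(r > 1 + 1e-12) || any(t < -1e-12) || any(t > 1 + 1e-12))
    stop("reflectance and transmittance must be fractions in [0, 1]")
  if (any(r + t > 1 + 1e-9))
    stop("per band, reflectance + transmittance must not exceed 1")
  structure(list(grid = reflectance$grid,
                 reflectance = reflectance,
                 transmittance = transmittance,
                 cell_density = cell_density),
            class = "target_spectrum")
}

#' @export
print.target_spectrum <- function(x, ...) {
  cat(sprintf("<target_spectrum> %s%s\n  t in [%.3f, %.3f], r in [%.3f, %.3f]\n",
              format(x$grid),
              if (is.finite(x$cell_density))
                sprintf(", %.3g cells/ml", x$cell_density) else "",
              min(x$transmittance$values), max(x$transmittance$values),
              min(x$reflectance$values), max(x$reflectance$values)))
  invisible(x)
}

# Reference density: the culture used for the validation-style configuration
# (1.912e7 cells/ml); the decadal absorption template below is scaled so that
# this density corresponds to unit optical depth scale c = 1.
.chlorella_ref_density <- 1.912e7

# Absorption template A(lambda): flat green baseline plus Gaussian troughs for
# the chlorophyll/carotenoid features in the blue (440-500 nm) and the red
# (675 nm). Chosen once to emulate the qualitative shape of dense Chlorella
# vulgaris suspensions: strong blue and red absorption, >= 60% transmission in
# the green at all densities considered.
chlorella_absorption_template <- function(wavelengths) {
  0.08 +
    1.30 * exp(-(wavelengths - 460)^2 / (2 * 25^2)) +
    0.50 * exp(-(wavelengths - 490)^2 / (2 * 15^2)) +
    1.00 * exp(-(wavelengths - 675)^2 / (2 * 12^2))
}

#' Synthetic Chlorella-like reflectance/transmittance targets
#'
#' Deterministic parametric emulation of integrating-sphere measurements of a
#' *Chlorella vulgaris* suspension: transmittance follows
#' `t = (1 - r) * exp(-c * A(lambda))` where `A` is a fixed absorption
#' template with troughs centred at 460, 490 and 675 nm and
#' `c = cell_density / 1.912e7` scales linearly with density; reflectance is
#' a low (<= 0.1), slowly varying curve that decreases with density. At every
#' band `r + t <= 1` by construction, transmittance is monotonically
#' non-increasing in density, and in the green (500--650 nm) at least 60% of
#' light is transmitted for all densities up to ~8e7 cells/ml.
#'
#' @param grid a [band_grid()].
#' @param cell_density suspension density in cells/ml (>= 0).
#' @return A [target_spectrum()].
#' @export
synth_chlorella_targets <- function(grid, cell_density) {
  stopifnot(inherits(grid, "band_grid"))
  if (!is.numeric(cell_density) || length(cell_density) != 1 || cell_density < 0)
    stop("cell_density must be a single nonnegative number")
  wl <- grid$wavelengths
  c_scale <- cell_density / .chlorella_ref_density
  A <- chlorella_absorption_template(wl)
  # low, slowly varying reflectance, decreasing with density; tilted slightly
  # downward toward the red as in measured suspensions
  r0 <- 0.075 - 0.015 * (wl - 400) / 300
  r <- r0 / (1 + cell_density / 6e7)
  t <- (1 - r) * exp(-c_scale * A)
  target_spectrum(spectrum(grid, r, fractional = TRUE),
                  spectrum(grid, t, fractional = TRUE),
                  cell_density = cell_density)
}

#' Synthetic dual-peak grow-light emission spectrum
#'
#' Emulates a horticultural LED grow light with maximum emission in the blue
#' at 450 nm and a broader, slightly lower red lobe peaking at 640 nm.
#' Values are relative radiance in arbitrary units.
#'
#' @param grid a [band_grid()] covering 400--700 nm.
#' @return An object of class `light_spectrum` with elements `grid`,
#'   `relative_power` and `peak_wavelengths`.
#' @export
synth_growlight_spectrum <- function(grid) {
  stopifnot(inherits(grid, "band_grid"))
  wl <- grid$wavelengths
  if (min(wl) > 450 || max(wl) < 640)
    stop("grid must cover the 450 and 640 nm emission peaks")
  p <- 1.00 * exp(-(wl - 450)^2 / (2 * 20^2)) +
       0.80 * exp(-(wl - 640)^2 / (2 * 45^2)) +
       0.02
  light_spectrum(grid, p, peak_wavelengths = c(450, 640))
}

#' Light emission spectrum
#'
#' @param grid a [band_grid()].
#' @param relative_power nonnegative relative radiance per band, at least one
#'   strictly positive value.
#' @param peak_wavelengths nominal emission peaks in nm (metadata; checked to
#'   be local maxima of `relative_power`).
#' @return An object of class `light_spectrum`.
#' @export
light_spectrum <- function(grid, relative_power, peak_wavelengths = numeric()) {
  stopifnot(inherits(grid, "band_grid"))
  p <- as.numeric(relative_power)
  if (length(p) != length(grid$wavelengths))
    stop("one relative_power value per band required")
  if (any(!is.finite(p)) || any(p < 0)) stop("relative_power must be finite and >= 0")
  if (!any(p > 0)) stop("at least one band must have positive power")
  for (pk in peak_wavelengths) {
    i <- which.min(abs(grid$wavelengths - pk))
    # a peak must dominate its immediate neighbourhood; on coarse grids a
    # neighbouring band can belong to a different peak, so only bands
    # within 30 nm count as neighbourhood
    nb <- which(abs(grid$wavelengths - grid$wavelengths[i]) <= 30)
    if (p[i] < max(p[nb]) - 1e-12)
      stop("declared peak at ", pk, " nm is not a local maximum")
  }
  structure(list(grid = grid, relative_power = p,
                 peak_wavelengths = peak_wavelengths),
            class = "light_spectrum")
}

#' @export
print.light_spectrum <- function(x, ...) {
  cat(sprintf("<light_spectrum> %s, peaks at %s nm\n", format(x$grid),
              paste(x$peak_wavelengths, collapse = ", ")))
  invisible(x)
}
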