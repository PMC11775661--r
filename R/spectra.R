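#' Uniform band grid
#'
#' Constructs the wavelength axis used throughout the package: an inclusive,
#' uniformly spaced grid of band centres in nanometres. The reference
#' configuration for photosynthetically active radiation is 400--700 nm at
#' 10 nm resolution, giving 31 bands.
#'
#' @param start_nm,end_nm first and last band centre in nm (inclusive).
#' @param step_nm band spacing in nm; `(end_nm - start_nm)` must be an
#'   integer multiple of it.
#' @return An object of class `band_grid` with elements `wavelengths` and
#'   `step`.
#' @examples
#' band_grid(400, 700, 10)   # 31 bands
#' @export
band_grid <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (start_nm <= 0) stop("band centres must be positive wavelengths")
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (end_nm < start_nm) stop("end_nm must be >= start_nm")
  k <- (end_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-9)
    stop("(end_nm - start_nm) is not divisible by step_nm")
  wl <- start_nm + step_nm * seq.int(0L, round(k))
  structure(list(wavelengths = wl, step = step_nm), class = "band_grid")
}

#' @export
length.band_grid <- function(x) length(x$wavelengths)

#' @export
print.band_grid <- function(x, ...) {
  n <- length(x$wavelengths)
  cat(sprintf("<band_grid> %d bands, %g-%g nm, step %g nm\n",
              n, x$wavelengths[1], x$wavelengths[n], x$step))
  invisible(x)
}

#' @export
format.band_grid <- function(x, ...) {
  sprintf("%g-%g/%g nm", x$wavelengths[1],
          x$wavelengths[length(x$wavelengths)], x$step)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    max(abs(a$wavelengths - b$wavelengths)) < 1e-9
}

#' Per-band spectrum
#'
#' A spectrum is a vector of nonnegative values attached to a [band_grid()].
#' Fractional spectra (reflectance, transmittance) must lie in \[0, 1\].
#'
#' @param grid a [band_grid()].
#' @param values numeric, one nonnegative value per band.
#' @param fractional if `TRUE`, additionally require values in \[0, 1\].
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(grid, values, fractional = FALSE) {
  stopifnot(inherits(grid, "band_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid$wavelengths))
    stop("length(values) must equal the number of bands")
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrum values must be finite and nonnegative")
  if (fractional && any(values > 1 + 1e-12))
    stop("fractional spectrum values must lie in [0, 1]")
  structure(list(grid = grid, values = values, fractional = isTRUE(fractional)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, range [%.4g, %.4g]\n", format(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = "value",
                          type = "l") {
  graphics::plot(x$grid$wavelengths, x$values, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Gaussian smoothing of a spectrum
#'
#' Discrete Gaussian convolution along the band axis with reflecting
#' boundaries, used to suppress band-to-band measurement noise before
#' inversion. `sigma_bands` is expressed in band widths; `sigma_bands = 0`
#' is the identity.
#'
#' @param s a [spectrum()].
#' @param sigma_bands Gaussian standard deviation in units of bands (>= 0).
#' @return A smoothed `spectrum` on the same grid.
#' @export
smooth_spectrum <- function(s, sigma_bands) {
  stopifnot(inherits(s, "spectrum"))
  if (!is.numeric(sigma_bands) || length(sigma_bands) != 1 || sigma_bands < 0)
    stop("sigma_bands must be a single nonnegative number")
  if (sigma_bands == 0) return(s)
  v <- s$values
  n <- length(v)
  half <- max(1L, ceiling(4 * sigma_bands))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_bands^2))
  k <- k / sum(k)
  # symmetric reflection with edge repeat: ...cba|abc...xyz|zyx...
  fold <- function(i) {
    j <- ((i - 1) %% (2L * n) + 2L * n) %% (2L * n)  # 0 .. 2n-1
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  padded <- v[fold(seq.int(1L - half, n + half))]
  out <- as.numeric(stats::filter(padded, k, sides = 2))
  out <- out[(half + 1):(half + n)]
  spectrum(s$grid, pmax(out, 0), fractional = s$fractional)
}

#' Resample a spectrum onto a new grid by cubic interpolation
#'
#' Cubic-spline interpolation within the support of the original grid; no
#' extrapolation is performed (the request is rejected instead, because
#' cubic splines diverge outside their support).
#'
#' @param s a [spectrum()].
#' @param new_grid a [band_grid()] contained in the support of `s$grid`.
#' @return A `spectrum` on `new_grid`.
#' @export
resample_spectrum <- function(s, new_grid) {
  stopifnot(inherits(s, "spectrum"), inherits(new_grid, "band_grid"))
  wl <- s$grid$wavelengths
  nw <- new_grid$wavelengths
  if (min(nw) < min(wl) - 1e-9 || max(nw) > max(wl) + 1e-9)
    stop("resample_spectrum: new grid extends outside the original support (no extrapolation)")
  if (length(wl) < 4) {
    vals <- stats::approx(wl, s$values, xout = nw)$y
  } else {
    vals <- stats::spline(wl, s$values, xout = nw, method = "fmm")$y
  }
  spectrum(new_grid, pmax(vals, 0), fractional = s$fractional)
}

#' Read / write a spectrum as two-column CSV
#'
#' The on-disk format is `wavelength_nm,value` with a header line, matching
#' common spectrophotometer exports.
#'
#' @param s a [spectrum()].
#' @param path file path.
#' @param fractional passed to [spectrum()] when reading.
#' @return `read_spectrum_csv` returns a `spectrum`; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = s$grid$wavelengths,
                              value = s$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, fractional = FALSE) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns: wavelength_nm, value")
  wl <- as.numeric(d[[1]])
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6)
    stop("spectrum CSV must be on a uniform wavelength grid")
  g <- band_grid(wl[1], wl[length(wl)], steps[1])
  spectrum(g, as.numeric(d[[2]]), fractional = fractional)
}
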