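#' Rectangular region of interest
#'
#' 0-based, row-major, half-open pixel rectangle: rows
#' `row0 .. row0 + height - 1`, columns `col0 .. col0 + width - 1`.
#'
#' @param row0,col0 top-left corner (0-based).
#' @param height,width extent in pixels (>= 1).
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  stopifnot(row0 >= 0, col0 >= 0, height >= 1, width >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_rows <- function(r) (r$row0 + 1):(r$row0 + r$height)
roi_cols <- function(r) (r$col0 + 1):(r$col0 + r$width)

check_roi <- function(r, cube) {
  d <- dim(cube$values)
  if (r$row0 + r$height > d[1] || r$col0 + r$width > d[2])
    stop("roi extends outside the image")
  invisible(r)
}

#' False-colour composite of a cube
#'
#' Photosynthesis-oriented composite: the blue channel shows the band
#' nearest `blue_nm`, the red channel the band nearest `red_nm`, and the
#' green channel is identically zero (green light penetrates far but is
#' photosynthetically uninteresting, so showing it would flatter the light
#' field). Both channels are scaled by one shared display maximum.
#'
#' @param cube a [hypercube()].
#' @param blue_nm,red_nm channel wavelengths (defaults 450 and 640 nm).
#' @return `rows x cols x 3` RGB array in \[0, 1\].
#' @export
false_colour <- function(cube, blue_nm = 450, red_nm = 640) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$grid$wavelengths
  if (blue_nm < min(wl) - cube$grid$step / 2 ||
      red_nm > max(wl) + cube$grid$step / 2)
    stop("cube does not cover the requested wavelengths")
  blue <- cube_band(cube, blue_nm)
  red <- cube_band(cube, red_nm)
  mx <- max(red, blue)
  if (mx == 0) mx <- 1
  out <- array(0, dim = c(dim(blue), 3))
  out[, , 1] <- red / mx
  out[, , 3] <- blue / mx
  out
}

#' Write an RGB array as PNG
#' @param rgb `rows x cols x 3` array in \[0, 1\].
#' @param path output path.
#' @export
write_composite_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Mean spectrum over a region of interest
#'
#' Arithmetic mean and population standard deviation (divide by N) of the
#' cube values over the region, per band.
#'
#' @param cube a [hypercube()].
#' @param region a [roi()].
#' @return Data frame with `wavelength`, `mean`, `sd`.
#' @export
region_mean_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "hypercube"), inherits(region, "roi"))
  check_roi(region, cube)
  sub <- cube$values[roi_rows(region), roi_cols(region), , drop = FALSE]
  n <- prod(dim(sub)[1:2])
  m <- apply(sub, 3, mean)
  s <- sqrt(apply(sub, 3, function(x) mean((x - mean(x))^2)))
  data.frame(wavelength = cube$grid$wavelengths, mean = m, sd = s)
}

#' Upward-scatter decay curve
#'
#' Collapses a region of interest to a one-dimensional intensity profile:
#' the mean across the region's width per step along `axis`, ordered from
#' the bright edge (determined on the reference band), and normalized so
#' that the brightest single pixel of the *reference* band inside the region
#' equals unity. The curve is therefore invariant under uniform rescaling of
#' the cube, and the reference band's own curve never exceeds 1 at its
#' brightest pixel's row only when averaging; its maximum pixel maps to
#' exactly 1 in the normalization constant.
#'
#' @param cube a [hypercube()].
#' @param band_nm band to profile.
#' @param region a [roi()].
#' @param axis `"rows"` (profile runs along rows, averaging across columns)
#'   or `"cols"`.
#' @param reference_band_nm normalization band (default 640 nm).
#' @return An object of class `decay_curve`: data frame `distance_px`,
#'   `intensity`, with attributes `band_nm` and `normalization`.
#' @export
decay_curve <- function(cube, band_nm, region, axis = c("rows", "cols"),
                        reference_band_nm = 640) {
  stopifnot(inherits(cube, "hypercube"), inherits(region, "roi"))
  axis <- match.arg(axis)
  check_roi(region, cube)
  img <- cube_band(cube, band_nm)[roi_rows(region), roi_cols(region),
                                  drop = FALSE]
  ref <- cube_band(cube, reference_band_nm)[roi_rows(region),
                                            roi_cols(region), drop = FALSE]
  norm_const <- max(ref)
  if (norm_const <= 0) stop("reference band is zero in the region: cannot normalize")
  if (axis == "cols") { img <- t(img); ref <- t(ref) }
  prof <- rowMeans(img)
  ref_prof <- rowMeans(ref)
  # order from the bright edge of the reference profile
  if (which.max(ref_prof) > length(ref_prof) / 2) {
    prof <- rev(prof)
  }
  out <- data.frame(distance_px = seq_along(prof) - 1L,
                    intensity = prof / norm_const)
  structure(out, band_nm = band_nm, normalization = norm_const,
            reference_band_nm = reference_band_nm,
            class = c("decay_curve", class(out)))
}

#' @export
plot.decay_curve <- function(x, ..., log = "y") {
  graphics::plot(x$distance_px, pmax(x$intensity, 1e-12), type = "l",
                 log = log, xlab = "distance (px)",
                 ylab = "normalized intensity", ...)
  invisible(x)
}

#' Well-lit pixel percentage
#'
#' The light-availability metric: percentage of masked pixels whose value on
#' the selected band exceeds the threshold (strictly), the mask typically
#' being the suspension-surface mask of [render_surface_mask()].
#'
#' @param cube a [hypercube()].
#' @param band_nm band to evaluate.
#' @param mask 0/1 matrix of the cube's image size with at least one pixel
#'   set.
#' @param threshold intensity threshold (default 1000 counts).
#' @return Percentage in \[0, 100\].
#' @export
well_lit_fraction <- function(cube, band_nm, mask, threshold = 1000) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  if (!all(dim(mask) == d[1:2])) stop("mask size does not match the cube")
  sel <- mask > 0
  if (!any(sel)) stop("empty mask")
  img <- cube_band(cube, band_nm)
  100 * sum(img[sel] > threshold) / sum(sel)
}

#' Common exposure scaling for comparable cubes
#'
#' Meters the cube set like a photographer meters a subject: one shared
#' linear factor maps the median of the suspension pixels (all cubes and
#' bands pooled; `masks` select the suspension, otherwise every pixel
#' counts) to mid-grey, `grey_fraction` of `full_scale` (default 18% of a
#' 10000-count scale). The subject is then "sufficiently illuminated" while
#' only the few pixels adjacent to the lamps overexpose; anchoring on the
#' median rather than the maximum keeps the scale independent of the
#' near-lamp singular highlights. Because the factor is common, orderings
#' and ratios between the cubes are unchanged.
#'
#' @param cubes list of [hypercube()] objects.
#' @param masks optional list of 0/1 matrices (one per cube) selecting the
#'   pixels to meter on.
#' @param full_scale sensor full scale in counts.
#' @param grey_fraction fraction of full scale the metered median maps to.
#' @return List of rescaled cubes, with the factor stored in each cube's
#'   metadata as `exposure_factor`.
#' @export
expose_cubes <- function(cubes, masks = NULL, full_scale = 10000,
                         grey_fraction = 0.18) {
  stopifnot(length(cubes) >= 1, all(vapply(cubes, inherits, TRUE, "hypercube")))
  if (!is.null(masks)) stopifnot(length(masks) == length(cubes))
  vals <- unlist(lapply(seq_along(cubes), function(i) {
    v <- cubes[[i]]$values
    if (is.null(masks)) as.numeric(v) else {
      sel <- masks[[i]] > 0
      as.numeric(apply(v, 3, function(img) img[sel]))
    }
  }))
  med <- stats::median(vals)
  if (med <= 0) stop("metered median is zero: nothing to expose")
  f <- grey_fraction * full_scale / med
  lapply(cubes, function(cb) {
    cb$values <- cb$values * f
    cb$metadata$exposure_factor <- f
    cb
  })
}

#' Macro-pixel aggregation of a cube or mask
#'
#' Block-averages each band image over `factor` x `factor` pixel blocks.
#' Monte Carlo estimates of dim, multiply-scattered radiance are
#' heavy-tailed per pixel; averaging blocks pools their samples so that
#' thresholded area metrics respond to the underlying light level instead
#' of to sampling spikes. `downsample_mask` marks a macro-pixel as inside
#' when more than half of its pixels are.
#'
#' @param cube a [hypercube()].
#' @param factor block edge length in pixels (image size must be divisible).
#' @return A smaller `hypercube` (or 0/1 matrix for `downsample_mask`).
#' @export
downsample_cube <- function(cube, factor) {
  stopifnot(inherits(cube, "hypercube"), factor >= 1)
  d <- dim(cube$values)
  if (d[1] %% factor || d[2] %% factor)
    stop("image size is not divisible by the aggregation factor")
  out <- array(0, dim = c(d[1] / factor, d[2] / factor, d[3]))
  for (b in seq_len(d[3])) out[, , b] <- block_mean(cube$values[, , b], factor)
  hypercube(out, cube$grid, metadata = c(cube$metadata,
                                         list(aggregated = factor)))
}

#' @rdname downsample_cube
#' @param mask 0/1 matrix.
#' @export
downsample_mask <- function(mask, factor) {
  (block_mean(mask + 0, factor) > 0.5) + 0L
}

block_mean <- function(m, k) {
  k <- as.integer(k)
  if (k == 1L) return(m)
  n <- nrow(m) %/% k; p <- ncol(m) %/% k
  out <- matrix(0, n, p)
  for (a in seq_len(k))
    for (b in seq_len(k))
      out <- out + m[seq(a, n * k, k), seq(b, p * k, k)]
  out / k^2
}
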