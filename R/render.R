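#' Render settings
#'
#' Desk-scale defaults (128 x 128 px via the scene camera, 200 rays per
#' pixel) keep renders tractable on one CPU; the full-scale configuration of
#' 512 x 512 px and 5000 rays per pixel is a preset, not the default. The
#' density multiplier dilutes the inverted suspension at render time
#' (default 1/4), compensating the absorption overestimate of the port-loss
#' slab convention. `exposure_scale` is a global linear factor applied to
#' every pixel.
#'
#' @param rays_per_pixel samples per pixel (>= 1).
#' @param max_bounces path length cap.
#' @param rr_start bounce index at which Russian roulette termination starts.
#' @param seed master seed; per-band, per-pixel, per-sample streams are
#'   derived from it counter-style, so renders are bitwise reproducible and
#'   band-order independent.
#' @param density_multiplier dilution of the medium coefficients (> 0).
#' @param exposure_scale linear output scaling.
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(rays_per_pixel = 200L, max_bounces = 64L,
                            rr_start = 8L, seed = 1L,
                            density_multiplier = 0.25, exposure_scale = 1.0) {
  stopifnot(rays_per_pixel >= 1, max_bounces >= 1, density_multiplier > 0,
            exposure_scale > 0)
  structure(list(rays_per_pixel = as.integer(rays_per_pixel),
                 max_bounces = as.integer(max_bounces),
                 rr_start = as.integer(rr_start),
                 seed = as.integer(seed),
                 density_multiplier = density_multiplier,
                 exposure_scale = exposure_scale),
            class = "render_settings")
}

#' Render one band of a scene as a greyscale image
#'
#' Backward path tracing from the camera with next-event estimation toward
#' the emitter surfaces; the medium attenuates and scatters with the band's
#' coefficients multiplied by the density multiplier. Deterministic for a
#' fixed seed and settings.
#'
#' @param scene a `scene`.
#' @param band_index 1-based band index into the scene's band grid.
#' @param settings a [render_settings()].
#' @return A `grey_image`: numeric matrix (rows = image rows) with
#'   attributes `band_nm` and `settings`.
#' @export
render_band <- function(scene, band_index, settings = render_settings()) {
  stopifnot(inherits(scene, "scene"), inherits(settings, "render_settings"))
  grid <- scene_grid(scene)
  if (!is.null(grid))
    stopifnot(band_index >= 1, band_index <= length(grid$wavelengths))
  pk <- scene_pack(scene, band_index, settings)
  img <- cpp_render_band(pk$surfaces, pk$medium, pk$camera,
                         scene$camera$width, scene$camera$height,
                         settings$rays_per_pixel, settings$max_bounces,
                         settings$rr_start, as.numeric(settings$seed),
                         as.integer(band_index))
  if (any(!is.finite(img)))
    stop("render_band: non-finite radiance at pixel(s) ",
         paste(utils::head(which(!is.finite(img)), 3), collapse = ", "))
  img <- img * settings$exposure_scale
  structure(img, band_nm = if (is.null(grid)) NA_real_ else
    grid$wavelengths[band_index], class = c("grey_image", class(img)))
}

scene_grid <- function(scene) {
  if (!is.null(scene$medium)) return(scene$medium$spectrum$grid)
  if (!is.null(scene$light)) return(scene$light$grid)
  NULL
}

#' Render a full hyperspectral cube
#'
#' One [render_band()] per band over shared geometry; per-band random
#' streams are derived from the master seed counter-style, so adding or
#' reordering bands does not reshuffle the noise of other bands, and two
#' runs with the same settings are bitwise identical.
#'
#' @param scene a `scene` whose medium and light share one band grid.
#' @param settings a [render_settings()].
#' @return A [hypercube()].
#' @export
render_cube <- function(scene, settings = render_settings()) {
  stopifnot(inherits(scene, "scene"))
  grid <- scene_grid(scene)
  if (is.null(grid)) stop("scene has neither medium nor light: no band grid")
  if (!is.null(scene$medium) && !is.null(scene$light))
    stopifnot(same_grid(scene$medium$spectrum$grid, scene$light$grid))
  nb <- length(grid$wavelengths)
  vals <- array(0, dim = c(scene$camera$height, scene$camera$width, nb))
  times <- numeric(nb)
  for (b in seq_len(nb)) {
    t0 <- proc.time()[["elapsed"]]
    vals[, , b] <- render_band(scene, b, settings)
    times[b] <- proc.time()[["elapsed"]] - t0
  }
  hypercube(vals, grid,
            metadata = list(scene = scene$meta$kind %||% "custom",
                            rays_per_pixel = settings$rays_per_pixel,
                            density_multiplier = settings$density_multiplier,
                            exposure_scale = settings$exposure_scale,
                            seed = settings$seed,
                            band_seconds = times))
}

#' Binary mask of the suspension surface
#'
#' Marks the pixels whose primary camera ray first hits the top surface of
#' the medium; lamps, walls and background are zero. Used as the region of
#' interest for the well-lit-fraction metric.
#'
#' @param scene a `scene` with a medium.
#' @param settings a [render_settings()] (only the camera is used).
#' @return Integer matrix of 0/1 of the camera's image size.
#' @export
render_surface_mask <- function(scene, settings = render_settings()) {
  stopifnot(inherits(scene, "scene"))
  pk <- scene_pack(scene, 1L, settings)
  cpp_surface_mask(pk$surfaces, pk$medium, pk$camera,
                   scene$camera$width, scene$camera$height)
}
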