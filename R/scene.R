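# Scene model: analytic primitives (z-aligned cylinder shells, discs,
# rectangles with an optional circular aperture) carrying one of four
# materials -- matte (Lambertian, albedo 0 = black absorber), metal (glossy
# specular), thin glass (Fresnel reflect / straight-through transmit) and
# lamp (diffuse or spot emitter). One homogeneous medium region (a z-aligned
# cylinder volume) holds the suspension. Meshes for export/validation are
# generated separately by build_cylinder_mesh(); the renderer consumes the
# analytic description.

#' Scene surface primitives
#'
#' Low-level building blocks for composing custom scenes: a z-aligned
#' finite cylinder shell, a disc with an optional concentric hole, and a
#' rectangle with an optional circular aperture. Materials are `"matte"`
#' (Lambertian; `mat_param` = albedo, 0 is a black absorber), `"metal"`
#' (specular; `mat_param` = reflectance), `"glass"` (thin dielectric;
#' `mat_param` = refractive index) and `"lamp"` (diffuse emitter;
#' `emission_scale` multiplies the scene's per-area power, `cone_cos` > -1
#' restricts emission to a cone about the normal).
#'
#' @param cx,cy,z0,z1,radius cylinder axis position, z-extent and radius (m).
#' @param material one of `"matte"`, `"metal"`, `"glass"`, `"lamp"`.
#' @param mat_param material parameter (see above).
#' @param orient +1 for outward-facing normals, -1 for inward (cylinders).
#' @param emission_scale relative emitter strength (lamps).
#' @param cone_cos cosine of the spot half-angle, or <= -1 for diffuse.
#' @param two_sided emit from both faces.
#' @return A surface description list.
#' @export
surf_cylinder <- function(cx, cy, z0, z1, radius, material, mat_param = 0,
                          orient = 1, emission_scale = 0, cone_cos = -2,
                          two_sided = FALSE) {
  list(type = "cylinder", cx = cx, cy = cy, z0 = z0, z1 = z1, radius = radius,
       orient = orient, material = material, mat_param = mat_param,
       emission_scale = emission_scale, cone_cos = cone_cos,
       two_sided = two_sided)
}

#' @rdname surf_cylinder
#' @param centre,normal disc centre and unit normal.
#' @param hole_radius concentric hole radius (discs), m.
#' @export
surf_disc <- function(centre, normal, radius, hole_radius = 0, material,
                      mat_param = 0, emission_scale = 0, cone_cos = -2,
                      two_sided = FALSE) {
  list(type = "disc", centre = centre, normal = normal, radius = radius,
       hole_radius = hole_radius, material = material, mat_param = mat_param,
       emission_scale = emission_scale, cone_cos = cone_cos,
       two_sided = two_sided)
}

#' @rdname surf_cylinder
#' @param p0,u,v rectangle corner and edge vectors (m).
#' @param hole_uv aperture centre in local metric (u, v) coordinates.
#' @export
surf_rect <- function(p0, u, v, material, mat_param = 0, hole_uv = c(0, 0),
                      hole_radius = 0, emission_scale = 0, cone_cos = -2,
                      two_sided = FALSE) {
  list(type = "rect", p0 = p0, u = u, v = v, hole_uv = hole_uv,
       hole_radius = hole_radius, material = material, mat_param = mat_param,
       emission_scale = emission_scale, cone_cos = cone_cos,
       two_sided = two_sided)
}

.mat_code <- c(matte = 0, metal = 1, glass = 2, lamp = 3)

#' Pinhole camera description
#'
#' @param position,look_at,up camera frame in scene coordinates (m).
#' @param fov_deg vertical field of view in degrees.
#' @param width,height image size in pixels.
#' @return A camera list used by scenes.
#' @export
camera <- function(position, look_at, up = c(0, 1, 0), fov_deg = 31,
                   width = 128L, height = 128L) {
  list(position = as.numeric(position), look_at = as.numeric(look_at),
       up = as.numeric(up), fov_deg = fov_deg,
       width = as.integer(width), height = as.integer(height))
}

#' Assemble a scene from primitives
#'
#' @param surfaces list of [surf_cylinder()]/[surf_disc()]/[surf_rect()]
#'   primitives.
#' @param medium `NULL` or a list with `cx`, `cy`, `z0`, `z1`, `radius` and
#'   `spectrum` (a [medium_spectrum()]) describing the suspension cylinder.
#' @param light a [light_spectrum()] or `NULL`.
#' @param power_per_area emitter radiance per unit area (arbitrary linear
#'   units).
#' @param cam a [camera()].
#' @param meta free-form metadata list.
#' @return A `scene`.
#' @export
new_scene <- function(surfaces, medium, light, power_per_area, cam, meta = list()) {
  structure(list(surfaces = surfaces, medium = medium, light = light,
                 power_per_area = power_per_area, camera = cam, meta = meta),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s: %d surfaces (%d emissive), %s medium, camera %dx%d px, %g deg FOV\n",
              x$meta$kind %||% "custom", length(x$surfaces),
              sum(vapply(x$surfaces, function(s) s$material == "lamp", TRUE)),
              if (is.null(x$medium)) "no" else "one", x$camera$width,
              x$camera$height, x$camera$fov_deg))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total emissive surface area of a scene
#' @param scene a `scene`.
#' @return Area in m^2.
#' @export
scene_emitter_area <- function(scene) {
  a <- 0
  for (s in scene$surfaces) {
    if (s$material != "lamp") next
    a <- a + switch(s$type,
      cylinder = 2 * pi * s$radius * (s$z1 - s$z0),
      disc = pi * (s$radius^2 - s$hole_radius^2),
      rect = sqrt(sum(crossprod3(s$u, s$v)^2)) - pi * s$hole_radius^2)
  }
  a
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a photobioreactor scene
#'
#' Assembles the renderable digital reactor. Glass type: the lateral wall is
#' the light sheet itself (an inward-emitting cylindrical emitter at the wall
#' radius, the LED sheet pressed against the wall); the suspension column is
#' inset by `wall_gap` (the wall thickness), and the bottom is a black
#' absorber. Steel type: reflective metal wall and bottom, and `n_lamps`
#' emissive rod lamps spanning the full inner height, laid out by
#' [lamp_layout()]; the rods' top caps are emissive discs so the rods are
#' closed solids. The reactor is filled to the brim and imaged from above
#' through the open top, looking down the axis.
#'
#' @param dims a [glass_reactor_dims()] or [steel_reactor_dims()] result.
#' @param medium a [medium_spectrum()] (the suspension).
#' @param light a [light_spectrum()] (same grid as `medium`).
#' @param power_per_area emitted radiance per unit lamp area (arbitrary
#'   linear units per m^2); identical values make glass and steel scenes
#'   comparable because their lamp areas are matched.
#' @param cam optional [camera()] override; the default looks straight down
#'   from above, framing the whole vessel with the 31 degree field of view.
#' @param steel_reflectance flat specular reflectance of the steel wall.
#' @param wall_gap glass wall thickness separating suspension from the
#'   emitter sheet, m.
#' @return A `scene`.
#' @export
build_reactor_scene <- function(dims, medium, light, power_per_area = 1,
                                cam = NULL, steel_reflectance = 0.6,
                                wall_gap = 0.002) {
  stopifnot(inherits(dims, "reactor_dims"), inherits(medium, "medium_spectrum"),
            inherits(light, "light_spectrum"))
  if (!same_grid(medium$grid, light$grid))
    stop("medium and light must share one band grid")
  R <- dims$radius; h <- dims$height
  surfaces <- list()
  if (dims$type == "glass") {
    surfaces <- list(
      surf_cylinder(0, 0, 0, h, R, material = "lamp", orient = -1,
                    emission_scale = 1),
      surf_disc(c(0, 0, 0), c(0, 0, -1), R, material = "matte", mat_param = 0))
    med_radius <- R - wall_gap
  } else {
    pos <- lamp_layout(dims$n_lamps, R, dims$lamp_radius)
    # rough industrial steel: reflectance split evenly between a mirror
    # lobe and a diffuse lobe, so the wall redistributes rod light and
    # evens out the field instead of acting as a perfect mirror
    surfaces <- list(
      surf_cylinder(0, 0, 0, h, R, material = "metal",
                    mat_param = steel_reflectance, orient = -1),
      surf_disc(c(0, 0, 0), c(0, 0, -1), R, material = "metal",
                mat_param = steel_reflectance))
    for (i in seq_len(nrow(pos))) {
      surfaces <- c(surfaces, list(
        surf_cylinder(pos[i, 1], pos[i, 2], 0, h, dims$lamp_radius,
                      material = "lamp", orient = 1, emission_scale = 1),
        surf_disc(c(pos[i, 1], pos[i, 2], h), c(0, 0, 1), dims$lamp_radius,
                  material = "lamp", emission_scale = 1)))
    }
    med_radius <- R
  }
  if (is.null(cam)) {
    dist <- 1.15 * R / tan(31 / 2 * pi / 180)
    cam <- camera(c(0, 0, h + dist), c(0, 0, 0), fov_deg = 31)
  }
  medium_region <- list(cx = 0, cy = 0, z0 = 0, z1 = h, radius = med_radius,
                        spectrum = medium)
  new_scene(surfaces, medium_region, light, power_per_area, cam,
            meta = list(kind = paste0(dims$type, "_reactor"), dims = dims))
}

#' Build the black-box validation scene
#'
#' A digital twin of a desk validation set-up: an open-topped cylinder of
#' suspension (a sawed-off cultivation bottle with a thin plastic/glass
#' wall) stands in a matte-black box; a spot lamp outside the box shines
#' through one circular aperture onto the top of the bottle, and the camera
#' images the bottle through a second aperture in a neighbouring wall. With
#' both apertures closed (radius 0) no light can enter and the render is
#' identically zero.
#'
#' @param light a [light_spectrum()].
#' @param medium a [medium_spectrum()] on the same grid.
#' @param bottle_radius,bottle_height bottle dimensions, m.
#' @param box_size inner box edge length, m.
#' @param aperture_radius radius of both apertures, m (0 closes them).
#' @param power_per_area emitter radiance (arbitrary linear units per m^2).
#' @param cam optional [camera()] override (default 512 x 512 px, 31 degree
#'   field of view, looking through the camera aperture).
#' @return A `scene`.
#' @export
build_validation_scene <- function(light, medium,
                                   bottle_radius = 0.04,
                                   bottle_height = 0.11,
                                   box_size = 0.5,
                                   aperture_radius = 0.03,
                                   power_per_area = 1,
                                   cam = NULL) {
  stopifnot(inherits(medium, "medium_spectrum"), inherits(light, "light_spectrum"))
  if (!same_grid(medium$grid, light$grid))
    stop("medium and light must share one band grid")
  L <- box_size; hw <- L / 2
  # box interior: x,y in [-hw, hw], z in [0, L]; matte black walls
  black <- function(p0, u, v, hole_uv = c(0, 0), hole_radius = 0)
    surf_rect(p0, u, v, material = "matte", mat_param = 0,
              hole_uv = hole_uv, hole_radius = hole_radius)
  # light aperture high on the +x wall; camera aperture on the -y wall at
  # bottle height, with the camera pinhole just behind it so the whole
  # frustum passes through
  ap_light_z <- 0.4 * L
  ap_cam_z <- 0.6 * bottle_height
  surfaces <- list(
    # floor and ceiling
    black(c(-hw, -hw, 0), c(L, 0, 0), c(0, L, 0)),
    black(c(-hw, -hw, L), c(0, L, 0), c(L, 0, 0)),
    # +x wall with the light aperture (u along y, v along z)
    black(c(hw, -hw, 0), c(0, L, 0), c(0, 0, L),
          hole_uv = c(hw, ap_light_z), hole_radius = aperture_radius),
    # -x wall
    black(c(-hw, -hw, 0), c(0, 0, L), c(0, L, 0)),
    # -y wall with the camera aperture (u along x, v along z)
    black(c(-hw, -hw, 0), c(L, 0, 0), c(0, 0, L),
          hole_uv = c(hw, ap_cam_z), hole_radius = aperture_radius),
    # +y wall
    black(c(-hw, hw, 0), c(0, 0, L), c(L, 0, 0)),
    # bottle: thin wall + matte bottom
    surf_cylinder(0, 0, 0, bottle_height, bottle_radius, material = "glass",
                  mat_param = 1.5),
    surf_disc(c(0, 0, 0), c(0, 0, -1), bottle_radius, material = "matte",
              mat_param = 0.2))
  # spot lamp outside the +x wall on the line bottle-top -> aperture centre,
  # so its cone (half-angle 25 degrees) shines through the hole onto the
  # suspension surface
  f <- (hw + 0.10) / hw
  lamp_pos <- c(hw + 0.10, 0, bottle_height + f * (ap_light_z - bottle_height))
  aim <- c(0, 0, bottle_height) - lamp_pos
  aim <- aim / sqrt(sum(aim^2))
  surfaces <- c(surfaces, list(
    surf_disc(lamp_pos, aim, 0.03, material = "lamp", emission_scale = 1,
              cone_cos = cos(25 * pi / 180))))
  if (is.null(cam))
    cam <- camera(c(0, -hw - 0.01, ap_cam_z), c(0, 0, bottle_height / 2),
                  up = c(0, 0, 1), fov_deg = 31, width = 512L, height = 512L)
  medium_region <- list(cx = 0, cy = 0, z0 = 0, z1 = bottle_height,
                        radius = bottle_radius - 0.001, spectrum = medium)
  new_scene(surfaces, medium_region, light, power_per_area, cam,
            meta = list(kind = "validation_box"))
}

# flatten a scene into the matrices the C++ kernels consume
scene_pack <- function(scene, band_index, settings) {
  ns <- length(scene$surfaces)
  S <- matrix(0, nrow = ns, ncol = 19)
  for (i in seq_len(ns)) {
    s <- scene$surfaces[[i]]
    S[i, 1] <- switch(s$type, cylinder = 1, disc = 2, rect = 3)
    if (s$type == "cylinder") {
      S[i, 2:7] <- c(s$cx, s$cy, s$z0, s$z1, s$radius, s$orient)
    } else if (s$type == "disc") {
      S[i, 2:9] <- c(s$centre, s$normal, s$radius, s$hole_radius)
    } else {
      S[i, 2:13] <- c(s$p0, s$u, s$v, s$hole_uv, s$hole_radius)
    }
    S[i, 14] <- .mat_code[[s$material]]
    S[i, 15] <- s$mat_param
    if (s$material == "lamp" && s$emission_scale > 0) {
      rel <- if (is.null(scene$light)) 1 else
        scene$light$relative_power[band_index]
      S[i, 16] <- scene$power_per_area * rel * s$emission_scale
    }
    S[i, 17] <- s$cone_cos
    S[i, 18] <- as.numeric(isTRUE(s$two_sided))
    S[i, 19] <- if (is.null(s$gloss)) 0.5 else s$gloss
  }
  med <- scene$medium
  medium_vec <- if (is.null(med)) numeric(0) else {
    sp <- med$spectrum
    k <- settings$density_multiplier
    c(med$cx, med$cy, med$z0, med$z1, med$radius,
      k * sp$sigma_a[band_index], k * sp$sigma_s[band_index], sp$g)
  }
  cm <- scene$camera
  fwd <- cm$look_at - cm$position
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- crossprod3(fwd, cm$up)
  right <- right / sqrt(sum(right^2))
  up2 <- crossprod3(right, fwd)
  cam_vec <- c(cm$position, fwd, right, up2, tan(cm$fov_deg / 2 * pi / 180))
  list(surfaces = S, medium = medium_vec, camera = cam_vec)
}
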