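# Small bespoke scenes keep the per-test renders cheap; the full desk-scale
# reactor renders live in the shared fixtures and the acceptance tests.

vf_scene <- function(width = 33, height = 33, rho = 0.5, radiance = 10,
                     a = 0.05, he = 0.2) {
  # matte floor lit by a diffuse disc emitter straight above the origin;
  # the camera looks at the floor centre from a shallow angle
  new_scene(
    surfaces = list(
      surf_rect(c(-0.5, -0.5, 0), c(1, 0, 0), c(0, 1, 0),
                material = "matte", mat_param = rho),
      surf_disc(c(0, 0, he), c(0, 0, -1), a, material = "lamp",
                emission_scale = 1)),
    medium = NULL, light = NULL, power_per_area = radiance,
    cam = camera(c(0.18, 0, 0.12), c(0, 0, 0), up = c(0, 0, 1),
                 width = width, height = height),
    meta = list(kind = "view_factor"))
}

test_that("direct illumination matches the analytic view factor at the centre pixel", {
  rho <- 0.5; L <- 10; a <- 0.05; he <- 0.2
  sc <- vf_scene(rho = rho, radiance = L, a = a, he = he)
  img <- render_band(sc, 1, render_settings(rays_per_pixel = 800, seed = 4))
  centre <- img[17, 17]
  analytic <- rho * L * a^2 / (a^2 + he^2)   # disc view factor times rho*L
  expect_lt(abs(centre / analytic - 1), 0.02)
})

test_that("renders are bitwise deterministic and exactly linear in emitter power", {
  sc <- vf_scene(width = 24, height = 24)
  st <- render_settings(rays_per_pixel = 64, seed = 11)
  i1 <- render_band(sc, 1, st)
  i2 <- render_band(sc, 1, st)
  expect_identical(unclass(i1), unclass(i2))
  sc2 <- sc; sc2$power_per_area <- 2 * sc$power_per_area
  i3 <- render_band(sc2, 1, st)
  expect_identical(unclass(i3), 2 * unclass(i1))
  # different seed, different noise
  i4 <- render_band(sc, 1, render_settings(rays_per_pixel = 64, seed = 12))
  expect_false(identical(unclass(i1), unclass(i4)))
})

test_that("zero-emission bands and closed scenes render black", {
  g <- band_grid(450, 640, 190)
  med <- medium_spectrum(g, c(5, 5), c(10, 10))
  li <- light_spectrum(g, c(1, 0))     # red band dark
  dims <- glass_reactor_dims(0.01)
  sc <- build_reactor_scene(dims, med, li, power_per_area = 5)
  sc$camera$width <- sc$camera$height <- 24L
  st <- render_settings(rays_per_pixel = 16, seed = 2)
  expect_true(all(render_band(sc, 2, st) == 0))
  expect_gt(max(render_band(sc, 1, st)), 0)
  # validation box with closed apertures: no light can enter
  vsc <- build_validation_scene(li, med, aperture_radius = 0,
                                cam = camera(c(0, -0.26, 0.07),
                                             c(0, 0, 0.05), up = c(0, 0, 1),
                                             width = 16L, height = 16L))
  expect_true(all(render_band(vsc, 1, st) == 0))
})

test_that("the validation scene sees light only through the apertures", {
  g <- band_grid(450, 640, 190)
  med <- medium_spectrum(g, c(20, 10), c(200, 200))
  li <- light_spectrum(g, c(1, 0.8))
  vsc <- build_validation_scene(li, med, aperture_radius = 0.03)
  vsc$camera$width <- vsc$camera$height <- 48L
  img <- render_band(vsc, 1, render_settings(rays_per_pixel = 64, seed = 6))
  expect_gt(max(img), 0)
  # exactly one medium region, camera defaults documented
  expect_equal(vsc$camera$fov_deg, 31)
  def <- build_validation_scene(li, med)
  expect_equal(c(def$camera$width, def$camera$height), c(512L, 512L))
})

test_that("beer-lambert attenuation holds through a scattering-free medium in situ", {
  # camera looks straight down onto an emitting floor disc through a
  # medium column: the primary ray crosses depth h of pure absorber, so
  # the pixel value is L * exp(-k * sigma_a * h)
  g <- structure(list(wavelengths = 500, step = NA_real_),
                 class = "band_grid")
  sa <- 40; h <- 0.1; k <- 0.25
  med <- medium_spectrum(g, sa, 0)
  sc <- new_scene(
    surfaces = list(surf_disc(c(0, 0, 0), c(0, 0, 1), 0.2,
                              material = "lamp", emission_scale = 1)),
    medium = list(cx = 0, cy = 0, z0 = 0, z1 = h, radius = 0.2,
                  spectrum = med),
    light = light_spectrum(g, 1), power_per_area = 100,
    cam = camera(c(0, 0, 0.3), c(0, 0, 0), width = 9L, height = 9L),
    meta = list(kind = "bl_column"))
  st <- render_settings(rays_per_pixel = 4000, seed = 3,
                        density_multiplier = k)
  img <- render_band(sc, 1, st)
  expected <- 100 * exp(-k * sa * h)
  # survival through the column is binomial: compare the mean of the
  # central 3x3 pixels at 3.5 standard errors
  p_surv <- exp(-k * sa * h)
  se_rel <- sqrt((1 - p_surv) / (p_surv * 9 * 4000))
  expect_lt(abs(mean(img[4:6, 4:6]) / expected - 1), 3.5 * se_rel + 0.005)
})

test_that("surface masks classify the suspension top and lamp caps correctly", {
  g <- band_grid(450, 640, 190)
  med <- medium_spectrum(g, c(5, 5), c(10, 10))
  li <- light_spectrum(g, c(1, 1))
  gd <- glass_reactor_dims(0.1)
  gsc <- build_reactor_scene(gd, med, li)
  gsc$camera$width <- gsc$camera$height <- 96L
  st <- render_settings(seed = 1)
  gm <- render_surface_mask(gsc, st)
  # filled disc: area close to the projected medium disc, no holes inside
  expect_gt(mean(gm), 0.3)
  i <- which(gm > 0, arr.ind = TRUE)
  ctr <- colMeans(i)
  expect_lt(max(abs(ctr - (96 + 1) / 2)), 1.5)      # disc centred
  # steel: disc minus the lamp discs
  sd <- steel_reactor_dims(0.1, 12, gd$lamp_area)
  ssc <- build_reactor_scene(sd, med, li)
  ssc$camera$width <- ssc$camera$height <- 96L
  sm <- render_surface_mask(ssc, st)
  frac_expected <- (pi * sd$radius^2 - 12 * pi * sd$lamp_radius^2) /
    (pi * sd$radius^2)
  # the two reactors frame slightly differently; compare hole fraction
  ratio <- sum(sm) / sum(gm) *
    (gd$radius - 0.002)^2 / gd$radius^2  # undo the glass medium inset
  expect_lt(abs(ratio - frac_expected), 0.05)
  # empty scene (no medium): all zeros
  esc <- new_scene(list(surf_disc(c(0, 0, 0), c(0, 0, 1), 0.1,
                                  material = "matte", mat_param = 0)),
                   medium = NULL, light = NULL, power_per_area = 1,
                   cam = camera(c(0, 0, 1), c(0, 0, 0), width = 16L,
                                height = 16L),
                   meta = list())
  expect_true(all(render_surface_mask(esc, st) == 0))
})

test_that("scene construction enforces the matched-lamp-area comparability", {
  g <- band_grid(450, 640, 190)
  med <- medium_spectrum(g, c(5, 5), c(10, 10))
  li <- light_spectrum(g, c(1, 1))
  gd <- glass_reactor_dims(0.1)
  sd <- steel_reactor_dims(0.1, 12, gd$lamp_area)
  gsc <- build_reactor_scene(gd, med, li, power_per_area = 7)
  ssc <- build_reactor_scene(sd, med, li, power_per_area = 7)
  # glass scene: no internal solids besides the medium (wall sheet + bottom)
  expect_equal(length(gsc$surfaces), 2)
  # steel scene: 12 rods spanning the full height (plus caps, wall, bottom)
  rods <- Filter(function(s) s$type == "cylinder" && s$material == "lamp",
                 ssc$surfaces)
  expect_equal(length(rods), 12)
  expect_true(all(vapply(rods, function(s) s$z1 - s$z0, 0) == sd$height))
  # emitter area x power matched between the two types (rod caps excluded:
  # they close the solids but are not part of the matched side area)
  a_glass <- scene_emitter_area(gsc)
  rod_area <- sum(vapply(rods, function(s) 2 * pi * s$radius * (s$z1 - s$z0), 0))
  expect_equal(a_glass * gsc$power_per_area, rod_area * ssc$power_per_area,
               tolerance = 1e-6)
})
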