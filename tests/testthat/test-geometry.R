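# Printed reference dimensions (cm / m^2) for the three locked-geometry
# reactor volumes. Areas in the reference table were computed from
# cm-rounded radii, so areas are compared at the tolerance that radius
# rounding (half a unit in the last printed digit) propagates to the area:
# dA/A = 2 dr/r.
glass_ref <- data.frame(
  volume_l = c(10, 100, 1000),
  r_cm = c(11.68, 25.15, 54.19),
  h_cm = c(23.36, 50.30, 108.38),
  area_m2 = c(0.1714, 0.7949, 3.6902))

steel_ref <- data.frame(
  volume_l = c(10, 100, 1000),
  r_cm = c(12.27, 25.81, 54.82),
  h_cm = c(24.54, 51.63, 109.64),
  n = c(6, 12, 28),
  rl_cm = c(1.85, 2.04, 1.91),
  area_m2 = c(0.1714, 0.7949, 3.6902))

test_that("glass reactor dimensions follow the closed-form locked geometry", {
  for (i in 1:3) {
    dims <- glass_reactor_dims(glass_ref$volume_l[i] / 1000)
    expect_equal(100 * dims$radius, glass_ref$r_cm[i], tolerance = 5e-3 / glass_ref$r_cm[i])
    expect_equal(100 * dims$height, glass_ref$h_cm[i], tolerance = 1e-2 / glass_ref$h_cm[i])
    area_tol <- 2 * 0.005 / glass_ref$r_cm[i] + 1e-4
    expect_equal(dims$lamp_area, glass_ref$area_m2[i], tolerance = area_tol)
    # exact invariants
    expect_equal(dims$height, 2 * dims$radius)
    expect_equal(2 * pi * dims$radius^3, dims$volume, tolerance = 1e-9)
    expect_equal(dims$lamp_area, 2 * pi * dims$radius * dims$height,
                 tolerance = 1e-12)
  }
  # unit root: V = 2 pi gives r = 1 m exactly
  expect_equal(glass_reactor_dims(2 * pi)$radius, 1, tolerance = 1e-12)
  expect_error(glass_reactor_dims(-1), "positive")
})

test_that("steel reactor solver matches the reference table and its own system", {
  for (i in 1:3) {
    g <- glass_reactor_dims(steel_ref$volume_l[i] / 1000)
    dims <- steel_reactor_dims(steel_ref$volume_l[i] / 1000, steel_ref$n[i],
                               g$lamp_area)
    # printed values carry about one unit of slop in the last digit
    expect_lt(abs(100 * dims$radius - steel_ref$r_cm[i]), 0.011)
    expect_lt(abs(100 * dims$height - steel_ref$h_cm[i]), 0.022)
    expect_lt(abs(100 * dims$lamp_radius - steel_ref$rl_cm[i]), 0.006)
    # re-substitution: working volume and lamp area reproduced
    v_back <- pi * dims$radius^2 * dims$height -
      dims$n_lamps * pi * dims$lamp_radius^2 * dims$height
    a_back <- dims$n_lamps * 2 * pi * dims$lamp_radius * dims$height
    expect_equal(v_back, dims$working_volume, tolerance = 1e-6)
    expect_equal(a_back, dims$lamp_area, tolerance = 1e-6)
    # comparability: identical suspension volume as the glass reactor
    expect_equal(v_back, g$volume, tolerance = 1e-6)
  }
})

test_that("steel solver limits and failure modes behave", {
  # vanishing lamp area recovers the glass closed form
  d0 <- steel_reactor_dims(0.01, 6, 1e-8)
  expect_equal(d0$radius, (0.01 / (2 * pi))^(1 / 3), tolerance = 1e-6)
  # an absurd lamp area produces rods that cannot be packed: the solver
  # still finds the matching dimensions (the reduced cubic always has a
  # positive root) but the layout stage rejects them
  dbad <- steel_reactor_dims(0.001, 2, 5)
  expect_error(lamp_layout(dbad$n_lamps, dbad$radius, dbad$lamp_radius),
               "overlap")
})

test_that("lamp layout respects clearances and ring symmetry", {
  expect_equal(lamp_layout(1, 0.1, 0.01), matrix(c(0, 0), 1,
               dimnames = list(NULL, c("x", "y"))))
  dims <- steel_reactor_dims(0.01, 6, glass_reactor_dims(0.01)$lamp_area)
  pos <- lamp_layout(6, dims$radius, dims$lamp_radius)
  expect_equal(nrow(pos), 6)
  dmin <- min(dist(pos))
  expect_gte(dmin, 2 * dims$lamp_radius)
  wall <- dims$radius - sqrt(rowSums(pos^2))
  expect_true(all(wall >= dims$lamp_radius))
  # rotating by 2 pi / 6 maps the position set onto itself
  th <- 2 * pi / 6
  rot <- pos %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  match_dist <- apply(rot, 1, function(p)
    min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)))
  expect_lt(max(match_dist), 1e-9)
  # impossible packing is rejected
  expect_error(lamp_layout(6, 0.1, 0.09))
})

test_that("cylinder meshes are watertight with the predicted element counts", {
  m3 <- build_cylinder_mesh(0.1, 0.2, n_segments = 3, with_caps = TRUE)
  expect_equal(nrow(m3$vertices), 8)           # 6 rim + 2 cap centres
  chk <- mesh_check(m3)
  expect_true(chk$watertight)
  expect_equal(chk$euler, 2)
  expect_gt(chk$min_triangle_area, 0)
  # lateral-area convergence: inscribed polygon error at 64 segments < 0.2%
  lat64 <- build_cylinder_mesh(0.1, 0.2, 64, with_caps = FALSE)
  expect_lt(abs(mesh_area(lat64) - 2 * pi * 0.1 * 0.2) / (2 * pi * 0.1 * 0.2),
            0.002)
  # doubling the segment count monotonically shrinks the error
  errs <- sapply(c(8, 16, 32, 64, 128), function(n) {
    m <- build_cylinder_mesh(0.1, 0.2, n, with_caps = FALSE)
    abs(mesh_area(m) - 2 * pi * 0.1 * 0.2)
  })
  expect_true(all(diff(errs) < 0))
  # caps requested: watertight at higher resolutions too
  expect_true(mesh_check(build_cylinder_mesh(0.05, 0.3, 32))$watertight)
})

test_that("mesh export writes well-formed OBJ and PLY", {
  m <- build_cylinder_mesh(0.1, 0.2, 12)
  obj <- tempfile(fileext = ".obj")
  write_mesh_obj(m, obj)
  ln <- readLines(obj)
  expect_equal(sum(grepl("^v ", ln)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", ln)), nrow(m$triangles))
  ply <- tempfile(fileext = ".ply")
  write_mesh_ply(m, ply)
  ln2 <- readLines(ply)
  expect_equal(ln2[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(m$vertices)), ln2)))
})
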