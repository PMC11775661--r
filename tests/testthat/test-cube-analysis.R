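make_cube <- function(vals, wl0 = 450, step = 10) {
  nb <- dim(vals)[3]
  hypercube(vals, band_grid(wl0, wl0 + step * (nb - 1), step))
}

test_that("ENVI round trip is bitwise lossless and errors are explicit", {
  set.seed(6)
  cube <- make_cube(array(runif(4 * 4 * 3) * 1000, dim = c(4, 4, 3)))
  base <- file.path(tempdir(), "cube_rt")
  write_envi(cube, base)
  back <- read_envi(base)
  expect_identical(back$values, cube$values)
  expect_equal(back$grid$wavelengths, cube$grid$wavelengths,
               tolerance = 1e-9)
  file.remove(paste0(base, ".hdr"))
  expect_error(read_envi(base), "header not found")
  expect_error(read_envi(file.path(tempdir(), "no_such_cube")), "not found")
})

test_that("false colour picks nearest bands, zeroes green, shares the display maximum", {
  vals <- array(0, dim = c(2, 2, 3))
  vals[, , 1] <- 4   # 450 nm
  vals[, , 3] <- 8   # 470 nm -> will be the "red" pick below
  cube <- make_cube(vals, wl0 = 450, step = 10)
  fc <- false_colour(cube, blue_nm = 450, red_nm = 470)
  expect_true(all(fc[, , 2] == 0))
  expect_equal(fc[, , 1], matrix(1, 2, 2))      # red channel = 8/8
  expect_equal(fc[, , 3], matrix(0.5, 2, 2))    # blue channel = 4/8
  # zero red band -> zero red channel
  vals2 <- vals; vals2[, , 3] <- 0
  fc2 <- false_colour(make_cube(vals2), blue_nm = 450, red_nm = 470)
  expect_true(all(fc2[, , 1] == 0))
  # nearest-band tie resolves to the lower wavelength
  expect_equal(pbrsim:::band_index_of(cube, 455), 1L)
})

test_that("region mean spectra match a brute-force double loop", {
  cube <- make_cube(array(7, dim = c(3, 3, 2)))
  ms <- region_mean_spectrum(cube, roi(0, 0, 3, 3))
  expect_equal(ms$mean, c(7, 7))
  expect_equal(ms$sd, c(0, 0))
  two <- make_cube(array(c(0, 2), dim = c(1, 2, 1)))
  ms2 <- region_mean_spectrum(two, roi(0, 0, 1, 2))
  expect_equal(ms2$mean, 1)
  expect_equal(ms2$sd, 1)   # population standard deviation
  set.seed(8)
  rc <- make_cube(array(runif(8 * 8 * 5), dim = c(8, 8, 5)))
  reg <- roi(2, 1, 4, 5)
  ms3 <- region_mean_spectrum(rc, reg)
  for (b in 1:5) {
    acc <- c()
    for (i in (reg$row0 + 1):(reg$row0 + reg$height))
      for (j in (reg$col0 + 1):(reg$col0 + reg$width))
        acc <- c(acc, rc$values[i, j, b])
    expect_equal(ms3$mean[b], mean(acc), tolerance = 1e-12)
    expect_equal(ms3$sd[b], sqrt(mean((acc - mean(acc))^2)), tolerance = 1e-12)
  }
  expect_error(region_mean_spectrum(rc, roi(6, 6, 4, 4)), "outside")
})

test_that("decay curves are geometric for exponential input and normalized on the reference band", {
  # intensity halves every row on band 1; band 2 (reference) peaks at 1000
  nr <- 12
  vals <- array(0, dim = c(nr, 4, 2))
  vals[, , 1] <- matrix(rep(800 * 0.5^(0:(nr - 1)), 4), nr)
  vals[, , 2] <- matrix(rep(1000 * 0.7^(0:(nr - 1)), 4), nr)
  cube <- make_cube(vals, wl0 = 450, step = 190)   # bands 450, 640
  reg <- roi(0, 0, nr, 4)
  dc <- decay_curve(cube, 450, reg, reference_band_nm = 640)
  ratios <- dc$intensity[-1] / dc$intensity[-nr]
  expect_equal(ratios, rep(0.5, nr - 1), tolerance = 1e-12)
  expect_equal(attr(dc, "normalization"), 1000)
  # the reference band's own curve starts at <= 1 and its maximum pixel
  # maps to exactly 1
  dr <- decay_curve(cube, 640, reg, reference_band_nm = 640)
  expect_lte(max(dr$intensity), 1)
  expect_equal(dr$intensity[1], 1)     # constant rows: mean = max here
  # invariance under uniform rescaling of the cube
  cube2 <- make_cube(vals * 37, wl0 = 450, step = 190)
  dc2 <- decay_curve(cube2, 450, reg, reference_band_nm = 640)
  expect_equal(dc2$intensity, dc$intensity, tolerance = 1e-12)
  # ordering from the bright edge also when the profile is flipped
  dcf <- decay_curve(make_cube(vals[nr:1, , , drop = FALSE], 450, 190),
                     450, reg, reference_band_nm = 640)
  expect_equal(dcf$intensity, dc$intensity, tolerance = 1e-12)
  # zero reference: cannot normalize
  vz <- vals; vz[, , 2] <- 0
  expect_error(decay_curve(make_cube(vz, 450, 190), 450, reg,
                           reference_band_nm = 640), "normalize")
})

test_that("decay-curve slope recovers the effective absorption of a synthetic cube", {
  # emulate a side-lit absorbing column: exp(-k sigma_a x) down the rows,
  # with row pitch 1 mm
  k <- 0.25; sa <- 120; pitch <- 0.001
  nr <- 60
  prof <- exp(-k * sa * pitch * (0:(nr - 1)))
  vals <- array(rep(1000 * prof, 6), dim = c(nr, 6, 1))
  cube <- make_cube(vals, wl0 = 640, step = 10)
  dc <- decay_curve(cube, 640, roi(0, 0, nr, 6), reference_band_nm = 640)
  slope <- -coef(lm(log(dc$intensity) ~ dc$distance_px))[2] / pitch
  expect_lt(abs(slope - k * sa) / (k * sa), 0.1)
})

test_that("well-lit fraction counts thresholded mask pixels and is monotone in the threshold", {
  vals <- array(0, dim = c(4, 4, 1))
  vals[, , 1] <- matrix(c(rep(2000, 8), rep(500, 8)), 4)
  cube <- make_cube(vals, wl0 = 640, step = 10)
  mask <- matrix(1L, 4, 4)
  expect_equal(well_lit_fraction(cube, 640, mask, 1000), 50)
  expect_equal(well_lit_fraction(cube, 640, mask, 100), 100)
  expect_equal(well_lit_fraction(cube, 640, mask, 1e6), 0)
  # monotone non-increasing in the threshold
  th <- seq(0, 3000, by = 250)
  wl <- sapply(th, function(x) well_lit_fraction(cube, 640, mask, x))
  expect_true(all(diff(wl) <= 0))
  # masked subset only
  mask2 <- matrix(0L, 4, 4); mask2[1:2, 1:2] <- 1L
  expect_equal(well_lit_fraction(cube, 640, mask2, 1000), 100)
  expect_error(well_lit_fraction(cube, 640, matrix(0L, 4, 4), 1000), "empty")
  expect_error(well_lit_fraction(cube, 640, matrix(1L, 2, 2), 1000), "size")
})

test_that("mid-grey exposure meters the masked median and preserves orderings", {
  set.seed(11)
  a <- make_cube(array(runif(16, 0, 5), dim = c(4, 4, 1)))
  b <- make_cube(array(runif(16, 0, 9), dim = c(4, 4, 1)))
  ex <- expose_cubes(list(a, b), full_scale = 10000, grey_fraction = 0.18)
  pooled <- c(ex[[1]]$values, ex[[2]]$values)
  expect_equal(median(pooled), 1800, tolerance = 1e-9)
  f <- ex[[1]]$metadata$exposure_factor
  expect_equal(ex[[2]]$metadata$exposure_factor, f)
  expect_equal(ex[[1]]$values, a$values * f, tolerance = 1e-12)
  # metering on a mask ignores everything outside it
  mask <- matrix(0L, 4, 4); mask[1:2, ] <- 1L
  exm <- expose_cubes(list(a), masks = list(mask))
  expect_equal(median(a$values[, , 1][mask > 0]) *
                 exm[[1]]$metadata$exposure_factor, 1800, tolerance = 1e-9)
})

test_that("macro-pixel aggregation averages blocks and votes masks by majority", {
  vals <- array(0, dim = c(4, 4, 2))
  vals[, , 1] <- matrix(1:16, 4)
  vals[, , 2] <- 2 * matrix(1:16, 4)
  cube <- make_cube(vals)
  small <- downsample_cube(cube, 2)
  expect_equal(dim(small), c(2L, 2L, 2L))
  expect_equal(small$values[1, 1, 1], mean(vals[1:2, 1:2, 1]))
  expect_equal(small$values[, , 2], 2 * small$values[, , 1])
  mask <- matrix(0L, 4, 4); mask[1:2, 1:4] <- 1L; mask[3, 1] <- 1L
  dm <- downsample_mask(mask, 2)
  expect_equal(dm, matrix(c(1L, 0L, 1L, 0L), 2))
  expect_error(downsample_cube(cube, 3), "divisible")
})
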