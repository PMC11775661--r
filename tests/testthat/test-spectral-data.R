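test_that("band grid construction follows the inclusive-endpoint count formula", {
  expect_equal(length(band_grid(400, 700, 10)), 31L)
  expect_equal(length(band_grid(400, 400, 10)), 1L)
  expect_equal(band_grid(400, 700, 100)$wavelengths, c(400, 500, 600, 700))
  # property: count formula exact across many valid triples
  set.seed(1)
  for (k in 1:25) {
    start <- sample(300:800, 1)
    step <- sample(c(1, 2, 5, 10, 25), 1)
    nb <- sample(1:60, 1)
    g <- band_grid(start, start + step * (nb - 1), step)
    expect_equal(length(g), nb)
    expect_true(all(abs(diff(g$wavelengths) - step) < 1e-9))
  }
  expect_error(band_grid(400, 705, 10), "divisible")
  expect_error(band_grid(400, 700, -5))
})

test_that("gaussian smoothing preserves constants, identity at sigma 0, and matches a direct kernel sum", {
  g <- band_grid(400, 700, 10)
  const <- spectrum(g, rep(0.4, 31))
  expect_equal(smooth_spectrum(const, 3)$values, const$values, tolerance = 1e-12)
  s <- spectrum(g, runif(31))
  expect_identical(smooth_spectrum(s, 0)$values, s$values)
  # unit spike mid-grid vs brute-force discrete Gaussian convolution
  spike <- spectrum(g, replace(rep(0, 31), 16, 1))
  sm <- smooth_spectrum(spike, 2)
  half <- ceiling(4 * 2)
  kern <- exp(-(-half:half)^2 / (2 * 2^2)); kern <- kern / sum(kern)
  expected <- sapply(1:31, function(i) {
    off <- i - 16
    if (abs(off) <= half) kern[off + half + 1] else 0
  })
  expect_equal(sm$values, expected, tolerance = 1e-12)
  # mass preserved for interior-supported signals
  expect_equal(sum(sm$values), 1, tolerance = 1e-3)
  expect_error(smooth_spectrum(s, -1), "nonnegative")
})

test_that("cubic resampling reproduces nodes, lines and cubics, and rejects extrapolation", {
  g <- band_grid(400, 700, 10)
  s <- spectrum(g, runif(31))
  expect_equal(resample_spectrum(s, g)$values, s$values, tolerance = 1e-12)
  lin <- spectrum(g, 0.1 + 0.002 * (g$wavelengths - 400))
  fine <- band_grid(400, 700, 5)
  rl <- resample_spectrum(lin, fine)
  expect_equal(rl$values, 0.1 + 0.002 * (fine$wavelengths - 400),
               tolerance = 1e-9)
  # a cubic polynomial sampled at 20 nodes, resampled to midpoints
  g20 <- band_grid(400, 590, 10)
  f <- function(x) 1e-6 * (x - 500)^3 / 50 + 0.5 + 1e-3 * (x - 450)
  cubic <- spectrum(g20, f(g20$wavelengths))
  mids <- band_grid(405, 585, 10)
  rm <- resample_spectrum(cubic, mids)
  expect_equal(rm$values, f(mids$wavelengths), tolerance = 1e-9)
  expect_error(resample_spectrum(s, band_grid(390, 700, 10)), "extrapolation")
})

test_that("smoothing and resampling commute with scalar multiplication", {
  g <- band_grid(400, 700, 10)
  v <- runif(31, 0.1, 0.5)
  s1 <- spectrum(g, v); s2 <- spectrum(g, 3 * v)
  expect_equal(3 * smooth_spectrum(s1, 1.5)$values,
               smooth_spectrum(s2, 1.5)$values, tolerance = 1e-12)
  fine <- band_grid(405, 695, 10)
  expect_equal(3 * resample_spectrum(s1, fine)$values,
               resample_spectrum(s2, fine)$values, tolerance = 1e-12)
})

test_that("synthetic Chlorella targets have the documented spectral shape", {
  g <- band_grid(400, 700, 10)
  # zero density: no attenuation beyond the reflectance ceiling
  t0 <- synth_chlorella_targets(g, 0)
  expect_true(all(t0$transmittance$values + t0$reflectance$values <= 1 + 1e-12))
  expect_true(all(t0$transmittance$values >= 0.9))
  expect_true(all(t0$reflectance$values <= 0.1))
  # validation-like density: at least 60% transmitted in the green
  t14 <- synth_chlorella_targets(g, 1.4e7)
  i550 <- which(g$wavelengths == 550)
  expect_gte(t14$transmittance$values[i550], 0.6)
  # monotone attenuation with density, r + t <= 1 over a wide density range
  prev <- NULL
  for (dens in c(0, 1e6, 5e6, 1.4e7, 1.9e7, 4.6e7, 7.4e7, 1e8)) {
    tg <- synth_chlorella_targets(g, dens)
    expect_true(all(tg$reflectance$values + tg$transmittance$values <= 1 + 1e-9))
    expect_true(all(tg$reflectance$values <= 0.1 + 1e-12))
    if (!is.null(prev))
      expect_true(all(tg$transmittance$values <= prev + 1e-12))
    prev <- tg$transmittance$values
  }
  # blue trough deeper than red trough at high density (chlorophyll blue
  # absorption grows faster)
  td <- synth_chlorella_targets(g, 7.4e7)
  i450 <- which(g$wavelengths == 450); i640 <- which(g$wavelengths == 640)
  expect_lt(td$transmittance$values[i450], td$transmittance$values[i640])
  expect_error(synth_chlorella_targets(g, -1), "nonnegative")
})

test_that("synthetic grow light peaks at the 450 and 640 nm bands", {
  g <- band_grid(400, 700, 10)
  li <- synth_growlight_spectrum(g)
  wl <- g$wavelengths
  blue_window <- wl <= 550
  red_window <- wl >= 550
  expect_equal(wl[blue_window][which.max(li$relative_power[blue_window])], 450)
  expect_equal(wl[red_window][which.max(li$relative_power[red_window])], 640)
  expect_true(all(is.finite(li$relative_power)) && all(li$relative_power >= 0))
  # blue peak higher than red peak
  expect_gt(li$relative_power[wl == 450], li$relative_power[wl == 640])
})

test_that("spectrum CSV round trip is lossless and header errors are caught", {
  g <- band_grid(400, 700, 10)
  s <- spectrum(g, round(runif(31), 6), fractional = TRUE)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path, fractional = TRUE)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(s2$grid$wavelengths, g$wavelengths)
  expect_error(read_spectrum_csv(tempfile()), "not found")
})
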