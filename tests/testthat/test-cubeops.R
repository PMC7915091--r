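# Reflectance, false color, spectral angle mapping, scan simulation.

scan3 <- function(n_frames = 60, distortion = NULL, seed = 5)
  simulate_scan(tiles = c(0.2, 0.5, 0.8), n_frames = n_frames,
                n_rows = 80, n_cols = 160, distortion = distortion, seed = seed)

test_that("reflectance of the white and dark frames is 1 and 0", {
  sc <- scan3(n_frames = 4)
  cube_w <- hsi_cube(aperm(array(sc$refs$white, c(80, 160, 2)), c(3, 1, 2)))
  r <- compute_reflectance(cube_w, sc$refs)
  expect_equal(mean(r$values), 1, tolerance = 1e-12)
  cube_d <- hsi_cube(aperm(array(sc$refs$dark, c(80, 160, 2)), c(3, 1, 2)))
  expect_equal(max(compute_reflectance(cube_d, sc$refs)$values), 0)
})

test_that("known tile reflectances are recovered within 2%", {
  sc <- scan3()
  r <- compute_reflectance(sc$cube, sc$refs)
  for (tile in 1:3) {
    got <- mean(r$values[sc$tile_index == tile, , ])
    expect_lt(abs(got - c(0.2, 0.5, 0.8)[tile]) / c(0.2, 0.5, 0.8)[tile], 0.02)
  }
})

test_that("a uniform unit-reflectance scene closes the loop at R = 1", {
  sc <- simulate_scan(tiles = 1, n_frames = 20, n_rows = 60, n_cols = 120, seed = 9)
  r <- compute_reflectance(sc$cube, sc$refs)
  expect_equal(mean(r$values), 1, tolerance = 0.02)
})

test_that("zero illumination yields an all-dark cube", {
  dark_ill <- structure(list(intensities = rep(0, 120), peak_cols = numeric(0),
                             background = 0), class = "base_spectrum")
  expect_warning( # white reference carries no signal either
    sc <- simulate_scan(tiles = 1, n_frames = 5, n_rows = 60, n_cols = 120,
                        base = dark_ill, noise_amplitude = 1, dark_offset = 10,
                        seed = 2),
    "white reference"
  )
  expect_lt(max(abs(sc$cube$values - 10)), 1.01) # offset plus noise only
})

test_that("reflectance guards shapes, flags and invalid denominators", {
  sc <- scan3(n_frames = 4)
  bad <- hsi_cube(array(0, c(4, 80, 159)))
  expect_error(compute_reflectance(bad, sc$refs), class = "desmile_shape_error")
  corrected_cube <- sc$cube
  corrected_cube$meta$corrected <- TRUE
  expect_error(compute_reflectance(corrected_cube, sc$refs),
               class = "desmile_validation_error")
  refs2 <- sc$refs
  refs2$white[5, 7] <- refs2$dark[5, 7] - 1 # invalid pixel
  r <- suppressWarnings(compute_reflectance(sc$cube, refs2))
  expect_true(all(is.na(r$values[, 5, 7])))
  expect_lte(max(r$values, na.rm = TRUE), 2) # clipping ceiling
})

test_that("reflectance is invariant to global illumination rescaling", {
  sc <- scan3(n_frames = 6)
  r0 <- compute_reflectance(sc$cube, sc$refs)
  scaled <- sc$cube
  scaled$values <- 3 * (scaled$values - rep(sc$refs$dark, each = 6)) +
    rep(sc$refs$dark, each = 6)
  refs <- sc$refs
  refs$white <- 3 * (refs$white - refs$dark) + refs$dark
  r1 <- compute_reflectance(scaled, refs)
  expect_equal(r1$values, r0$values, tolerance = 1e-9)
})

test_that("false color separates the tiles at the right scan positions", {
  sc <- scan3()
  rgb <- false_color(sc$cube, bands = c(40, 80, 120))
  expect_equal(dim(rgb), c(60, 80, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  lum <- rowMeans(rgb[, , 1])
  tile_means <- tapply(lum, sc$tile_index, mean)
  expect_true(all(diff(tile_means) > 0.1)) # three distinct brightness levels
  # boundary between tiles lands at the generator-known frame index +/- 1
  jump <- which.max(abs(diff(lum[1:40])))
  expect_lte(abs(jump - max(which(sc$tile_index == 1))), 1)
  # equal bands give a grayscale image
  gray <- false_color(sc$cube, bands = c(80, 80, 80))
  expect_identical(gray[, , 1], gray[, , 2])
  expect_error(false_color(sc$cube, c(1, 2, 999)), class = "desmile_validation_error")
})

test_that("a cube of identical frames maps to identical image rows", {
  b120 <- make_base_spectrum(
    120, data.frame(col = c(30, 60, 90), height = c(800, 500, 700), width = 3))
  f <- generate_ideal_frame(b120, clean_spec(n_rows = 40, n_cols = 120))
  cube <- hsi_cube(aperm(array(f, c(40, 120, 8)), c(3, 1, 2)))
  rgb <- false_color(cube, c(30, 60, 90))
  for (i in 2:8) expect_equal(rgb[i, , ], rgb[1, , ])
})

test_that("spectral angle is a scale-invariant, symmetric pseudo-metric", {
  s1 <- c(1, 2, 3, 4)
  s2 <- c(4, 3, 2, 1)
  expect_equal(spectral_angle(s1, s1), 0)
  expect_equal(spectral_angle(s1, 3 * s1), 0)
  expect_equal(spectral_angle(c(1, 0), c(0, 2)), pi / 2)
  expect_equal(spectral_angle(s1, s2), spectral_angle(s2, s1))
  expect_equal(spectral_angle(5 * s1, 0.1 * s2), spectral_angle(s1, s2))
  expect_error(spectral_angle(s1, c(0, 0, 0, 0)), class = "desmile_domain_error")
  expect_error(spectral_angle(s1, 1:3), class = "desmile_shape_error")
})

test_that("SAM map is zero at the reference pixel and minimal on its tile", {
  # spectrally distinct tiles: falling, flat and rising reflectance curves
  x <- seq(0, 1, length.out = 160)
  spectral_tiles <- rbind(0.7 - 0.5 * x, rep(0.5, 160), 0.2 + 0.6 * x)
  sc <- simulate_scan(tiles = spectral_tiles, n_frames = 60, n_rows = 80,
                      n_cols = 160, seed = 5)
  ref_frame <- which(sc$tile_index == 2)[3]
  ref <- sc$cube$values[ref_frame, 11, ]
  ang <- sam_map(sc$cube, ref)
  expect_equal(dim(ang), c(60, 80))
  expect_true(all(ang >= 0 & ang <= pi))
  expect_lt(ang[ref_frame, 11], 1e-6)
  by_tile <- tapply(rowMeans(ang), sc$tile_index, mean)
  expect_equal(which.min(by_tile), c("2" = 2L))
  # constant cube maps to a constant angle
  const <- hsi_cube(array(rep(1:5, each = 12), c(3, 4, 5)))
  angc <- sam_map(const, rep(1, 5))
  expect_equal(max(angc) - min(angc), 0, tolerance = 1e-9)
})
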