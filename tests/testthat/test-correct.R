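# Shift-distance formula, shift-matrix construction and frame correction.

test_that("shift distance matches the sagitta and is symmetric about b", {
  circ <- list(b = 400, r = 33333.33)
  expect_equal(line_shift_distance(circ, 400), 0)
  d <- line_shift_distance(circ, 800)
  expect_equal(d, 400^2 / (2 * 33333.33), tolerance = 1e-4 / d)
  expect_equal(line_shift_distance(list(b = 0, r = 1000), 100),
               line_shift_distance(list(b = 0, r = 1000), -100))
  expect_error(line_shift_distance(list(b = 0, r = 50), 60),
               class = "desmile_domain_error")
})

test_that("closed form agrees with direct circle-line intersection", {
  # independent oracle: intersect the circle with the horizontal row line in
  # the numerically stable product form, measure to the apex tangent
  set.seed(4)
  for (i in 1:1000) {
    r <- 10^runif(1, 2, 6)
    b <- runif(1, -500, 1300)
    u <- runif(1, -r / 10, r / 10)
    d_cf <- line_shift_distance(list(b = b, r = r), b + u)
    d_bf <- r - sqrt((r - u) * (r + u))
    expect_lt(abs(d_cf - d_bf), 1e-9)
    expect_lt(abs(d_cf - u^2 / (2 * r)), 0.01 * max(d_cf, 1e-12))
  }
})

make_model <- function(frame, estimates, params = small_params()) {
  correction_model(detect_lines(frame, estimates, params))
}

test_that("a center-row arc yields a shift profile symmetric about the center", {
  n_rows <- 401
  line <- structure(list(line_id = 1, estimate_col = 150,
                         points = arc_points(1:n_rows, a = 150 + 2e4, b = 201, r = 2e4),
                         coverage = 1), class = "emission_line")
  m <- correction_model(list(line))
  s <- build_shift_matrix(m, n_rows, 300)
  expect_equal(s[201, 150], 0, tolerance = 1e-9)
  expect_equal(s[1, 150], s[401, 150], tolerance = 1e-9)
  prov <- attr(s, "provenance")
  expect_equal(prov$mode, "apex")
})

test_that("near-straight tilted lines shift linearly with slope tan(theta)", {
  b <- small_base()
  n_rows <- 400
  s_dist <- make_distortion_shift_matrix(distortion_spec(tilt_deg = 1), n_rows, 300)
  f <- distort_frame(generate_ideal_frame(b, small_spec(n_rows = n_rows, seed = 8)),
                     s_dist, fill = 10)
  m <- make_model(f, small_estimates())
  s <- build_shift_matrix(m, n_rows, 300)
  anchor <- round(attr(s, "provenance")$anchor_col[2])
  slope <- unname(coef(lm(s[, anchor] ~ seq_len(n_rows)))[2])
  expect_equal(abs(slope), tan(pi / 180), tolerance = 0.05)
})

test_that("shifts interpolate linearly between anchors and clamp outside", {
  lines <- lapply(c(1, 2), function(i) {
    structure(list(line_id = i, estimate_col = c(100, 200)[i],
                   points = arc_points(1:201, a = c(100, 200)[i] + 1e4 * i,
                                       b = 101, r = 1e4 * i),
                   coverage = 1), class = "emission_line")
  })
  s <- build_shift_matrix(correction_model(lines), 201, 300)
  a <- attr(s, "provenance")$anchor_col
  expect_true(all(a > 90 & a < 210))
  for (y in c(1, 51, 201)) {
    # linear in x between the anchors: three interior columns are collinear
    expect_equal(s[y, 150],
                 approx(c(120, 180), s[y, c(120, 180)], xout = 150)$y,
                 tolerance = 1e-9)
    # constant beyond the outermost anchors
    expect_equal(s[y, 5], s[y, floor(a[1])], tolerance = 1e-9)
    expect_equal(s[y, 295], s[y, ceiling(a[2])], tolerance = 1e-9)
  }
})

test_that("applying a zero matrix is the identity and resampling is linear", {
  f1 <- matrix(rnorm(80 * 90), 80, 90)
  f2 <- matrix(rnorm(80 * 90), 80, 90)
  s <- matrix(rnorm(80 * 90, sd = 2), 80, 90)
  expect_identical(apply_shift(f1, matrix(0, 80, 90)), f1)
  expect_equal(apply_shift(f1 + f2, s, fill = 0),
               apply_shift(f1, s, fill = 0) + apply_shift(f2, s, fill = 0),
               tolerance = 1e-12)
})

test_that("distorting then applying the exact negation restores the interior", {
  # broad peaks keep the double linear-interpolation loss in the small-error
  # regime the 1% bound describes
  b <- make_base_spectrum(
    300, data.frame(col = c(80, 150, 230), height = c(1000, 800, 900), width = 8))
  f <- generate_ideal_frame(b, clean_spec(n_rows = 400))
  s <- make_distortion_shift_matrix(
    distortion_spec(tilt_deg = 1, curvature = 1e-4), 400, 300)
  round_trip <- apply_shift(distort_frame(f, s, fill = 30), -s, fill = 30)
  interior <- cbind(rep(1:400, 200), rep(51:250, each = 400))
  # double interpolation loss only, relative to the frame's intensity scale
  rel <- abs(round_trip[interior] - f[interior]) / max(f)
  expect_lt(max(rel), 0.01)
})

test_that("correcting an ideal frame is a near no-op", {
  f <- generate_ideal_frame(small_base(), small_spec(seed = 31))
  res <- correct_frame(f, small_estimates(), small_params())
  expect_lt(max(res$diagnostics$mean_abs_shift), 0.2)
  expect_true(all(abs(res$diagnostics$tilt_post) < 0.05, na.rm = TRUE))
})

test_that("tilt-only distortion is corrected below 0.05 degrees", {
  b <- small_base()
  n_rows <- 400
  s <- make_distortion_shift_matrix(distortion_spec(tilt_deg = 1), n_rows, 300)
  f <- distort_frame(generate_ideal_frame(b, small_spec(n_rows = n_rows, seed = 13)),
                     s, fill = 10)
  res <- correct_frame(f, small_estimates(), small_params())
  expect_true(all(abs(res$diagnostics$tilt_pre + 1) < 0.05)) # metric reads -1 deg
  expect_true(all(abs(res$diagnostics$tilt_post) < 0.05))
})

test_that("correction is idempotent at the metric fluctuation floor", {
  b <- small_base()
  n_rows <- 400
  s <- make_distortion_shift_matrix(
    distortion_spec(tilt_deg = 1, curvature = 1e-4), n_rows, 300)
  f <- distort_frame(generate_ideal_frame(b, small_spec(n_rows = n_rows, seed = 17)),
                     s, fill = 10)
  res1 <- correct_frame(f, small_estimates(), small_params())
  est2 <- round(sort(res1$diagnostics$target_col))
  res2 <- correct_frame(res1$frame, est2, small_params())
  expect_true(all(abs(res2$diagnostics$tilt_post - res2$diagnostics$tilt_pre) < 0.05))
  expect_true(all(abs(res2$diagnostics$kappa_post - res2$diagnostics$kappa_pre) < 2e-6))
})

test_that("a degenerate (already straight) line contributes zero shift", {
  f <- generate_ideal_frame(small_base(), clean_spec()) # perfectly vertical lines
  res <- correct_frame(f, small_estimates(), small_params())
  expect_true(all(res$diagnostics$mode == "straight"))
  expect_true(all(res$diagnostics$mean_abs_shift == 0))
  expect_equal(res$frame, f)
})

test_that("correction moves emission lines off their original columns", {
  # consequence: wavelength calibration only makes sense after correction
  b <- small_base()
  n_rows <- 400
  s <- make_distortion_shift_matrix(
    distortion_spec(tilt_deg = 1, curvature = 1e-4), n_rows, 300)
  f <- distort_frame(generate_ideal_frame(b, small_spec(n_rows = n_rows, seed = 23)),
                     s, fill = 10)
  res <- correct_frame(f, small_estimates(), small_params())
  moved <- abs(res$diagnostics$target_col - res$diagnostics$anchor_col)
  expect_gt(max(moved), 1)
})
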