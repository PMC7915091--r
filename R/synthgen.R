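## Synthetic sensor frames: an emission-line base spectrum repeated over the
## illuminated rows with Gaussian per-row gains and uniform pixel noise, then
## distorted by running the correction algorithm in reverse (a known tilt +
## smile shift field applied by row-wise interpolation).

#' Build a base spectrum with Gaussian emission peaks
#'
#' The base spectrum stands in for the mean-row spectrogram of a sharp-lined
#' light source (e.g. a fluorescent lamp): a low constant background plus one
#' Gaussian profile per emission line.
#'
#' @param n_cols Number of spectral pixels.
#' @param peaks Peak table: a data frame (or list of length-3 vectors) with
#'   columns `col` (center column, 1-based), `height` (counts above
#'   background) and `width` (Gaussian sigma, px).
#' @param background Constant background level (counts).
#' @return A `base_spectrum`: list with `intensities` (length `n_cols`) and
#'   `peak_cols`.
#' @examples
#' b <- make_base_spectrum(200, data.frame(col = 100, height = 1000, width = 3))
#' which.max(b$intensities) # 100
#' @export
make_base_spectrum <- function(n_cols, peaks = NULL, background = 30) {
  if (n_cols < 2) stop_validation("`n_cols` must be at least 2")
  if (is.null(peaks) || (is.data.frame(peaks) && nrow(peaks) == 0) ||
      (is.list(peaks) && !is.data.frame(peaks) && length(peaks) == 0)) {
    pk <- data.frame(col = numeric(0), height = numeric(0), width = numeric(0))
  } else if (is.data.frame(peaks)) {
    pk <- peaks
  } else {
    pk <- as.data.frame(do.call(rbind, lapply(peaks, function(p) {
      stats::setNames(as.numeric(p[1:3]), c("col", "height", "width"))
    })))
  }
  if (nrow(pk) > 0) {
    if (any(pk$col < 1 | pk$col > n_cols))
      stop_validation("peak columns must lie in [1, n_cols]")
    if (any(pk$height <= 0)) stop_validation("peak heights must be positive")
    if (any(pk$width < 1)) stop_validation("peak widths must be >= 1 px")
    if (nrow(pk) > 1) {
      gaps <- diff(sort(pk$col))
      min_sep <- 3 * max(pk$width)
      if (any(gaps < min_sep))
        stop_validation(sprintf(
          "emission peaks closer than 3 * max(width) = %.1f px are not separable",
          min_sep
        ))
    }
  }
  x <- seq_len(n_cols)
  intens <- rep(background, n_cols)
  for (i in seq_len(nrow(pk)))
    intens <- intens + pk$height[i] * exp(-(x - pk$col[i])^2 / (2 * pk$width[i]^2))
  structure(
    list(intensities = intens, peak_cols = sort(pk$col), background = background),
    class = "base_spectrum"
  )
}

#' Default emission-line base spectrum
#'
#' Six Gaussian emission lines on a 30-count background. The four interior
#' lines at columns 629, 762, 980 and 1517 are the bands used for correction
#' throughout the package examples; the line at 980 is deliberately weaker
#' (it is the hardest to track). Two extra lines (350, 1800) are bystanders
#' that let the post-correction displacement of unused lines be observed.
#'
#' @param n_cols Number of spectral pixels (default 2000, the spectral crop).
#' @return A [make_base_spectrum()] object.
#' @export
default_base_spectrum <- function(n_cols = 2000) {
  make_base_spectrum(
    n_cols,
    data.frame(
      col = c(350, 629, 762, 980, 1517, 1800),
      height = c(700, 1100, 950, 500, 1000, 850),
      width = c(3, 3, 3, 4, 3, 3)
    )
  )
}

#' Columns of the four correction bands of [default_base_spectrum()]
#' @return Integer vector `c(629, 762, 980, 1517)`.
#' @export
default_band_estimates <- function() c(629, 762, 980, 1517)

#' Smooth broadband illumination spectrum
#'
#' A broad Gaussian hump with a raised floor, emulating halogen-lamp
#' illumination for simulated scans (no sharp emission lines).
#'
#' @param n_cols Number of spectral pixels.
#' @param peak_height Maximum intensity (counts).
#' @return A `base_spectrum` with no emission peaks.
#' @export
illumination_spectrum <- function(n_cols = 400, peak_height = 1000) {
  x <- seq_len(n_cols)
  mu <- 0.55 * n_cols
  sigma <- 0.30 * n_cols
  intens <- peak_height * (0.15 + 0.85 * exp(-(x - mu)^2 / (2 * sigma^2)))
  structure(
    list(intensities = intens, peak_cols = numeric(0), background = 0),
    class = "base_spectrum"
  )
}

#' Frame generation parameters
#'
#' @param n_rows,n_cols Frame size in pixels (spatial x spectral). The
#'   defaults match the 800 x 2000 crop of the illuminated sensor area.
#' @param illuminated_rows Inclusive `c(first, last)` row range receiving the
#'   base spectrum; remaining rows carry only noise. Default: all rows (the
#'   crop is the illuminated area).
#' @param gain_sigma Standard deviation of the Gaussian per-row multiplicative
#'   gain (mean 1, dimensionless).
#' @param noise_amplitude Half-width of the zero-mean uniform additive pixel
#'   noise (counts). `NULL` resolves at generation time to 1% of the maximum
#'   peak height of the base spectrum.
#' @param seed Integer RNG seed; `NULL` uses the current RNG stream.
#' @return A validated `frame_spec` list.
#' @export
frame_spec <- function(n_rows = 800, n_cols = 2000,
                       illuminated_rows = c(1, n_rows),
                       gain_sigma = 0.02, noise_amplitude = NULL,
                       seed = NULL) {
  if (n_rows < 8 || n_cols < 8) stop_validation("frame must be at least 8 x 8 px")
  if (length(illuminated_rows) != 2 ||
      illuminated_rows[1] < 1 || illuminated_rows[2] > n_rows ||
      illuminated_rows[1] > illuminated_rows[2])
    stop_validation("`illuminated_rows` must be c(first, last) within [1, n_rows]")
  if (gain_sigma < 0) stop_validation("`gain_sigma` must be >= 0")
  if (!is.null(noise_amplitude) && noise_amplitude < 0)
    stop_validation("`noise_amplitude` must be >= 0")
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      illuminated_rows = as.integer(illuminated_rows),
      gain_sigma = gain_sigma, noise_amplitude = noise_amplitude,
      seed = seed
    ),
    class = "frame_spec"
  )
}

resolve_noise_amplitude <- function(spec, base) {
  if (!is.null(spec$noise_amplitude)) return(spec$noise_amplitude)
  peak <- max(base$intensities) - base$background
  if (peak <= 0) peak <- max(base$intensities)
  0.01 * peak
}

#' Generate an ideal (undistorted) synthetic frame
#'
#' Each illuminated row is `gain_i * base` plus zero-mean uniform noise, with
#' `gain_i ~ N(1, gain_sigma^2)`. Rows outside the illuminated range are
#' filled with uniform noise on `[0, 2 * noise_amplitude]` (a purely dark
#' sensor region). Bit-reproducible given `spec$seed`.
#'
#' @param base A [make_base_spectrum()] object with `length == spec$n_cols`.
#' @param spec A [frame_spec()].
#' @return Numeric matrix `spec$n_rows` x `spec$n_cols`.
#' @export
generate_ideal_frame <- function(base, spec) {
  if (!inherits(base, "base_spectrum")) stop_validation("`base` must be a base_spectrum")
  if (length(base$intensities) != spec$n_cols)
    stop_shape("base spectrum length must equal spec$n_cols")
  amp <- resolve_noise_amplitude(spec, base)
  with_seed(spec$seed, {
    n <- spec$n_rows
    m <- spec$n_cols
    il <- seq.int(spec$illuminated_rows[1], spec$illuminated_rows[2])
    frame <- matrix(0, n, m)
    dark <- setdiff(seq_len(n), il)
    if (length(dark) > 0 && amp > 0)
      frame[dark, ] <- matrix(stats::runif(length(dark) * m, 0, 2 * amp),
                              length(dark), m)
    gains <- stats::rnorm(length(il), mean = 1, sd = spec$gain_sigma)
    signal <- outer(gains, base$intensities)
    if (amp > 0)
      signal <- signal + matrix(stats::runif(length(il) * m, -amp, amp),
                                length(il), m)
    frame[il, ] <- signal
    frame
  })
}

#' Distortion parameters for synthetic frames
#'
#' @param tilt_deg Tilt angle in degrees. Positive tilt leans the top of an
#'   emission line toward larger `x`.
#' @param curvature Signed curvature kappa in 1/px. Positive curvature bows
#'   the line's apex toward larger `x`. The generating arc radius is
#'   `1 / abs(curvature)`.
#' @param center_row_b Row coordinate of the generating circle center; `NULL`
#'   defaults to the frame's vertical center, which makes pure smile
#'   symmetric top/bottom.
#' @param reference_row Row at which the tilt shift is zero; `NULL` defaults
#'   to the frame's vertical center.
#' @return A validated `distortion_spec` list.
#' @export
distortion_spec <- function(tilt_deg = 0, curvature = 0,
                            center_row_b = NULL, reference_row = NULL) {
  if (abs(tilt_deg) >= 45) stop_validation("`tilt_deg` must satisfy |tilt| < 45")
  if (abs(curvature) >= 1e-2) stop_validation("`curvature` must satisfy |kappa| < 1e-2")
  structure(
    list(tilt_deg = tilt_deg, curvature = curvature,
         center_row_b = center_row_b, reference_row = reference_row),
    class = "distortion_spec"
  )
}

## Exact arc sagitta: horizontal distance from the arc to the vertical
## tangent line at its apex row, at vertical offset u = y - b from the
## center row (Eq.-style closed form; see line_shift_distance()).
arc_distance <- function(u, r) r * (1 - cos(asin(u / r)))

#' Build a distortive shift matrix for known tilt and curvature
#'
#' The distortion field is
#' `s(y) = tan(tilt) * (y - reference_row) + sign(kappa) * d_arc(y)` with
#' `d_arc(y) = r * (1 - cos(asin((y - b) / r)))`, `r = 1 / abs(kappa)`,
#' constant across columns (one global field per frame). Applying it with
#' [distort_frame()] moves features by `-s`, producing the stated tilt and
#' smile. The tilt and arc terms are exactly additive.
#'
#' @param d A [distortion_spec()].
#' @param n_rows,n_cols Target frame size.
#' @return `n_rows` x `n_cols` shift matrix (px).
#' @export
make_distortion_shift_matrix <- function(d, n_rows, n_cols) {
  if (!inherits(d, "distortion_spec")) stop_validation("`d` must be a distortion_spec")
  center <- (n_rows + 1) / 2
  ref <- if (is.null(d$reference_row)) center else d$reference_row
  b <- if (is.null(d$center_row_b)) center else d$center_row_b
  y <- seq_len(n_rows)
  s <- tan(d$tilt_deg * pi / 180) * (y - ref)
  if (d$curvature != 0) {
    r <- 1 / abs(d$curvature)
    if (r <= n_rows)
      stop_validation("arc radius 1/|kappa| must exceed n_rows (arc would fold)")
    s <- s + sign(d$curvature) * arc_distance(y - b, r)
  }
  matrix(s, n_rows, n_cols)
}

#' Apply a distortive shift matrix to a frame
#'
#' Resamples each row by linear interpolation at `x + s[y, x]`; samples
#' outside the frame take `fill` (default: the frame's median, i.e. the
#' background/noise level).
#'
#' @param frame Numeric matrix.
#' @param s Shift matrix of identical shape.
#' @param fill Out-of-range fill value.
#' @return Distorted frame, same shape.
#' @export
distort_frame <- function(frame, s, fill = NULL) {
  if (is.null(fill)) fill <- default_fill(frame)
  resample_rows(frame, s, fill)
}

#' Generate a batch-ready distorted synthetic frame in one call
#'
#' Convenience wrapper: ideal frame from `base` + `spec`, then distorted by
#' `dist`. The distortion matrix can be precomputed and passed via
#' `shift` to avoid rebuilding it per frame.
#'
#' @inheritParams generate_ideal_frame
#' @param dist A [distortion_spec()] (ignored when `shift` is given).
#' @param shift Optional precomputed distortion shift matrix.
#' @return Distorted frame matrix.
#' @export
generate_distorted_frame <- function(base, spec, dist = distortion_spec(),
                                     shift = NULL) {
  frame <- generate_ideal_frame(base, spec)
  if (is.null(shift))
    shift <- make_distortion_shift_matrix(dist, spec$n_rows, spec$n_cols)
  amp <- resolve_noise_amplitude(spec, base)
  distort_frame(frame, shift, fill = amp) # median of U(0, 2*amp) dark noise
}
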