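## Image-cube plumbing and downstream products: reflectance from dark/white
## references, false-color reconstruction, spectral angle mapping, and a
## synthetic push-broom scan simulator.

#' Construct a hyperspectral image cube
#'
#' @param values 3D numeric array with dims `(scan_index, y, x)`.
#' @param exposure_ms Exposure time per frame (ms).
#' @param scan_length,scan_velocity Scan geometry in arbitrary units.
#' @param corrected Logical: has the smile correction been applied?
#' @param crop Optional crop window `c(x0, x1, y0, y1)` recorded as metadata.
#' @param units Value units, e.g. `"counts"` or `"reflectance"`.
#' @param extra Named list of additional metadata (e.g. a tile mask).
#' @return An `hsi_cube` object.
#' @export
hsi_cube <- function(values, exposure_ms = NA_real_, scan_length = NA_real_,
                     scan_velocity = NA_real_, corrected = FALSE,
                     crop = NULL, units = "counts", extra = list()) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_shape("`values` must be a 3D array (scan_index, y, x)")
  structure(
    list(values = values,
         meta = list(exposure_ms = exposure_ms, scan_length = scan_length,
                     scan_velocity = scan_velocity,
                     corrected = isTRUE(corrected), crop = crop,
                     units = units, extra = extra)),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hsi_cube> %d frames of %d x %d px (%s, %s)\n",
    d[1], d[2], d[3], x$meta$units,
    if (x$meta$corrected) "corrected" else "uncorrected"
  ))
  invisible(x)
}

#' Dark and white reference frames
#'
#' @param dark,white Frame matrices of identical shape.
#' @param corrected Logical: corrected with the same shift matrix as the
#'   cubes they will calibrate?
#' @return A `reference_frames` object.
#' @export
reference_frames <- function(dark, white, corrected = FALSE) {
  if (!is.matrix(dark) || !is.matrix(white) || !identical(dim(dark), dim(white)))
    stop_shape("`dark` and `white` must be matrices of identical shape")
  if (mean(white > dark) < 0.99)
    warning("white reference exceeds dark on fewer than 99% of pixels")
  structure(list(dark = dark, white = white, corrected = isTRUE(corrected)),
            class = "reference_frames")
}

#' Reflectance from dark and white references
#'
#' `R = (S - dark) / (white - dark)` per pixel, clipped to `[0, r_max]`.
#' Pixels where `white - dark <= 0` become `NA`. The cube and the references
#' must agree on whether the smile correction has been applied (corrected
#' data must never be ratioed against uncorrected references).
#'
#' @param cube An [hsi_cube()] in counts.
#' @param refs A [reference_frames()] of matching frame shape.
#' @param r_max Clipping ceiling (default 2; specular highlights can push
#'   reflectance above 1).
#' @return An [hsi_cube()] with `units = "reflectance"`.
#' @export
compute_reflectance <- function(cube, refs, r_max = 2) {
  d <- dim(cube$values)
  if (!identical(dim(refs$dark), d[2:3]))
    stop_shape("reference frames do not match the cube's frame shape")
  if (!identical(cube$meta$corrected, refs$corrected))
    stop_validation(
      "cube and references disagree on the `corrected` flag; calibrate corrected data with corrected references"
    )
  denom <- refs$white - refs$dark
  denom[denom <= 0] <- NA_real_
  n_scan <- d[1]
  darkA <- aperm(array(refs$dark, c(d[2], d[3], n_scan)), c(3, 1, 2))
  denomA <- aperm(array(denom, c(d[2], d[3], n_scan)), c(3, 1, 2))
  r <- (cube$values - darkA) / denomA
  r <- pmin(pmax(r, 0), r_max)
  out <- cube
  out$values <- array(r, d)
  out$meta$units <- "reflectance"
  out
}

#' False-color image from three spectral bands
#'
#' Extracts three spectral columns across all frames and normalizes each
#' channel independently to `[0, 1]` between its 1st and 99th percentiles.
#'
#' @param cube An [hsi_cube()].
#' @param bands Integer vector `(xR, xG, xB)` of spectral column indices.
#' @return Array `(scan_index, y, 3)` of channel values in `[0, 1]`.
#' @export
false_color <- function(cube, bands) {
  d <- dim(cube$values)
  if (length(bands) != 3 || any(bands < 1 | bands > d[3]))
    stop_validation(sprintf("`bands` must be 3 column indices in [1, %d]", d[3]))
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    img <- cube$values[, , bands[ch]]
    q <- stats::quantile(img, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
    out[, , ch] <- if (q[2] > q[1]) pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1) else 0
  }
  out
}

#' Spectral angle between two spectra
#'
#' `acos(<s1, s2> / (||s1|| * ||s2||))`, clamped to `[0, pi]`. Scale
#' invariant in both arguments.
#'
#' @param s1,s2 Numeric vectors of equal length and non-zero norm.
#' @return Angle in radians.
#' @export
spectral_angle <- function(s1, s2) {
  if (length(s1) != length(s2)) stop_shape("spectra must have equal length")
  n1 <- sqrt(sum(s1^2))
  n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) stop_domain("spectral angle undefined for zero-norm input")
  acos(pmin(pmax(sum(s1 * s2) / (n1 * n2), -1), 1))
}

#' Spectral angle map against a reference spectrum
#'
#' Maps [spectral_angle()] over all spatial pixels `(scan_index, y)` of a
#' cube. Pixels whose own spectrum has zero norm yield `NA`.
#'
#' @param cube An [hsi_cube()].
#' @param reference_spectrum Numeric vector of length `dim(values)[3]`.
#' @return Matrix `(scan_index, y)` of angles in `[0, pi]`.
#' @export
sam_map <- function(cube, reference_spectrum) {
  d <- dim(cube$values)
  if (length(reference_spectrum) != d[3])
    stop_shape("reference spectrum length must equal the cube's spectral size")
  nref <- sqrt(sum(reference_spectrum^2))
  if (nref == 0) stop_domain("spectral angle undefined for zero-norm reference")
  M <- matrix(cube$values, d[1] * d[2], d[3]) # rows indexed by (scan, y)
  norms <- sqrt(rowSums(M^2))
  cosang <- (M %*% reference_spectrum) / (norms * nref)
  cosang[norms == 0] <- NA_real_
  matrix(acos(pmin(pmax(cosang, -1), 1)), d[1], d[2])
}

#' Simulate a push-broom scan of a tiled reflectance scene
#'
#' Synthetic stand-in for scanning a flat test target (e.g. color-checker
#' tiles) under broadband illumination. Scan position maps to tile index;
#' each frame is `dark_offset + gain_row * reflectance * illumination +
#' uniform noise`, optionally distorted with a tilt/smile field. Dark and
#' white reference frames are generated consistently (white = reflectance 1).
#'
#' @param tiles Tile reflectances in scan order: either a numeric vector of
#'   spectrally flat reflectances (e.g. `c(0.2, 0.5, 0.8)`) or a
#'   `k x n_cols` matrix of per-tile spectral reflectance curves (colored
#'   tiles).
#' @param n_frames Number of scan positions (>= 1).
#' @param n_rows,n_cols Frame size.
#' @param base Illumination spectrum ([illumination_spectrum()] by default).
#' @param distortion Optional [distortion_spec()] applied to every frame and
#'   to the references.
#' @param gain_sigma,noise_amplitude As in [frame_spec()].
#' @param dark_offset Constant sensor offset (counts); default 5% of the
#'   illumination maximum.
#' @param tile_breaks Optional increasing frame indices of the first frame of
#'   tiles 2..k; default splits the scan evenly.
#' @param seed Master seed; frame `i` uses `seed + i`, the references
#'   `seed - 1` (white) and `seed - 2` (dark).
#' @return List with `cube` (an [hsi_cube()], tile index in
#'   `meta$extra$tile_index`), `refs` ([reference_frames()]) and
#'   `tile_index` (integer vector, one entry per frame).
#' @export
simulate_scan <- function(tiles, n_frames, n_rows = 160, n_cols = 320,
                          base = NULL, distortion = NULL,
                          gain_sigma = 0.02, noise_amplitude = NULL,
                          dark_offset = NULL, tile_breaks = NULL, seed = 1) {
  if (n_frames < 1) stop_validation("`n_frames` must be >= 1")
  if (length(tiles) < 1) stop_validation("need at least one tile reflectance")
  if (is.null(base)) base <- illumination_spectrum(n_cols)
  if (length(base$intensities) != n_cols)
    stop_shape("illumination spectrum length must equal n_cols")
  peak <- max(base$intensities)
  if (is.null(noise_amplitude)) noise_amplitude <- 0.01 * peak
  if (is.null(dark_offset)) dark_offset <- 0.05 * peak
  if (is.matrix(tiles)) {
    if (ncol(tiles) != n_cols)
      stop_shape("spectral tile matrix must have n_cols columns")
    tile_refl <- tiles
  } else {
    tile_refl <- matrix(tiles, length(tiles), n_cols)
  }
  k <- nrow(tile_refl)
  if (is.null(tile_breaks)) {
    tile_index <- if (k == 1) rep(1L, n_frames)
      else as.integer(cut(seq_len(n_frames), breaks = k, labels = FALSE))
  } else {
    if (length(tile_breaks) != k - 1 || is.unsorted(tile_breaks, strictly = TRUE))
      stop_validation("`tile_breaks` must be k - 1 strictly increasing frame indices")
    tile_index <- 1L + rowSums(outer(seq_len(n_frames), tile_breaks, ">="))
  }
  shift <- if (!is.null(distortion))
    make_distortion_shift_matrix(distortion, n_rows, n_cols)

  gen <- function(rho, s) { # one frame at reflectance rho
    with_seed(s, {
      gains <- stats::rnorm(n_rows, 1, gain_sigma)
      f <- dark_offset + outer(gains, rho * base$intensities) +
        matrix(stats::runif(n_rows * n_cols, -noise_amplitude, noise_amplitude),
               n_rows, n_cols)
      if (!is.null(shift)) f <- resample_rows(f, shift, fill = dark_offset)
      f
    })
  }

  values <- array(0, c(n_frames, n_rows, n_cols))
  for (i in seq_len(n_frames))
    values[i, , ] <- gen(tile_refl[tile_index[i], ], seed + i)
  white <- gen(1, seed - 1)
  dark <- gen(0, seed - 2)
  cube <- hsi_cube(values, corrected = FALSE, units = "counts",
                   extra = list(tile_index = tile_index, tiles = tiles))
  list(cube = cube,
       refs = reference_frames(dark, white, corrected = FALSE),
       tile_index = tile_index)
}
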