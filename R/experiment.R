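## Batch validation on synthetic frames: generate distorted frames, correct
## each, and summarize the tilt and curvature metrics before and after
## correction (a Table-1-style report), plus a side-by-side cube comparison.

#' Run the synthetic distort-and-correct experiment
#'
#' Generates `n_frames` synthetic frames (emission-line base spectrum,
#' Gaussian per-row gains, uniform pixel noise), distorts each with the
#' given tilt and curvature, runs the full correction
#' (detect -> circle fit -> shift matrix -> resample), re-detects the lines
#' on the corrected frame, and aggregates the per-line tilt and curvature
#' metrics before and after correction. Frames where detection fails are
#' counted, not fatal. Fully reproducible from `master_seed` (frame `i`
#' uses seed `master_seed + i`).
#'
#' @param n_frames Number of frames.
#' @param master_seed Integer master seed.
#' @param tilt_deg,curvature Distortion parameters (defaults: the 1 degree
#'   tilt and 3e-5 1/px curvature typical of real frames).
#' @param n_rows,n_cols Frame size (defaults: the 800 x 2000 sensor crop).
#' @param base Base spectrum; default [default_base_spectrum()].
#' @param estimates Emission-line column estimates; default the four
#'   correction bands 629, 762, 980, 1517.
#' @param params A [detection_params()].
#' @param gain_sigma,noise_amplitude Frame noise model (see [frame_spec()]).
#' @param out_csv Optional path: write the summary as CSV.
#' @return List with `summary` (per-line and total means with standard
#'   deviations of the mean for tilt and curvature, original and corrected,
#'   plus mean absolute applied shift), `details` (per frame x line metric
#'   table), `n_success` (frames with successful detection) and `n_frames`.
#' @export
run_experiment_synthetic <- function(n_frames, master_seed,
                                     tilt_deg = 1, curvature = 3e-5,
                                     n_rows = 800, n_cols = 2000,
                                     base = NULL, estimates = NULL,
                                     params = detection_params(),
                                     gain_sigma = 0.02,
                                     noise_amplitude = NULL,
                                     out_csv = NULL) {
  if (is.null(base)) base <- default_base_spectrum(n_cols)
  if (is.null(estimates)) estimates <- default_band_estimates()
  dist <- distortion_spec(tilt_deg = tilt_deg, curvature = curvature)
  shift <- make_distortion_shift_matrix(dist, n_rows, n_cols)
  details <- vector("list", n_frames)
  n_success <- 0L
  for (i in seq_len(n_frames)) {
    fs <- frame_spec(n_rows = n_rows, n_cols = n_cols, gain_sigma = gain_sigma,
                     noise_amplitude = noise_amplitude, seed = master_seed + i)
    frame <- generate_distorted_frame(base, fs, shift = shift)
    res <- tryCatch(correct_frame(frame, estimates, params),
                    desmile_detection_failure = function(e) NULL)
    if (is.null(res)) next
    n_success <- n_success + 1L
    details[[i]] <- cbind(frame_id = i, res$diagnostics)
  }
  details <- do.call(rbind, details)
  if (is.null(details))
    stop_detection("emission-line detection failed on every generated frame")

  summarize <- function(d) {
    sdm <- function(v) stats::sd(v) / sqrt(sum(is.finite(v)))
    data.frame(
      n = nrow(d),
      tilt_orig_mean = mean(d$tilt_pre), tilt_orig_sdm = sdm(d$tilt_pre),
      tilt_corr_mean = mean(d$tilt_post, na.rm = TRUE),
      tilt_corr_sdm = sdm(d$tilt_post),
      kappa_orig_mean = mean(d$kappa_pre), kappa_orig_sdm = sdm(d$kappa_pre),
      kappa_corr_mean = mean(d$kappa_post, na.rm = TRUE),
      kappa_corr_sdm = sdm(d$kappa_post),
      mean_abs_shift = mean(d$mean_abs_shift)
    )
  }
  per_line <- do.call(rbind, lapply(split(details, details$estimate_col), summarize))
  per_line <- cbind(band = as.numeric(rownames(per_line)), per_line)
  rownames(per_line) <- NULL
  total <- cbind(band = NA_real_, summarize(details))
  summary <- rbind(per_line, total)
  summary$scope <- c(rep("line", nrow(per_line)), "total")
  if (!is.null(out_csv))
    utils::write.csv(summary, out_csv, row.names = FALSE)
  list(summary = summary, details = details,
       n_success = n_success, n_frames = n_frames)
}

#' Side-by-side comparison of two image cubes
#'
#' Emits paired false-color PNGs and per-band difference statistics for two
#' cubes of identical shape (typically uncorrected vs corrected data).
#'
#' @param cube_a,cube_b [hsi_cube()]s of identical dimensions.
#' @param bands Three spectral band indices for the false-color views.
#' @param out_dir Optional directory for `a.png`, `b.png` and
#'   `band_diffs.csv`; skipped when `NULL`.
#' @return Data frame `band, mean_abs_diff, max_abs_diff, rmse` over all
#'   spectral bands, invisibly when `out_dir` is given.
#' @export
compare_report <- function(cube_a, cube_b, bands, out_dir = NULL) {
  if (!identical(dim(cube_a$values), dim(cube_b$values)))
    stop_shape("cubes must have identical dimensions")
  d <- dim(cube_a$values)
  if (any(bands < 1 | bands > d[3]))
    stop_validation(sprintf("`bands` must lie in [1, %d]", d[3]))
  diff <- cube_a$values - cube_b$values
  per_band <- data.frame(
    band = seq_len(d[3]),
    mean_abs_diff = apply(abs(diff), 3, mean),
    max_abs_diff = apply(abs(diff), 3, max),
    rmse = sqrt(apply(diff^2, 3, mean))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_false_color_png(false_color(cube_a, bands), file.path(out_dir, "a.png"))
    write_false_color_png(false_color(cube_b, bands), file.path(out_dir, "b.png"))
    utils::write.csv(per_band, file.path(out_dir, "band_diffs.csv"),
                     row.names = FALSE)
    return(invisible(per_band))
  }
  per_band
}
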