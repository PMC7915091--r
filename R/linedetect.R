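## Emission-line location: a peak finder runs over every sensor row and the
## per-row peaks are grouped into per-line point sets around user-supplied
## column estimates.

#' Peak-detection parameters
#'
#' @param window_halfwidth Half-width (px) of the column window searched
#'   around each emission-line estimate. Must cover the expected wander of a
#'   line (tilt of 2 degrees over 800 rows moves a line by about 14 px from
#'   its center column).
#' @param min_prominence Minimum peak prominence (counts): the drop from the
#'   peak to the higher of the valley floors on its two sides.
#' @param smoothing_halfwidth Moving-average half-width (px) applied to each
#'   row before peak finding; 0 disables smoothing.
#' @param min_coverage Minimum fraction of illuminated rows on which a line
#'   must yield a peak to be accepted.
#' @param subpixel Refine peak positions with a three-point parabola fit.
#' @return A validated `detection_params` list.
#' @export
detection_params <- function(window_halfwidth = 20, min_prominence = 50,
                             smoothing_halfwidth = 0, min_coverage = 0.8,
                             subpixel = TRUE) {
  if (window_halfwidth < 1) stop_validation("`window_halfwidth` must be >= 1")
  if (min_coverage <= 0 || min_coverage > 1)
    stop_validation("`min_coverage` must be in (0, 1]")
  if (smoothing_halfwidth < 0) stop_validation("`smoothing_halfwidth` must be >= 0")
  if (min_prominence <= 0) stop_validation("`min_prominence` must be > 0")
  structure(
    list(window_halfwidth = as.integer(window_halfwidth),
         min_prominence = min_prominence,
         smoothing_halfwidth = as.integer(smoothing_halfwidth),
         min_coverage = min_coverage, subpixel = isTRUE(subpixel)),
    class = "detection_params"
  )
}

## Moving average with edge replication, length-preserving.
smooth_vec <- function(v, halfwidth) {
  if (halfwidth <= 0) return(v)
  k <- 2 * halfwidth + 1
  padded <- c(rep(v[1], halfwidth), v, rep(v[length(v)], halfwidth))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[
    (halfwidth + 1):(halfwidth + length(v))]
}

## Parabolic vertex through (p-1, p, p+1); offset clamped to half a pixel.
parabolic_offset <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  off <- ifelse(abs(den) < .Machine$double.eps, 0, 0.5 * (vm - vp) / den)
  pmax(pmin(off, 0.5), -0.5)
}

#' Find peaks in a single sensor row
#'
#' Locates strict local maxima (after optional smoothing), computes their
#' prominence (peak height above the higher of the two flanking valley
#' floors, searching to the next higher sample or the row end) and keeps
#' peaks with prominence at or above `params$min_prominence`. With
#' `params$subpixel` the position is refined by fitting a parabola through
#' the peak sample and its two neighbours.
#'
#' @param row_values Numeric vector of one row's intensities.
#' @param params A [detection_params()].
#' @return Data frame with columns `col` (possibly fractional) and
#'   `prominence`; zero rows if nothing qualifies.
#' @export
find_row_peaks <- function(row_values, params = detection_params()) {
  if (!all(is.finite(row_values))) stop_validation("`row_values` must be finite")
  v <- smooth_vec(row_values, params$smoothing_halfwidth)
  n <- length(v)
  if (n < 3) return(data.frame(col = numeric(0), prominence = numeric(0)))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(idx) == 0) return(data.frame(col = numeric(0), prominence = numeric(0)))
  prom <- vapply(idx, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1)]
    higher <- which(left > h)
    lmin <- min(left[if (length(higher)) (max(higher) + 1):(p - 1) else seq_len(p - 1)])
    right <- v[(p + 1):n]
    higher <- which(right > h)
    rmin <- min(right[if (length(higher)) seq_len(min(higher) - 1) else seq_along(right)])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= params$min_prominence
  idx <- idx[keep]
  prom <- prom[keep]
  col <- as.numeric(idx)
  if (params$subpixel && length(idx) > 0)
    col <- col + parabolic_offset(v[idx - 1], v[idx], v[idx + 1])
  data.frame(col = col, prominence = prom)
}

## Vectorized per-row peak pick inside one column window of a frame.
## Returns data.frame(row, col, prominence) with at most one point per row.
## Prominence is window-limited: value minus the higher of the running
## minima toward the two window edges. The highest-prominence local maximum
## wins; ties go to the candidate nearest the window center.
window_peaks <- function(frame, rows, cols, params) {
  sub <- frame[rows, cols, drop = FALSE]
  n <- nrow(sub)
  k <- ncol(sub)
  if (k < 3) return(data.frame(row = integer(0), col = numeric(0), prominence = numeric(0)))
  if (params$smoothing_halfwidth > 0)
    sub <- t(apply(sub, 1, smooth_vec, halfwidth = params$smoothing_halfwidth))
  lmin <- sub
  for (j in 2:k) lmin[, j] <- pmin(lmin[, j - 1], sub[, j])
  rmin <- sub
  for (j in (k - 1):1) rmin[, j] <- pmin(rmin[, j + 1], sub[, j])
  ismax <- matrix(FALSE, n, k)
  ismax[, 2:(k - 1)] <- sub[, 2:(k - 1), drop = FALSE] > sub[, 1:(k - 2), drop = FALSE] &
    sub[, 2:(k - 1), drop = FALSE] >= sub[, 3:k, drop = FALSE]
  prom <- sub - pmax(lmin, rmin) # zero at non-peaks; correct at local maxima
  prom[!ismax] <- -Inf
  prom[prom < params$min_prominence] <- -Inf
  # stable pick: highest prominence, ties to window center
  center_pen <- matrix(abs(seq_len(k) - (k + 1) / 2) * 1e-9, n, k, byrow = TRUE)
  score <- prom - center_pen
  best <- max.col(score, ties.method = "first")
  ok <- is.finite(score[cbind(seq_len(n), best)])
  if (!any(ok)) return(data.frame(row = integer(0), col = numeric(0), prominence = numeric(0)))
  ri <- which(ok)
  p <- best[ok]
  col <- as.numeric(p)
  if (params$subpixel) {
    col <- col + parabolic_offset(
      sub[cbind(ri, p - 1L)], sub[cbind(ri, p)], sub[cbind(ri, p + 1L)]
    )
  }
  data.frame(
    row = rows[ri],
    col = col + cols[1] - 1,
    prominence = prom[cbind(ri, p)]
  )
}

#' Detect emission lines around user-supplied column estimates
#'
#' For each estimate the frame is searched row by row within a window of
#' `params$window_halfwidth` columns; at most one peak per row is kept (the
#' most prominent local maximum). Lines whose coverage (fraction of
#' illuminated rows with a peak) falls below `params$min_coverage` are
#' dropped. If no line survives, a detection-failure error is raised.
#'
#' @param frame Numeric frame matrix.
#' @param estimates Strictly increasing approximate line columns, separated
#'   by more than `2 * window_halfwidth`.
#' @param params A [detection_params()].
#' @param rows Optional integer vector of illuminated rows to search
#'   (default: all rows).
#' @return List of `emission_line` objects: `line_id`, `estimate_col`,
#'   `points` (data frame `row`, `col`, `prominence`, ordered by row) and
#'   `coverage`.
#' @export
detect_lines <- function(frame, estimates, params = detection_params(),
                         rows = NULL) {
  if (length(estimates) == 0) stop_validation("`estimates` must be non-empty")
  estimates <- as.numeric(estimates)
  if (is.unsorted(estimates, strictly = TRUE))
    stop_validation("`estimates` must be strictly increasing")
  if (length(estimates) > 1 &&
      any(diff(estimates) <= 2 * params$window_halfwidth))
    stop_validation("estimates must be separated by more than 2 * window_halfwidth")
  if (is.null(rows)) rows <- seq_len(nrow(frame))
  lines <- list()
  for (i in seq_along(estimates)) {
    est <- estimates[i]
    cols <- max(1, round(est) - params$window_halfwidth):
      min(ncol(frame), round(est) + params$window_halfwidth)
    pts <- window_peaks(frame, rows, cols, params)
    coverage <- nrow(pts) / length(rows)
    if (coverage >= params$min_coverage) {
      lines[[length(lines) + 1]] <- structure(
        list(line_id = i, estimate_col = est,
             points = pts[order(pts$row), , drop = FALSE],
             coverage = coverage),
        class = "emission_line"
      )
    }
  }
  if (length(lines) == 0)
    stop_detection(sprintf(
      "no emission line reached coverage %.2f around any of the %d estimates",
      params$min_coverage, length(estimates)
    ))
  lines
}

#' Flatten detected lines to a table
#'
#' @param lines List of emission lines from [detect_lines()].
#' @return Data frame `line_id`, `row`, `col`, `prominence` (one row per
#'   detected peak), suitable for CSV export.
#' @export
lines_to_table <- function(lines) {
  do.call(rbind, lapply(lines, function(l) {
    cbind(line_id = l$line_id, l$points)
  }))
}

#' Per-line tilt and curvature metrics
#'
#' @param lines List of emission lines from [detect_lines()].
#' @return Data frame `line_id`, `estimate_col`, `n_points`, `coverage`,
#'   `tilt_deg`, `kappa`. Metrics are `NA` when the corresponding fit is
#'   degenerate.
#' @export
line_metrics <- function(lines) {
  do.call(rbind, lapply(lines, function(l) {
    tilt <- tryCatch(estimate_tilt(l$points)$angle_deg, error = function(e) NA_real_)
    kap <- tryCatch(estimate_curvature(l$points)$kappa, error = function(e) NA_real_)
    data.frame(
      line_id = l$line_id, estimate_col = l$estimate_col,
      n_points = nrow(l$points), coverage = l$coverage,
      tilt_deg = tilt, kappa = kap
    )
  }))
}
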