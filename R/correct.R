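## Smile/tilt correction: per-row shift distances from fitted arcs, a
## per-pixel shift matrix interpolated across columns between the emission
## lines, and row-wise application of the shift.

#' Shift distance from a fitted circular arc
#'
#' For a photon registered on the arc of circle `(a, b, r)` at row `yp`, the
#' horizontal distance from the arc to the vertical tangent line through the
#' arc's apex row is
#' `d = r * (1 - cos(asin((yp - b) / r)))`, which is zero at `yp = b` and
#' grows symmetrically with `|yp - b|`. For `r >> |yp - b|` it approaches
#' the sagitta approximation `(yp - b)^2 / (2 r)`.
#'
#' @param circle A `circle_params` object from [fit_circle()], or any list
#'   with fields `b` and `r`.
#' @param yp Row coordinate(s), px; must satisfy `|yp - b| < r`.
#' @return Shift distance(s) `d >= 0` in px.
#' @export
line_shift_distance <- function(circle, yp) {
  u <- yp - circle$b
  if (any(abs(u) >= circle$r))
    stop_domain("|yp - b| must be smaller than the arc radius r")
  arc_distance(u, circle$r)
}

#' Assemble a correction model from detected lines and their circle fits
#'
#' Each accepted line contributes an anchor column (the mean detected
#' column), its fitted circle and the curve-direction sign (`+1` when the
#' circle center lies at larger columns than the line, in which case the
#' correct value for a pixel is found at `x + d`; `-1` otherwise, sampling
#' at `x - d`). Lines whose circle fit is degenerate are kept with a `NULL`
#' circle and contribute zero shift at their anchor (they are treated as
#' already straight).
#'
#' @param lines Emission lines from [detect_lines()].
#' @param fits Optional list of `circle_params` (or `NULL` for degenerate),
#'   one per line; computed from the line points when missing.
#' @return A `correction_model`: list of per-line entries sorted by anchor.
#' @export
correction_model <- function(lines, fits = NULL) {
  if (length(lines) < 1) stop_validation("need at least one detected line")
  if (is.null(fits))
    fits <- lapply(lines, function(l)
      tryCatch(fit_circle(l$points), error = function(e) NULL))
  entries <- Map(function(l, f) {
    list(line_id = l$line_id, anchor = mean(l$points$col), circle = f,
         sign = if (is.null(f)) 0 else f$sign)
  }, lines, fits)
  entries <- entries[order(vapply(entries, `[[`, numeric(1), "anchor"))]
  anchors <- vapply(entries, `[[`, numeric(1), "anchor")
  if (any(diff(anchors) <= 0))
    stop_validation("anchor columns must be strictly increasing")
  structure(entries, class = "correction_model")
}

## Per-line shift profile over rows 1..n_rows, plus the column the line is
## straightened onto. Lines whose fitted apex row lies within one frame
## height of the frame are anchored at the apex (the genuine-smile case);
## nearly straight lines, whose osculating apex sits far off the sensor,
## are anchored at the frame's center row instead so they stay in frame.
line_shift_profile <- function(entry, n_rows) {
  y <- seq_len(n_rows)
  if (is.null(entry$circle))
    return(list(shift = rep(0, n_rows), target = entry$anchor, mode = "straight"))
  circ <- entry$circle
  d <- tryCatch(line_shift_distance(circ, y), desmile_domain_error = function(e) NULL)
  if (is.null(d)) # arc does not span the frame rows: treat as straight
    return(list(shift = rep(0, n_rows), target = entry$anchor, mode = "straight"))
  apex_near <- circ$b >= 1 - n_rows && circ$b <= 2 * n_rows
  if (apex_near) {
    list(shift = entry$sign * d,
         target = circ$a - entry$sign * circ$r,
         mode = "apex")
  } else {
    yref <- (n_rows + 1) / 2
    dref <- line_shift_distance(circ, yref)
    list(shift = entry$sign * (d - dref),
         target = circ$a - entry$sign * sqrt(circ$r^2 - (yref - circ$b)^2),
         mode = "reference_row")
  }
}

#' Build the per-pixel shift matrix from a correction model
#'
#' At each anchor column the shift equals the signed arc distance of that
#' line; between anchors the shift is linearly interpolated across columns
#' and held constant beyond the outermost anchors. When the fitted circle
#' center row is off the frame's vertical center, the asymmetric profile
#' corrects the tilt as a side product.
#'
#' @param model A [correction_model()].
#' @param n_rows,n_cols Target frame size.
#' @return `n_rows` x `n_cols` shift matrix with attributes `provenance` (a
#'   data frame of per-line anchor, circle parameters, landing column,
#'   anchoring mode and mean absolute shift) and class `shift_matrix`.
#' @export
build_shift_matrix <- function(model, n_rows, n_cols) {
  if (!inherits(model, "correction_model"))
    stop_validation("`model` must be a correction_model")
  k <- length(model)
  profiles <- lapply(model, line_shift_profile, n_rows = n_rows)
  S <- vapply(profiles, `[[`, numeric(n_rows), "shift") # n_rows x k
  S <- matrix(S, n_rows, k)
  anchors <- vapply(model, `[[`, numeric(1), "anchor")
  x <- seq_len(n_cols)
  W <- matrix(0, k, n_cols)
  j <- findInterval(x, anchors)
  W[cbind(pmax(pmin(j, k), 1), x)] <- 1
  mid <- which(j >= 1 & j < k)
  if (length(mid) > 0) {
    t <- (x[mid] - anchors[j[mid]]) / (anchors[j[mid] + 1] - anchors[j[mid]])
    W[cbind(j[mid], mid)] <- 1 - t
    W[cbind(j[mid] + 1, mid)] <- t
  }
  s <- S %*% W
  if (any(!is.finite(s)) || any(abs(s) >= n_cols))
    stop_validation("shift matrix has non-finite entries or |s| >= n_cols")
  prov <- data.frame(
    line_id = vapply(model, `[[`, numeric(1), "line_id"),
    anchor_col = anchors,
    a = vapply(model, function(e) if (is.null(e$circle)) NA_real_ else e$circle$a, numeric(1)),
    b = vapply(model, function(e) if (is.null(e$circle)) NA_real_ else e$circle$b, numeric(1)),
    r = vapply(model, function(e) if (is.null(e$circle)) NA_real_ else e$circle$r, numeric(1)),
    target_col = vapply(profiles, `[[`, numeric(1), "target"),
    mode = vapply(profiles, `[[`, character(1), "mode"),
    mean_abs_shift = colMeans(abs(S))
  )
  structure(s, provenance = prov, class = c("shift_matrix", "matrix", "array"))
}

#' Apply a shift matrix to a frame
#'
#' Row-wise linear interpolation of each row at `x + s[y, x]`. The same
#' resampling is used to distort synthetic frames ([distort_frame()]) and to
#' correct real ones; it is exactly linear in the frame argument (for a
#' fixed fill value of 0).
#'
#' @param frame Numeric frame matrix.
#' @param s Shift matrix of identical shape.
#' @param fill Value for samples outside the frame; default the frame's
#'   median (background level).
#' @return Corrected frame, same shape.
#' @export
apply_shift <- function(frame, s, fill = NULL) {
  if (is.null(fill)) fill <- default_fill(frame)
  resample_rows(frame, s, fill)
}

#' Detect, fit and correct a frame in one pass
#'
#' Composes [detect_lines()], [fit_circle()] per line,
#' [build_shift_matrix()] and [apply_shift()]. Diagnostics report, per line,
#' the tilt and curvature metrics before and after correction (the corrected
#' frame is re-detected at the predicted landing columns), the mean absolute
#' shift applied at the anchor column, and the circle-fit parameters.
#' Detection failure on the input frame propagates; a degenerate circle fit
#' on a single line downgrades that line to zero local shift.
#'
#' @param frame Numeric frame matrix.
#' @param estimates Emission-line column estimates (see [detect_lines()]).
#' @param params A [detection_params()].
#' @param rows Optional illuminated rows.
#' @param fill Out-of-range fill value for resampling.
#' @return List with `frame` (corrected), `shift` (the `shift_matrix`), and
#'   `diagnostics` (data frame: `line_id`, `estimate_col`, `anchor_col`,
#'   `target_col`, `mode`, `a`, `b`, `r`, `rmse`, `coverage`, `n_points`,
#'   `tilt_pre`, `kappa_pre`, `tilt_post`, `kappa_post`,
#'   `mean_abs_shift`).
#' @export
correct_frame <- function(frame, estimates, params = detection_params(),
                          rows = NULL, fill = NULL) {
  lines <- detect_lines(frame, estimates, params, rows)
  fits <- lapply(lines, function(l)
    tryCatch(fit_circle(l$points), error = function(e) NULL))
  model <- correction_model(lines, fits)
  s <- build_shift_matrix(model, nrow(frame), ncol(frame))
  corrected <- apply_shift(frame, s, fill)
  prov <- attr(s, "provenance")
  pre <- line_metrics(lines)

  # re-detect on the corrected frame at the predicted landing columns
  post <- data.frame(line_id = prov$line_id, tilt_post = NA_real_,
                     kappa_post = NA_real_)
  targets <- round(prov$target_col)
  reorder <- order(targets)
  valid <- !is.na(targets) & targets - params$window_halfwidth >= 1 &
    targets + params$window_halfwidth <= ncol(frame)
  if (all(valid) && !is.unsorted(targets[reorder], strictly = TRUE) &&
      all(diff(sort(targets)) > 2 * params$window_halfwidth)) {
    post_lines <- tryCatch(
      detect_lines(corrected, sort(targets), params, rows),
      desmile_detection_failure = function(e) NULL
    )
    if (!is.null(post_lines)) {
      pm <- line_metrics(post_lines)
      # map re-detected lines (indexed by sorted target) back to line_id
      ids <- prov$line_id[reorder][pm$line_id]
      post <- data.frame(line_id = ids, tilt_post = pm$tilt_deg,
                         kappa_post = pm$kappa)
    }
  }

  rmse <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rmse, numeric(1))
  diag0 <- data.frame(
    line_id = pre$line_id, estimate_col = pre$estimate_col,
    coverage = pre$coverage, n_points = pre$n_points,
    tilt_pre = pre$tilt_deg, kappa_pre = pre$kappa, rmse = rmse
  )
  diagnostics <- merge(merge(diag0, prov, by = "line_id"), post,
                       by = "line_id", all.x = TRUE)
  diagnostics <- diagnostics[order(diagnostics$line_id),
                             c("line_id", "estimate_col", "anchor_col",
                               "target_col", "mode", "a", "b", "r", "rmse",
                               "coverage", "n_points", "tilt_pre", "kappa_pre",
                               "tilt_post", "kappa_post", "mean_abs_shift")]
  list(frame = corrected, shift = s, diagnostics = diagnostics)
}
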