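## Geometric models for an emission line's per-row peak positions: the
## circular arc that drives the correction, and the linear / parabolic fits
## used as tilt and curvature metrics.

radial_rmse <- function(pts, a, b, r) {
  sqrt(mean((sqrt((pts$col - a)^2 + (pts$row - b)^2) - r)^2))
}

circle_result <- function(pts, a, b, r) {
  if (!is.finite(a) || !is.finite(b) || !is.finite(r) || r <= 0 || r > 1e9)
    return(NULL)
  list(a = a, b = b, r = r, rmse = radial_rmse(pts, a, b, r))
}

## Algebraic (Kasa) circle fit on centered/scaled coordinates. NULL when the
## system is singular, ill-conditioned, or the radius is out of range.
kasa_circle <- function(pts) {
  x0 <- mean(pts$col)
  y0 <- mean(pts$row)
  sc <- diff(range(pts$row))
  if (sc <= 0) sc <- max(diff(range(pts$col)), 1)
  u <- (pts$col - x0) / sc
  v <- (pts$row - y0) / sc
  A <- cbind(2 * u, 2 * v, 1)
  sv <- svd(A)
  if (sv$d[3] <= 0 || sv$d[1] / sv$d[3] > 1e12) return(NULL)
  coef <- sv$v %*% ((t(sv$u) %*% (u^2 + v^2)) / sv$d)
  r2 <- coef[3] + coef[1]^2 + coef[2]^2
  if (r2 <= 0) return(NULL)
  circle_result(pts, x0 + coef[1] * sc, y0 + coef[2] * sc, sqrt(r2) * sc)
}

## Shallow-arc circle fit via the least-squares parabola x = alpha y^2 +
## beta y + gamma (y centered at the point mean): the circle osculating the
## parabola at the data center, with radius (1 + beta^2)^(3/2) / (2 |alpha|)
## and center offset along the local normal toward the concave side.
## Osculating at the data center (not at the parabola's vertex, which for
## tilted lines lies ~r*tan(theta) rows away) keeps the circle on the data.
## Immune to the noise amplification that makes the algebraic fit collapse
## onto small spurious circles when the points are almost collinear.
parabola_circle <- function(pts) {
  sc <- diff(range(pts$row))
  if (sc <= 0) return(NULL)
  ym <- mean(pts$row)
  yc <- (pts$row - ym) / sc
  fit <- stats::lm.fit(cbind(yc^2, yc, 1), pts$col)
  if (fit$rank < 3) return(NULL)
  alpha <- fit$coefficients[1] / sc^2
  beta <- fit$coefficients[2] / sc    # slope at the data center
  x_m <- fit$coefficients[3]          # column at the data center
  if (alpha == 0) return(NULL)
  den <- sqrt(1 + beta^2)
  r <- den^3 / (2 * abs(alpha))
  if (r > 1e9) return(NULL)
  s <- sign(alpha)
  circle_result(pts, x_m + s * r / den, ym - s * r * beta / den, r)
}

#' Least-squares circle fit for shallow emission-line arcs
#'
#' Fits a circle to `(row, col)` points, combining two routes: the algebraic
#' least-squares (Kasa) formulation on coordinates centered at the point
#' centroid and scaled to the row span, and a shallow-arc route through the
#' osculating parabola of `x(y)`. The algebraic route is essentially exact
#' whenever the points trace a genuine arc, but collapses onto small
#' spurious circles when the points are nearly collinear with noise; the
#' parabola route stays stable there and recovers the huge-radius,
#' off-center arc that encodes a straight tilted line. The route with the
#' smaller RMS radial residual wins. Fewer than 3 points, exactly collinear
#' input, or a radius above 1e9 px raise a degenerate-fit error; callers
#' treat such lines as already straight.
#'
#' @param points Data frame or two-column matrix of `(row, col)` positions.
#' @return A `circle_params` object: `a` (center column, px; often far
#'   outside the frame), `b` (center row, px), `r` (radius, px), `rmse`
#'   (RMS radial residual, px), `sign` (+1 when the center lies at larger
#'   columns than the line, i.e. the line's ends curve toward larger `x`),
#'   `n` (number of points).
#' @examples
#' fit_circle(data.frame(row = c(0, 1, 2), col = c(0, 1, 0))) # center (1, 0), r = 1
#' @export
fit_circle <- function(points) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 3) stop_degenerate("circle fit needs at least 3 points")
  candidates <- Filter(Negate(is.null), list(kasa_circle(pts), parabola_circle(pts)))
  if (length(candidates) == 0)
    stop_degenerate("points are collinear within tolerance (line treated as straight)")
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "rmse"))]]
  structure(
    c(best, list(sign = if (best$a >= mean(pts$col)) 1 else -1, n = n)),
    class = "circle_params"
  )
}

#' Tilt metric: linear least squares of column on row
#'
#' Emission lines are nearly vertical, so the fit is done in `(y, x)`
#' coordinates (column as a function of row); a fit the other way around
#' would have near-infinite slope. The tilt angle is `atan(slope)` in
#' degrees. Under the package's conventions a line whose top leans toward
#' larger `x` has negative metric slope.
#'
#' @param points Data frame or matrix of `(row, col)` positions spanning at
#'   least two distinct rows.
#' @return A `tilt_estimate`: `angle_deg`, `slope` (dx/dy), `intercept`.
#' @export
estimate_tilt <- function(points) {
  pts <- as_points(points)
  if (length(unique(pts$row)) < 2)
    stop_degenerate("tilt fit needs points on at least 2 distinct rows")
  vy <- stats::var(pts$row)
  slope <- stats::cov(pts$col, pts$row) / vy
  intercept <- mean(pts$col) - slope * mean(pts$row)
  structure(
    list(angle_deg = atan(slope) * 180 / pi, slope = slope, intercept = intercept),
    class = "tilt_estimate"
  )
}

#' Curvature metric: parabolic least squares of column on row
#'
#' Fits `x = alpha * y^2 + beta * y + gamma` (with `y` centered at its mean
#' for conditioning) and reports the signed curvature
#' `kappa = 2 * alpha / (1 + beta^2)^(3/2)` evaluated at the mean row. For
#' the near-vertical lines this metric targets, the `beta` correction
#' changes kappa by well under 0.1%. The sign follows the fitted `alpha`:
#' negative alpha (apex at maximal `x`, line bowing toward larger `x`) gives
#' negative kappa.
#'
#' @param points Data frame or matrix of `(row, col)` positions spanning at
#'   least three distinct rows.
#' @return A `curvature_estimate`: `kappa` (1/px) and `coeffs`
#'   `(alpha, beta, gamma)` of the centered-row parabola.
#' @export
estimate_curvature <- function(points) {
  pts <- as_points(points)
  if (length(unique(pts$row)) < 3)
    stop_degenerate("curvature fit needs points on at least 3 distinct rows")
  sc <- diff(range(pts$row))
  yc <- (pts$row - mean(pts$row)) / sc
  X <- cbind(yc^2, yc, 1)
  fit <- stats::lm.fit(X, pts$col)
  if (fit$rank < 3)
    stop_degenerate("degenerate design matrix in curvature fit")
  alpha <- fit$coefficients[1] / sc^2
  beta <- fit$coefficients[2] / sc
  gamma <- fit$coefficients[3]
  kappa <- 2 * alpha / (1 + beta^2)^1.5
  structure(
    list(kappa = unname(kappa),
         coeffs = c(alpha = unname(alpha), beta = unname(beta),
                    gamma = unname(gamma))),
    class = "curvature_estimate"
  )
}

#' Tabulate circle fits and metrics for a set of detected lines
#'
#' @param lines Emission lines from [detect_lines()].
#' @return Data frame `line_id, a, b, r, rmse, tilt_deg, kappa` with `NA`
#'   where a fit is degenerate.
#' @export
fit_table <- function(lines) {
  do.call(rbind, lapply(lines, function(l) {
    circ <- tryCatch(fit_circle(l$points), error = function(e) NULL)
    tilt <- tryCatch(estimate_tilt(l$points)$angle_deg, error = function(e) NA_real_)
    kap <- tryCatch(estimate_curvature(l$points)$kappa, error = function(e) NA_real_)
    data.frame(
      line_id = l$line_id,
      a = if (is.null(circ)) NA_real_ else circ$a,
      b = if (is.null(circ)) NA_real_ else circ$b,
      r = if (is.null(circ)) NA_real_ else circ$r,
      rmse = if (is.null(circ)) NA_real_ else circ$rmse,
      tilt_deg = tilt, kappa = kap
    )
  }))
}
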