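# Circle geometry from three-point annotations of the cell outline and
# contractile ring in the division-plane (z,x) view. All coordinates are in
# micrometres, image convention: origin top-left, y increasing downward.

#' Fit the circle through three annotated points
#'
#' Computes the circumcircle of three non-collinear points, the geometric
#' primitive behind every ring-closure metric: both the cell outline (radius
#' `R`) and the contractile ring (radius `r`) are annotated with three points
#' per frame and summarized as best-fit circles.
#'
#' The circumcenter is obtained by solving the linear system equating squared
#' distances to the three points. With exactly three points the circle passes
#' through all of them, so `residual` (RMS point-to-circle distance) is zero up
#' to round-off; it is reported to support a future least-squares extension to
#' more than three points.
#'
#' @param p1,p2,p3 Numeric vectors `c(x, y)` in micrometres.
#' @param collinear_tol Scale-free degeneracy tolerance: the fit aborts when
#'   the triangle's cross product is below `collinear_tol` times the squared
#'   maximum pairwise distance.
#' @return An object of class `circle_fit`: a list with `center` (numeric
#'   `c(x, y)`), `radius` and `residual`, all in micrometres.
#' @examples
#' circle_through_points(c(0, 1), c(1, 0), c(0, -1)) # unit circle at origin
#' @export
circle_through_points <- function(p1, p2, p3, collinear_tol = 1e-6) {
  pts <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3))
  if (ncol(pts) != 2L || !all(is.finite(pts)))
    stop("points must be finite (x, y) coordinate pairs", call. = FALSE)
  pd <- stats::dist(pts)
  if (any(pd == 0))
    stop("duplicate annotation points: all three points must be distinct",
         call. = FALSE)
  scale <- max(pd)
  v1 <- pts[2L, ] - pts[1L, ]
  v2 <- pts[3L, ] - pts[1L, ]
  crossz <- v1[1L] * v2[2L] - v1[2L] * v2[1L]
  if (abs(crossz) <= collinear_tol * scale^2)
    stop("collinear annotation points: cannot fit a circle", call. = FALSE)
  A <- 2 * rbind(pts[2L, ] - pts[1L, ], pts[3L, ] - pts[1L, ])
  b <- c(sum(pts[2L, ]^2) - sum(pts[1L, ]^2),
         sum(pts[3L, ]^2) - sum(pts[1L, ]^2))
  center <- as.numeric(solve(A, b))
  radii <- sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2)
  radius <- mean(radii)
  structure(
    list(center = center, radius = radius,
         residual = sqrt(mean((radii - radius)^2))),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.4g, %.4g) um, radius %.4g um, residual %.3g um\n",
              x$center[1L], x$center[2L], x$radius, x$residual))
  invisible(x)
}

#' Ring closure percentage
#'
#' Fractional constriction of the contractile ring relative to the cell
#' outline. The raw measurement is the radius ratio `r/R`; closure is reported
#' as `100 * (1 - r/R)` so that it runs from 0% (unclosed ring, r equal to
#' R) to 100% (fully closed, zero r) and increases over time. Annotation jitter
#' near cytokinesis onset can make the fitted ring marginally larger than the
#' cell; ratios in `(1, 1 + tol]` are clamped to 0% closure, larger ratios are
#' an error.
#'
#' @param ring,cell `circle_fit` objects for the contractile ring and the cell
#'   outline.
#' @param tol Clamping tolerance on `r/R` above 1 (default 0.02).
#' @return Closure percentage in `[0, 100]`.
#' @export
closure_percent <- function(ring, cell, tol = 0.02) {
  stopifnot(inherits(ring, "circle_fit"), inherits(cell, "circle_fit"))
  if (cell$radius <= 0)
    stop("cell radius must be positive", call. = FALSE)
  ratio <- ring$radius / cell$radius
  if (ratio > 1 + tol)
    stop(sprintf("ring radius exceeds cell radius beyond tolerance (r/R = %.4f)",
                 ratio), call. = FALSE)
  ratio <- min(max(ratio, 0), 1)
  100 * (1 - ratio)
}

#' Furrow asymmetry percentage
#'
#' Non-concentric ring closure quantified as `100 * D / R`, where `D` is the
#' distance between the cell and ring centers and `R` the cell radius: 0% for
#' perfectly concentric closure, approaching 100% when the ring closes
#' entirely at one side of the cell.
#'
#' @inheritParams closure_percent
#' @return Asymmetry percentage (non-negative; at most 100 whenever the ring
#'   lies inside the cell).
#' @export
asymmetry_percent <- function(ring, cell) {
  stopifnot(inherits(ring, "circle_fit"), inherits(cell, "circle_fit"))
  if (cell$radius <= 0)
    stop("cell radius must be positive", call. = FALSE)
  100 * sqrt(sum((ring$center - cell$center)^2)) / cell$radius
}

#' Signed apical displacement of the ring center
#'
#' Projects the ring-center displacement (ring center minus cell center) onto
#' the apical axis. Positive values mean the furrow is ingressing towards the
#' apical side, the polarity observed in epithelial cytokinesis.
#'
#' @inheritParams closure_percent
#' @param apical_axis Unit vector `c(x, y)` pointing towards the apical side
#'   of the cell (image convention; `c(0, 1)` when the apical membrane is at
#'   the bottom of the frame).
#' @return Signed displacement in micrometres.
#' @export
apical_displacement <- function(ring, cell, apical_axis) {
  stopifnot(inherits(ring, "circle_fit"), inherits(cell, "circle_fit"))
  apical_axis <- as.numeric(apical_axis)
  if (length(apical_axis) != 2L || abs(sqrt(sum(apical_axis^2)) - 1) > 1e-6)
    stop("apical_axis must be a unit vector of length 2", call. = FALSE)
  sum((ring$center - cell$center) * apical_axis)
}

#' Construct a single annotated timepoint
#'
#' One frame of a division-plane annotation: three points on the cell outline,
#' three on the contractile ring, the acquisition time, and the apical
#' direction.
#'
#' @param time Seconds since movie start.
#' @param cell_points,ring_points 3 x 2 matrices (rows are points, columns
#'   x/y) in micrometres; any object coercible by `rbind()` to that shape.
#' @param apical_axis Unit vector towards the apical side; default `c(0, 1)`
#'   (apical membrane at the bottom of the image).
#' @return An object of class `annotated_frame`.
#' @export
annotated_frame <- function(time, cell_points, ring_points,
                            apical_axis = c(0, 1)) {
  as_pts <- function(p, what) {
    p <- if (is.matrix(p)) p else do.call(rbind, p)
    p <- matrix(as.numeric(p), ncol = 2L,
                dimnames = list(NULL, c("x", "y")))
    if (nrow(p) != 3L || !all(is.finite(p)))
      stop(sprintf("%s must be three finite (x, y) points", what),
           call. = FALSE)
    p
  }
  time <- as.numeric(time)
  if (length(time) != 1L || !is.finite(time))
    stop("time must be a single finite number of seconds", call. = FALSE)
  apical_axis <- as.numeric(apical_axis)
  if (length(apical_axis) != 2L || abs(sqrt(sum(apical_axis^2)) - 1) > 1e-6)
    stop("apical_axis must be a unit vector of length 2", call. = FALSE)
  structure(
    list(time = time,
         cell_points = as_pts(cell_points, "cell_points"),
         ring_points = as_pts(ring_points, "ring_points"),
         apical_axis = apical_axis),
    class = "annotated_frame"
  )
}

#' Per-frame ring metrics from an annotated frame
#'
#' Fits the cell and ring circles from their three-point annotations and
#' derives the per-frame metrics: ring closure, furrow asymmetry, and signed
#' apical displacement of the ring center. Both fitted circles and the raw
#' radius ratio `r/R` are retained for downstream use.
#'
#' @param frame An [annotated_frame()].
#' @param label Optional frame label (e.g. frame index) prepended to error
#'   messages from degenerate annotations.
#' @param collinear_tol,closure_tol Passed to [circle_through_points()] and
#'   [closure_percent()].
#' @return A list of class `frame_metrics` with elements `time` (seconds),
#'   `closure_pct`, `asymmetry_pct`, `apical_displacement` (um), `r_over_R`,
#'   `cell` and `ring` (`circle_fit`s).
#' @export
frame_metrics <- function(frame, label = NULL,
                          collinear_tol = 1e-6, closure_tol = 0.02) {
  stopifnot(inherits(frame, "annotated_frame"))
  ctx <- if (is.null(label)) "" else sprintf(" [frame %s]", label)
  wrap <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s%s: %s", what, ctx, conditionMessage(e)), call. = FALSE)
    })
  }
  cell <- wrap(circle_through_points(frame$cell_points[1L, ],
                                     frame$cell_points[2L, ],
                                     frame$cell_points[3L, ],
                                     collinear_tol = collinear_tol),
               "cell outline")
  ring <- wrap(circle_through_points(frame$ring_points[1L, ],
                                     frame$ring_points[2L, ],
                                     frame$ring_points[3L, ],
                                     collinear_tol = collinear_tol),
               "contractile ring")
  closure <- wrap(closure_percent(ring, cell, tol = closure_tol),
                  "ring closure")
  structure(
    list(time = frame$time,
         closure_pct = closure,
         asymmetry_pct = asymmetry_percent(ring, cell),
         apical_displacement = apical_displacement(ring, cell,
                                                   frame$apical_axis),
         r_over_R = ring$radius / cell$radius,
         cell = cell, ring = ring),
    class = "frame_metrics"
  )
}
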