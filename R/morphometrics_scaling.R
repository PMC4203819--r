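# Cell and tissue morphometrics, ring-breadth extraction from intensity
# profiles, and the size-scaling regressions (breadth vs cell length,
# furrowing speed vs division-plane perimeter).

#' Cell volume from the box model
#'
#' Volume of an epithelial cell approximated as a box: anterior-posterior
#' length times apical-basal height times left-right thickness, with the
#' thickness obtained by counting the confocal z steps occupied by the cell.
#'
#' @param length,height Cell length and height in micrometres.
#' @param n_zsteps Number of z steps occupied by the cell.
#' @param z_step z-step size in micrometres (default 0.6).
#' @return Volume in cubic micrometres. Vectorized over all arguments.
#' @examples
#' cell_volume(10, 5, 8) # 10 * 5 * 4.8 = 240
#' @export
cell_volume <- function(length, height, n_zsteps, z_step = 0.6) {
  if (any(length <= 0) || any(height <= 0) || any(n_zsteps <= 0) ||
      any(z_step <= 0))
    stop("all cell dimensions must be positive", call. = FALSE)
  length * height * (n_zsteps * z_step)
}

#' Total length of a contiguous run of cells
#'
#' Longitudinal extent of a row of epithelial cells, the tissue-level
#' measurement used to show that reductive divisions proceed without
#' appreciable tissue growth.
#'
#' @param lengths Cell lengths in micrometres (numeric vector), or a
#'   `data.frame` with a `length_um` column.
#' @return Sum of lengths in micrometres.
#' @export
tissue_length <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length_um
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L)
    stop("at least one cell is required", call. = FALSE)
  if (any(!is.finite(lengths) | lengths <= 0))
    stop("cell lengths must be positive", call. = FALSE)
  sum(lengths)
}

#' Contractile ring breadth from an intensity profile
#'
#' Width of the equatorial myosin enrichment along the cell's long axis.
#' "Enrichment" is operationalized as intensity exceeding the baseline mean
#' plus `k` baseline standard deviations, where the baseline is taken from
#' the profile outside the central 50% of the cell (the poles). The breadth
#' is the spatial extent of the widest contiguous run above threshold; a
#' profile with no run returns breadth 0 and `detected = FALSE`.
#'
#' @param position Positions along the cell long axis in micrometres,
#'   covering the whole cell; at least 20 samples.
#' @param intensity Intensities at `position`.
#' @param k Threshold multiplier on the baseline SD (default 2).
#' @return A list with `breadth_um`, `detected`, `threshold`, and the run's
#'   `start_um`/`end_um` (`NA` when undetected).
#' @export
ring_breadth <- function(position, intensity, k = 2) {
  position <- as.numeric(position)
  intensity <- as.numeric(intensity)
  if (length(position) < 20L || length(position) != length(intensity))
    stop("profile too short: need >= 20 matched position/intensity samples",
         call. = FALSE)
  ord <- order(position)
  position <- position[ord]
  intensity <- intensity[ord]
  ext <- range(position)
  len <- diff(ext)
  central <- position > ext[1L] + 0.25 * len & position < ext[1L] + 0.75 * len
  base <- intensity[!central]
  if (length(base) < 2L)
    stop("profile must cover the cell poles outside the central 50%",
         call. = FALSE)
  thr <- mean(base) + k * stats::sd(base)
  above <- intensity > thr
  if (!any(above))
    return(list(breadth_um = 0, detected = FALSE, threshold = thr,
                start_um = NA_real_, end_um = NA_real_))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  widths <- position[ends[runs]] - position[starts[runs]]
  best <- runs[which.max(widths)]
  list(breadth_um = position[ends[best]] - position[starts[best]],
       detected = TRUE, threshold = thr,
       start_um = position[starts[best]], end_um = position[ends[best]])
}

#' Average ring breadth over the first detected timepoints
#'
#' Early-cytokinesis summary of ring breadth: the mean over the first
#' `n_points` (default 5) timepoints with detectable equatorial myosin.
#' Apply separately to the apical and basal breadth series.
#'
#' @param breadths Per-frame breadths in micrometres, time-ordered; `NA`
#'   marks frames without detectable enrichment.
#' @param n_points Maximum number of detected frames to average (default 5).
#' @return A list with `mean_um` and `n` (frames actually averaged).
#' @export
breadth_time_average <- function(breadths, n_points = 5) {
  breadths <- as.numeric(breadths)
  det <- breadths[!is.na(breadths)]
  if (length(det) == 0L)
    stop("no frames with detected myosin enrichment", call. = FALSE)
  used <- det[seq_len(min(n_points, length(det)))]
  list(mean_um = mean(used), n = length(used))
}

#' Linear scaling regression
#'
#' Ordinary least-squares fit of `y` on `x` with standard errors and R
#' squared, the workhorse for scaling analyses: contractile ring breadth
#' versus cell length across division rounds, and furrowing speed versus
#' division-plane perimeter pooled with external reference cells.
#'
#' @param x,y Numeric vectors, at least 3 points, `x` not all equal.
#' @return An object of class `scaling_fit`: a list with `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `r_squared`, `n_points` and the
#'   underlying `lm` fit.
#' @export
linear_scaling_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 (x, y) points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate x: all abscissa values are equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact lines are valid input; silence summary()'s perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(
    list(slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
         slope_se = co["x", "Std. Error"],
         intercept_se = co["(Intercept)", "Std. Error"],
         r_squared = sm$r.squared, n_points = length(x), fit = fit),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> y = %.4g x + %.4g (R2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  slope SE %.3g, intercept SE %.3g\n", x$slope_se,
              x$intercept_se))
  invisible(x)
}

#' Division-plane perimeter from cell height and thickness
#'
#' Perimeter of the division plane modelled as an ellipse with semi-axes
#' `height/2` and `thickness/2`, evaluated with Ramanujan's approximation
#' `pi * (3 (a + b) - sqrt((3a + b)(a + 3b)))`. This is the size against
#' which furrowing speed scales.
#'
#' @param height,thickness Division-plane dimensions in micrometres.
#' @return Perimeter in micrometres. Vectorized.
#' @export
division_plane_perimeter <- function(height, thickness) {
  if (any(height <= 0) || any(thickness <= 0))
    stop("height and thickness must be positive", call. = FALSE)
  a <- height / 2
  b <- thickness / 2
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Background-normalized mean intensity of a region
#'
#' Mean intensity of a rectangular region of interest divided by the mean of
#' a background region (outside the specimen), the normalization used for
#' fluorescence depletion measurements.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param roi,background_roi Rectangles `c(x, y, width, height)` in 0-based
#'   pixel coordinates, half-open (a pixel at `x` is included, at
#'   `x + width` excluded).
#' @return The ratio mean(roi) / mean(background).
#' @export
region_mean_intensity <- function(image, roi, background_roi) {
  stopifnot(is.matrix(image), is.numeric(image))
  extract <- function(r, what) {
    r <- as.numeric(r)
    if (length(r) != 4L || any(!is.finite(r)) || r[3L] < 1 || r[4L] < 1)
      stop(sprintf("%s must be c(x, y, width, height) with positive size",
                   what), call. = FALSE)
    x <- r[1L]; y <- r[2L]; w <- r[3L]; h <- r[4L]
    if (x < 0 || y < 0 || x + w > ncol(image) || y + h > nrow(image))
      stop(sprintf("%s out of image bounds", what), call. = FALSE)
    image[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
  }
  roi_px <- extract(roi, "roi")
  bg_px <- extract(background_roi, "background_roi")
  bg <- mean(bg_px)
  if (bg <= 0)
    stop("background mean intensity must be positive", call. = FALSE)
  mean(roi_px) / bg
}
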