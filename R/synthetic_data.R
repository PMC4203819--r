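# Ground-truth generators: sigmoidal ring-closure traces with apical drift
# and annotation jitter, size-halving cell populations with a known
# breadth-vs-length line, and annulus-like division-plane image stacks.
# These emulate the statistical structure the analysis assumes, so every
# pipeline stage is verifiable against known truth; they are stand-ins, not
# mechanistic models of ring contraction.

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Logistic closure law
#'
#' The symmetric sigmoid `c(t) = 100 / (1 + exp(-k (t - t0)))` used as the
#' generating law for ring closure: closure accelerates until about half
#' closed and decelerates thereafter, with instantaneous speed peaking at
#' `25 k` percent per minute at 50% closure.
#'
#' @param t Time in minutes.
#' @param k Logistic rate per minute.
#' @param t0 Midpoint time in minutes.
#' @return Closure percentage.
#' @export
logistic_closure <- function(t, k, t0) 100 / (1 + exp(-k * (t - t0)))

#' Ground-truth closure model
#'
#' Parameters of a simulated ring-closure trace. The defaults describe a
#' vulval-precursor-like division: a division-plane radius of 2.5 um, a peak
#' closure speed of 18 %/min (`k = 0.72`), closure essentially complete
#' within ~10 minutes, 30-second frame intervals, apically polarized drift
#' with half the ingressed distance taken up on the apical side
#' (`alpha = 0.5`), and 0.05 um isotropic annotation jitter.
#'
#' @param k Logistic closure rate per minute (> 0); peak speed is `25 k`.
#' @param t0 Midpoint (50% closure) time in minutes.
#' @param R0 Cell (division-plane) radius in micrometres.
#' @param alpha Apical drift fraction in `[0, 1]`: the ring center is
#'   displaced towards the apical side by `alpha * (R0 - r(t))`, so the
#'   ground-truth asymmetry equals `alpha` times closure.
#' @param dt Sampling interval in minutes (default 0.5, i.e. 30 s frames).
#' @param jitter_sigma_um Isotropic Gaussian SD of the annotation-point
#'   jitter in micrometres.
#' @param closure_range Closure percentages spanned by the annotated frames;
#'   the default `c(5, 92)` reflects that a furrow is annotated only once the
#'   ring is distinguishable from the cell outline, and only until the ring
#'   radius approaches the optical resolution limit (about 0.2 um for the
#'   default R0), below which three-point annotation is no longer meaningful.
#' @param apical_axis Unit vector towards the apical side (image convention;
#'   default `c(0, 1)`, apical at the bottom).
#' @param seed Integer seed; generators are pure functions of the model
#'   including the seed.
#' @return A list of class `closure_model`.
#' @export
closure_model <- function(k = 0.72, t0 = 5, R0 = 2.5, alpha = 0.5, dt = 0.5,
                          jitter_sigma_um = 0.05, closure_range = c(5, 92),
                          apical_axis = c(0, 1), seed = 1L) {
  if (k <= 0 || dt <= 0 || R0 <= 0)
    stop("k, dt and R0 must be positive", call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (jitter_sigma_um < 0)
    stop("jitter_sigma_um must be non-negative", call. = FALSE)
  if (length(closure_range) != 2L || closure_range[1L] <= 0 ||
      closure_range[2L] >= 100 || diff(closure_range) <= 0)
    stop("closure_range must be increasing within (0, 100)", call. = FALSE)
  apical_axis <- as.numeric(apical_axis)
  if (abs(sqrt(sum(apical_axis^2)) - 1) > 1e-6)
    stop("apical_axis must be a unit vector", call. = FALSE)
  structure(
    list(k = k, t0 = t0, R0 = R0, alpha = alpha, dt = dt,
         jitter_sigma_um = jitter_sigma_um, closure_range = closure_range,
         apical_axis = apical_axis, seed = as.integer(seed)),
    class = "closure_model"
  )
}

# Fixed, well-conditioned annotation angles (degrees, image coordinates).
.cell_angles <- c(90, 210, 330) * pi / 180
.ring_angles <- c(30, 150, 270) * pi / 180

#' Simulate an annotated ring-closure trace
#'
#' Generates a ground-truth trace under a [closure_model()]: ring radius
#' `r(t) = R0 (1 - c(t)/100)` with logistic closure `c(t)`, ring center
#' displaced towards the apical side by `alpha (R0 - r(t))` (so true
#' asymmetry is `alpha` times closure), and three-point annotations of cell
#' outline and ring sampled at fixed angles with isotropic Gaussian jitter.
#' The cell center sits at `(1.5 R0, 1.5 R0)` so all coordinates are
#' positive. Identical models (including seed) produce identical output.
#'
#' @param model A [closure_model()].
#' @param trace_id Identifier attached to the trace.
#' @return A list of class `simulated_trace` with `model`, `trace_id`,
#'   `truth` (per-frame data.frame: `time_min`, `time_s`, `closure_pct`,
#'   `asymmetry_pct`, `r_um`, `R_um`, `d_um`, `center_x_um`, `center_y_um`)
#'   and `frames` (list of [annotated_frame()]s, times in seconds).
#' @export
simulate_trace <- function(model = closure_model(), trace_id = "sim") {
  stopifnot(inherits(model, "closure_model"))
  t_of_c <- function(c) model$t0 + log(c / (100 - c)) / model$k
  t_lo <- t_of_c(model$closure_range[1L])
  t_hi <- t_of_c(model$closure_range[2L])
  # uniform frame grid, extended so the last frame covers the closure span
  times <- t_lo + model$dt * seq(0, ceiling((t_hi - t_lo) / model$dt))
  if (length(times) < 5L)
    stop("model produces fewer than 5 frames; decrease dt or widen closure_range",
         call. = FALSE)
  cc <- logistic_closure(times, model$k, model$t0)
  r <- model$R0 * (1 - cc / 100)
  d <- model$alpha * (model$R0 - r)
  cell_center <- c(1.5, 1.5) * model$R0
  truth <- data.frame(
    time_min = times, time_s = times * 60, closure_pct = cc,
    asymmetry_pct = model$alpha * cc, r_um = r, R_um = model$R0, d_um = d,
    center_x_um = cell_center[1L] + d * model$apical_axis[1L],
    center_y_um = cell_center[2L] + d * model$apical_axis[2L]
  )
  frames <- with_seed(model$seed, {
    lapply(seq_along(times), function(i) {
      ring_center <- c(truth$center_x_um[i], truth$center_y_um[i])
      jit <- function(n) stats::rnorm(n, 0, model$jitter_sigma_um)
      cell_pts <- cbind(cell_center[1L] + model$R0 * cos(.cell_angles),
                        cell_center[2L] + model$R0 * sin(.cell_angles)) +
        cbind(jit(3L), jit(3L))
      ring_pts <- cbind(ring_center[1L] + r[i] * cos(.ring_angles),
                        ring_center[2L] + r[i] * sin(.ring_angles)) +
        cbind(jit(3L), jit(3L))
      annotated_frame(time = times[i] * 60, cell_points = cell_pts,
                      ring_points = ring_pts,
                      apical_axis = model$apical_axis)
    })
  })
  structure(list(model = model, trace_id = as.character(trace_id),
                 truth = truth, frames = frames),
            class = "simulated_trace")
}

#' Simulate a size-halving cell population
#'
#' Generates per-cell dimension and ring-breadth tables across division
#' rounds. Stage mean lengths halve from one round to the next (the
#' reductive-division geometry) while mean height and thickness stay
#' constant; individual lengths are lognormal around the stage mean with
#' fractional SD `length_cv`, thickness is drawn as a count of z steps, and
#' apical/basal breadths follow ground-truth lines in cell length plus
#' Gaussian noise.
#'
#' @param n_per_stage Cells per stage (default 20).
#' @param stage_labels Stage names, one per division round.
#' @param mean_length0 Mean cell length at the first stage in micrometres.
#' @param mean_height Mean cell height in micrometres (constant across
#'   stages).
#' @param mean_n_zsteps Mean number of occupied z steps (constant across
#'   stages).
#' @param z_step z-step size in micrometres.
#' @param length_cv Fractional SD of cell length (default 0.1).
#' @param dim_cv Fractional SD of height and thickness (default 0.05).
#' @param halving If `TRUE` (default) successive stage mean lengths halve;
#'   otherwise all stages share `mean_length0`.
#' @param breadth_slope,breadth_intercept Named vectors `c(apical =, basal =)`
#'   for the ground-truth breadth-vs-length lines (um per um, um).
#' @param breadth_sd Gaussian SD of the breadth noise in micrometres.
#' @param seed Integer seed.
#' @return A list of class `simulated_population` with `dimensions`
#'   (`cell_id`, `stage`, `length_um`, `height_um`, `n_zsteps`, `z_step_um`,
#'   `thickness_um`, `volume_um3`), `breadths` (`cell_id`, `stage`,
#'   `length_um`, `apical_breadth_um`, `basal_breadth_um`) and the generator
#'   parameters.
#' @export
simulate_population <- function(n_per_stage = 20,
                                stage_labels = c("3 VPC", "6 VPC", "12 VPC"),
                                mean_length0 = 12, mean_height = 4.5,
                                mean_n_zsteps = 5, z_step = 0.6,
                                length_cv = 0.1, dim_cv = 0.05,
                                halving = TRUE,
                                breadth_slope = c(apical = 0.2, basal = 0.15),
                                breadth_intercept = c(apical = 0.8,
                                                      basal = 0.5),
                                breadth_sd = 0.3, seed = 1L) {
  stopifnot(n_per_stage >= 1, mean_length0 > 0, mean_height > 0,
            mean_n_zsteps >= 1, z_step > 0, length_cv >= 0, dim_cv >= 0,
            breadth_sd >= 0)
  n_stages <- length(stage_labels)
  stage_means <- if (halving) mean_length0 / 2^(seq_len(n_stages) - 1)
                 else rep(mean_length0, n_stages)
  rlnorm_mean <- function(n, m, cv) {
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_stages), function(s) {
      len <- rlnorm_mean(n_per_stage, stage_means[s], length_cv)
      hei <- rlnorm_mean(n_per_stage, mean_height, dim_cv)
      thick <- rlnorm_mean(n_per_stage, mean_n_zsteps * z_step, dim_cv)
      nz <- pmax(1L, as.integer(round(thick / z_step)))
      data.frame(
        cell_id = sprintf("%s_cell%02d", gsub("\\s+", "", stage_labels[s]),
                          seq_len(n_per_stage)),
        stage = stage_labels[s], length_um = len, height_um = hei,
        n_zsteps = nz, z_step_um = z_step, thickness_um = nz * z_step,
        volume_um3 = cell_volume(len, hei, nz, z_step),
        stringsAsFactors = FALSE
      )
    })
    dims <- do.call(rbind, rows)
    noise <- function(n) stats::rnorm(n, 0, breadth_sd)
    n_tot <- nrow(dims)
    breadths <- data.frame(
      cell_id = dims$cell_id, stage = dims$stage, length_um = dims$length_um,
      apical_breadth_um = pmin(pmax(
        breadth_intercept[["apical"]] +
          breadth_slope[["apical"]] * dims$length_um + noise(n_tot), 0),
        dims$length_um),
      basal_breadth_um = pmin(pmax(
        breadth_intercept[["basal"]] +
          breadth_slope[["basal"]] * dims$length_um + noise(n_tot), 0),
        dims$length_um),
      stringsAsFactors = FALSE
    )
    structure(
      list(dimensions = dims, breadths = breadths,
           stage_means = stats::setNames(stage_means, stage_labels),
           breadth_slope = breadth_slope,
           breadth_intercept = breadth_intercept, seed = as.integer(seed)),
      class = "simulated_population"
    )
  })
}

#' Division-plane image model
#'
#' Parameters of the synthetic division-plane (z, x view) movie: the myosin
#' ring renders as an annulus with a Gaussian radial intensity profile over a
#' uniform background, plus optional Gaussian pixel noise.
#'
#' @param frame_px Frame size `c(nx, ny)` in pixels.
#' @param voxel_um Pixel size in micrometres.
#' @param sigma_r_um Radial SD of the annulus profile in micrometres.
#' @param ring_intensity,background Intensities (arbitrary units, >= 0).
#' @param noise_sd Gaussian pixel-noise SD (default 0).
#' @param seed Integer seed for the noise.
#' @return A list of class `image_model`.
#' @export
image_model <- function(frame_px = c(64, 64), voxel_um = 0.1,
                        sigma_r_um = 0.2, ring_intensity = 200,
                        background = 100, noise_sd = 0, seed = 1L) {
  stopifnot(length(frame_px) == 2L, all(frame_px >= 4), voxel_um > 0,
            sigma_r_um > 0, ring_intensity >= 0, background >= 0,
            noise_sd >= 0)
  structure(
    list(frame_px = as.integer(frame_px), voxel_um = voxel_um,
         sigma_r_um = sigma_r_um, ring_intensity = ring_intensity,
         background = background, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "image_model"
  )
}

#' Render a synthetic division-plane movie
#'
#' Renders one image per frame of a closing ring: each pixel takes the value
#' `background + ring_intensity * exp(-(rho - r(t))^2 / (2 sigma_r^2))`,
#' where `rho` is the distance from the pixel center to the ring center,
#' plus Gaussian noise. The ring center starts at the frame center and
#' drifts by `d(t)` along the apical axis.
#'
#' @param truth A per-frame data.frame with columns `r_um` and `d_um`, e.g.
#'   the `$truth` of [simulate_trace()].
#' @param model An [image_model()].
#' @param apical_axis Unit drift direction (default `c(0, 1)`).
#' @return A numeric array `[ny, nx, n_frames]` (rows = y, columns = x).
#' @export
render_division_plane_movie <- function(truth, model = image_model(),
                                        apical_axis = c(0, 1)) {
  stopifnot(inherits(model, "image_model"),
            is.data.frame(truth), all(c("r_um", "d_um") %in% names(truth)))
  nx <- model$frame_px[1L]
  ny <- model$frame_px[2L]
  half <- min(nx, ny) / 2 * model$voxel_um
  if (any(truth$r_um + abs(truth$d_um) >= half))
    stop("ring circle falls outside the frame; enlarge frame_px or shrink R0",
         call. = FALSE)
  cx0 <- nx / 2 * model$voxel_um
  cy0 <- ny / 2 * model$voxel_um
  xs <- (seq_len(nx) - 0.5) * model$voxel_um
  ys <- (seq_len(ny) - 0.5) * model$voxel_um
  nt <- nrow(truth)
  stack <- with_seed(model$seed, {
    out <- array(0, dim = c(ny, nx, nt))
    for (t in seq_len(nt)) {
      cx <- cx0 + truth$d_um[t] * apical_axis[1L]
      cy <- cy0 + truth$d_um[t] * apical_axis[2L]
      rho <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
      img <- model$background + model$ring_intensity *
        exp(-(rho - truth$r_um[t])^2 / (2 * model$sigma_r_um^2))
      if (model$noise_sd > 0)
        img <- img + matrix(stats::rnorm(ny * nx, 0, model$noise_sd), ny, nx)
      out[, , t] <- img
    }
    out
  })
  attr(stack, "voxel_um") <- model$voxel_um
  stack
}

#' Kymograph of a time-lapse stack
#'
#' Collapses each frame of a 2D+t stack by maximum projection along one image
#' axis and juxtaposes the resulting 1D profiles over time, producing the
#' classic position-by-time view in which the two edges of a closing ring
#' converge.
#'
#' @param stack Numeric array `[ny, nx, n_frames]`.
#' @param axis Image axis collapsed by the projection: `"horizontal"`
#'   projects along x (kymograph rows are y positions), `"vertical"` along y
#'   (rows are x positions).
#' @return A numeric matrix `[position, time]`, inheriting the stack's
#'   `voxel_um` attribute if present.
#' @export
make_kymograph <- function(stack, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3L] == 0L)
    stop("stack must be a non-empty [ny, nx, time] array", call. = FALSE)
  nt <- dim(stack)[3L]
  cols <- lapply(seq_len(nt), function(t) {
    frame <- stack[, , t]
    if (axis == "horizontal") apply(frame, 1L, max) else apply(frame, 2L, max)
  })
  kymo <- do.call(cbind, cols)
  attr(kymo, "voxel_um") <- attr(stack, "voxel_um")
  kymo
}

#' Band separation along a kymograph
#'
#' Measures, per time column, the separation between the two edges of the
#' ring band in a kymograph as the full width at half maximum above the
#' column baseline. Because the annulus has a Gaussian radial profile of SD
#' `sigma_r_um`, the half-maximum crossing sits `sigma_r * sqrt(2 log 2)`
#' outside the true ring edge on each side; when `sigma_r_um` is supplied
#' the measured width is corrected for this known edge spread, so the result
#' estimates the ring diameter `2 r(t)`.
#'
#' @param kymo A kymograph matrix from [make_kymograph()].
#' @param voxel_um Pixel size in micrometres (default: the matrix's
#'   `voxel_um` attribute).
#' @param sigma_r_um Radial profile SD used for the edge-spread correction;
#'   `NULL` skips the correction.
#' @return Numeric vector of band separations in micrometres, one per time
#'   column.
#' @export
kymograph_band_separation <- function(kymo, voxel_um = NULL,
                                      sigma_r_um = NULL) {
  stopifnot(is.matrix(kymo))
  voxel_um <- voxel_um %||% attr(kymo, "voxel_um")
  if (is.null(voxel_um))
    stop("voxel_um is required (none stored on the kymograph)", call. = FALSE)
  corr <- if (is.null(sigma_r_um)) 0 else 2 * sigma_r_um * sqrt(2 * log(2))
  pos <- function(i) (i - 0.5) * voxel_um
  apply(kymo, 2L, function(col) {
    lo <- min(col); hi <- max(col)
    if (hi <= lo) return(0)
    thr <- lo + (hi - lo) / 2
    idx <- which(col > thr)
    l <- min(idx); r <- max(idx)
    # subpixel half-maximum crossings by linear interpolation
    left <- if (l > 1L)
      pos(l - 1L) + (thr - col[l - 1L]) / (col[l] - col[l - 1L]) * voxel_um
    else pos(l)
    right <- if (r < length(col))
      pos(r) + (col[r] - thr) / (col[r] - col[r + 1L]) * voxel_um
    else pos(r)
    max(right - left - corr, 0)
  })
}
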