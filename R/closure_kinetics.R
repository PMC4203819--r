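# Kinetics of contractile ring closure: per-trace read-outs (midpoint time,
# 20-80% average speed, peak speed, duration) and population-averaged curves
# aligned at the midpoint of closure. Times are in minutes throughout.

#' Construct a ring-closure trace
#'
#' A time-ordered table of per-frame ring metrics for one dividing cell.
#' Stored as a `data.frame` subclass with columns `time_min`, `closure_pct`,
#' `asymmetry_pct`, `apical_displacement_um`, `r_um`, `R_um`, carrying the
#' trace identifier and cell label (e.g. VPC stage) as attributes.
#'
#' @param time_min Acquisition times in minutes, strictly increasing.
#' @param closure_pct Ring closure percentages in `[0, 100]`.
#' @param asymmetry_pct,apical_displacement_um,r_um,R_um Optional per-frame
#'   columns (default `NA`).
#' @param trace_id Identifier for the trace.
#' @param cell_label Free-text label such as the division round ("3 VPC",
#'   "6 VPC", "12 VPC") or cell type.
#' @return An object of class `ring_trace` (and `data.frame`).
#' @export
ring_trace <- function(time_min, closure_pct, asymmetry_pct = NA_real_,
                       apical_displacement_um = NA_real_, r_um = NA_real_,
                       R_um = NA_real_, trace_id = "trace",
                       cell_label = NA_character_) {
  time_min <- as.numeric(time_min)
  closure_pct <- as.numeric(closure_pct)
  n <- length(time_min)
  if (n < 5L)
    stop("a ring trace needs at least 5 frames", call. = FALSE)
  if (length(closure_pct) != n)
    stop("time and closure must have equal length", call. = FALSE)
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(closure_pct < 0 | closure_pct > 100, na.rm = TRUE))
    stop("closure percentages must lie in [0, 100]", call. = FALSE)
  out <- data.frame(time_min = time_min,
                    closure_pct = closure_pct,
                    asymmetry_pct = rep_len(as.numeric(asymmetry_pct), n),
                    apical_displacement_um =
                      rep_len(as.numeric(apical_displacement_um), n),
                    r_um = rep_len(as.numeric(r_um), n),
                    R_um = rep_len(as.numeric(R_um), n))
  attr(out, "trace_id") <- as.character(trace_id)
  attr(out, "cell_label") <- as.character(cell_label)
  class(out) <- c("ring_trace", "data.frame")
  out
}

trace_id <- function(trace) attr(trace, "trace_id") %||% "trace"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify an annotated trace into per-frame ring metrics
#'
#' Runs [frame_metrics()] over a time-ordered list of annotated frames and
#' assembles the resulting closure, asymmetry and displacement series into a
#' [ring_trace()], converting times from seconds to minutes.
#'
#' @param frames A list of [annotated_frame()]s with strictly increasing
#'   times, or the result of [simulate_trace()] (its `$frames` are used).
#' @param trace_id,cell_label Passed to [ring_trace()].
#' @param drop_bad_frames If `TRUE`, frames whose annotations are degenerate
#'   (collinear points, ring larger than cell beyond tolerance) are dropped
#'   with a warning instead of aborting the trace.
#' @param collinear_tol,closure_tol Passed to [frame_metrics()].
#' @return A [ring_trace()].
#' @export
quantify_trace <- function(frames, trace_id = NULL, cell_label = NA_character_,
                           drop_bad_frames = FALSE,
                           collinear_tol = 1e-6, closure_tol = 0.02) {
  if (inherits(frames, "simulated_trace")) {
    if (is.null(trace_id)) trace_id <- frames$trace_id
    frames <- frames$frames
  }
  if (is.null(trace_id)) trace_id <- "trace"
  stopifnot(is.list(frames), length(frames) > 0L)
  mets <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    m <- if (drop_bad_frames) {
      tryCatch(frame_metrics(frames[[i]], label = i,
                             collinear_tol = collinear_tol,
                             closure_tol = closure_tol),
               error = function(e) {
                 warning(sprintf("dropping frame %d of trace '%s': %s", i,
                                 trace_id, conditionMessage(e)),
                         call. = FALSE)
                 NULL
               })
    } else {
      frame_metrics(frames[[i]], label = i, collinear_tol = collinear_tol,
                    closure_tol = closure_tol)
    }
    mets[[i]] <- m
  }
  mets <- Filter(Negate(is.null), mets)
  if (length(mets) < 5L)
    stop(sprintf("trace '%s' has fewer than 5 usable frames", trace_id),
         call. = FALSE)
  ring_trace(
    time_min = vapply(mets, `[[`, 0, "time") / 60,
    closure_pct = vapply(mets, `[[`, 0, "closure_pct"),
    asymmetry_pct = vapply(mets, `[[`, 0, "asymmetry_pct"),
    apical_displacement_um = vapply(mets, `[[`, 0, "apical_displacement"),
    r_um = vapply(mets, function(m) m$ring$radius, 0),
    R_um = vapply(mets, function(m) m$cell$radius, 0),
    trace_id = trace_id, cell_label = cell_label
  )
}

#' Time at which closure first crosses a level
#'
#' Linear interpolation between the two frames bracketing the first upward
#' crossing of `level`. `level = 50` gives the midpoint of closure used to
#' align traces before population averaging.
#'
#' @param trace A [ring_trace()].
#' @param level Closure percentage in `(0, 100)`.
#' @return Crossing time in minutes.
#' @export
crossing_time <- function(trace, level) {
  stopifnot(inherits(trace, "ring_trace"), length(level) == 1L,
            is.finite(level))
  cc <- trace$closure_pct
  tt <- trace$time_min
  if (cc[1L] > level)
    stop(sprintf("trace '%s' already exceeds %g%% closure at its first frame",
                 trace_id(trace), level), call. = FALSE)
  if (cc[1L] == level) return(tt[1L])
  n <- length(cc)
  up <- which(cc[-n] < level & cc[-1L] >= level)
  if (length(up) == 0L)
    stop(sprintf("trace '%s' never reaches %g%% closure", trace_id(trace),
                 level), call. = FALSE)
  i <- up[1L]
  tt[i] + (level - cc[i]) * (tt[i + 1L] - tt[i]) / (cc[i + 1L] - cc[i])
}

#' Align traces at the midpoint of closure
#'
#' Shifts each trace's time axis so that its 50%-closure crossing sits at
#' time zero; order and frame spacing are preserved. Applying the alignment
#' twice is a no-op.
#'
#' @param traces A list of [ring_trace()]s, each crossing `level`.
#' @param level Alignment level, default 50 (the midpoint).
#' @return The list of aligned traces.
#' @export
align_traces <- function(traces, level = 50) {
  stopifnot(is.list(traces), length(traces) > 0L)
  lapply(traces, function(tr) {
    tr$time_min <- tr$time_min - crossing_time(tr, level)
    tr
  })
}

# Moving average with a symmetric window that shrinks near the ends, so a
# linear series is reproduced exactly everywhere.
smooth_series <- function(x, window) {
  n <- length(x)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L)
    stop("smoothing window must be odd", call. = FALSE)
  if (window > n)
    stop("smoothing window exceeds trace length", call. = FALSE)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hw <- min(h, i - 1L, n - i)
    mean(x[(i - hw):(i + hw)])
  }, 0)
}

#' Closure speed over time
#'
#' Estimates the instantaneous speed of ring closure (percentage points per
#' minute) by moving-average smoothing of the closure series followed by
#' finite differencing: central differences in the interior, one-sided at the
#' endpoints.
#'
#' @param trace A [ring_trace()] with at least 3 frames.
#' @param smooth_window Odd moving-average window in frames applied to the
#'   closure series before differentiation (default 3; 1 disables smoothing).
#' @return A `data.frame` with `time_min`, `speed_pct_per_min` and the
#'   smoothed `closure_pct`.
#' @export
speed_series <- function(trace, smooth_window = 3) {
  stopifnot(inherits(trace, "ring_trace"))
  tt <- trace$time_min
  n <- length(tt)
  if (n < 3L)
    stop("speed estimation needs at least 3 frames", call. = FALSE)
  cs <- smooth_series(trace$closure_pct, smooth_window)
  sp <- numeric(n)
  sp[1L] <- (cs[2L] - cs[1L]) / (tt[2L] - tt[1L])
  sp[n] <- (cs[n] - cs[n - 1L]) / (tt[n] - tt[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    sp[i] <- (cs[i + 1L] - cs[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  }
  data.frame(time_min = tt, speed_pct_per_min = sp, closure_pct = cs)
}

#' Average closure speed between 20% and 80% closure
#'
#' The furrowing-speed summary statistic: the ordinary least-squares slope of
#' closure versus time restricted to frames with closure in `[20, 80]`, with
#' the interpolated 20% and 80% crossing points appended as virtual samples
#' (mirroring regression lines fitted to the 20-80% window of closure
#' curves). The simpler endpoint estimate, 60 percentage points divided by
#' the 20-to-80% crossing interval, is reported alongside.
#'
#' @param trace A [ring_trace()] spanning 20% and 80% closure.
#' @return A list with `speed` (OLS slope, %/min), `endpoint_speed` (%/min)
#'   and `n` (number of points in the regression).
#' @export
average_speed_20_80 <- function(trace) {
  t20 <- crossing_time(trace, 20)
  t80 <- crossing_time(trace, 80)
  sel <- trace$closure_pct >= 20 & trace$closure_pct <= 80
  tt <- c(t20, trace$time_min[sel], t80)
  cc <- c(20, trace$closure_pct[sel], 80)
  keep <- !duplicated(cbind(tt, cc))
  tt <- tt[keep]; cc <- cc[keep]
  tc <- tt - mean(tt)
  slope <- sum(tc * (cc - mean(cc))) / sum(tc^2)
  list(speed = slope, endpoint_speed = 60 / (t80 - t20), n = length(tt))
}

#' Peak closure speed and the closure at which it occurs
#'
#' Maximum of the smoothed speed series ([speed_series()]) together with the
#' (smoothed) closure percentage at that frame. For sigmoidal closure the
#' peak sits near 50% closure. Ties in the maximum (e.g. exactly linear
#' closure) are broken by taking the middle tied frame.
#'
#' @inheritParams speed_series
#' @return A list with `speed` (%/min), `closure_at_peak` (%) and `time_min`.
#' @export
peak_speed <- function(trace, smooth_window = 3) {
  ss <- speed_series(trace, smooth_window)
  mx <- max(ss$speed_pct_per_min)
  tied <- which(ss$speed_pct_per_min >= mx - 1e-9)
  i <- tied[ceiling(length(tied) / 2)]
  list(speed = ss$speed_pct_per_min[i],
       closure_at_peak = ss$closure_pct[i],
       time_min = ss$time_min[i])
}

#' Kinetics summary for one trace
#'
#' Bundles the per-trace kinetics read-outs: midpoint time (50% crossing),
#' 20-80% average speed (OLS slope and endpoint estimate), peak speed with
#' the closure at the peak, and the 10-to-90% closure duration. Traces whose
#' smoothed closure drops by more than 5 percentage points below its running
#' maximum are rejected as non-monotone rather than silently truncated. A
#' trace must span the 20-80% core; if it does not additionally cross 10% or
#' 90% (annotation often starts late or stops once the ring nears the
#' resolution limit), `duration_10_90_min` is `NA` with a warning instead of
#' an error.
#'
#' @inheritParams speed_series
#' @return A one-row `data.frame` with columns `trace_id`, `cell_label`,
#'   `t_mid_min`, `avg_speed_20_80`, `endpoint_speed_20_80`, `peak_speed`,
#'   `closure_at_peak`, `duration_10_90_min`.
#' @export
kinetics_summary <- function(trace, smooth_window = 3) {
  stopifnot(inherits(trace, "ring_trace"))
  cs <- smooth_series(trace$closure_pct, smooth_window)
  if (max(cummax(cs) - cs) > 5)
    stop(sprintf("trace '%s' is non-monotone: smoothed closure drops > 5 points",
                 trace_id(trace)), call. = FALSE)
  avg <- average_speed_20_80(trace)
  pk <- peak_speed(trace, smooth_window)
  duration <- tryCatch(
    crossing_time(trace, 90) - crossing_time(trace, 10),
    error = function(e) {
      warning(sprintf("trace '%s': 10-90%% duration unavailable (%s)",
                      trace_id(trace), conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  data.frame(
    trace_id = trace_id(trace),
    cell_label = attr(trace, "cell_label") %||% NA_character_,
    t_mid_min = crossing_time(trace, 50),
    avg_speed_20_80 = avg$speed,
    endpoint_speed_20_80 = avg$endpoint_speed,
    peak_speed = pk$speed,
    closure_at_peak = pk$closure_at_peak,
    duration_10_90_min = duration,
    stringsAsFactors = FALSE
  )
}

#' Population-averaged curve with SEM
#'
#' Averages a per-frame quantity across traces on a common grid, reporting the
#' per-point mean, standard error of the mean (sd/sqrt(n)) and the number of
#' traces defined at each point. For `value = "closure"` or `"speed"` the
#' abscissa is time (traces are midpoint-aligned first unless `align =
#' FALSE`); for `value = "asymmetry"` the abscissa is closure percentage on a
#' 0-100 grid, the form used to compare furrow asymmetry across division
#' rounds. Traces are resampled onto the grid by linear interpolation; no
#' extrapolation is performed. Speeds are computed per trace and then
#' averaged.
#'
#' @param traces A non-empty list of [ring_trace()]s.
#' @param value One of `"closure"`, `"speed"`, `"asymmetry"`.
#' @param grid_dt Time grid spacing in minutes (default 0.5).
#' @param grid_dc Closure grid spacing in percentage points for the asymmetry
#'   curve (default 2).
#' @param align Align traces at 50% closure before time-domain averaging
#'   (default `TRUE`).
#' @param smooth_window Smoothing window for per-trace speed series.
#' @return A `data.frame` of class `population_curve` with columns `grid`,
#'   `mean`, `sem`, `n` and `low_n` (`TRUE` where fewer than 3 traces
#'   contribute).
#' @export
population_average <- function(traces, value = c("closure", "speed",
                                                 "asymmetry"),
                               grid_dt = 0.5, grid_dc = 2, align = TRUE,
                               smooth_window = 3) {
  value <- match.arg(value)
  if (!is.list(traces) || length(traces) == 0L)
    stop("at least one trace is required", call. = FALSE)
  if (value == "asymmetry") {
    grid <- seq(0, 100, by = grid_dc)
    series <- lapply(traces, function(tr) {
      stats::approx(tr$closure_pct, tr$asymmetry_pct, xout = grid,
                    rule = 1, ties = mean)$y
    })
  } else {
    if (align) traces <- align_traces(traces)
    series_xy <- lapply(traces, function(tr) {
      if (value == "speed") {
        ss <- speed_series(tr, smooth_window)
        list(x = ss$time_min, y = ss$speed_pct_per_min)
      } else {
        list(x = tr$time_min, y = tr$closure_pct)
      }
    })
    rng <- range(unlist(lapply(series_xy, `[[`, "x")))
    grid <- seq(floor(rng[1L] / grid_dt) * grid_dt,
                ceiling(rng[2L] / grid_dt) * grid_dt, by = grid_dt)
    series <- lapply(series_xy, function(s) {
      stats::approx(s$x, s$y, xout = grid, rule = 1, ties = mean)$y
    })
  }
  mat <- do.call(cbind, series)
  n <- rowSums(!is.na(mat))
  keep <- n >= 1L
  mat <- mat[keep, , drop = FALSE]
  grid <- grid[keep]
  n <- n[keep]
  mean_ <- rowMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  structure(
    data.frame(grid = grid, mean = mean_, sem = sem, n = n, low_n = n < 3L),
    class = c("population_curve", "data.frame"),
    value = value
  )
}

#' Asymmetry interpolated at a given closure level
#'
#' Furrow asymmetry at a fixed extent of closure (e.g. 80%), interpolated
#' linearly in closure between the frames bracketing the first upward
#' crossing. This is the quantity compared across groups at "80% closed".
#'
#' @param trace A [ring_trace()] crossing `level`.
#' @param level Closure percentage.
#' @return Asymmetry percentage at the crossing.
#' @export
asymmetry_at_closure <- function(trace, level) {
  stopifnot(inherits(trace, "ring_trace"))
  cc <- trace$closure_pct
  aa <- trace$asymmetry_pct
  if (cc[1L] > level)
    stop(sprintf("trace '%s' already exceeds %g%% closure at its first frame",
                 trace_id(trace), level), call. = FALSE)
  if (cc[1L] == level) return(aa[1L])
  n <- length(cc)
  up <- which(cc[-n] < level & cc[-1L] >= level)
  if (length(up) == 0L)
    stop(sprintf("trace '%s' never reaches %g%% closure", trace_id(trace),
                 level), call. = FALSE)
  i <- up[1L]
  frac <- (level - cc[i]) / (cc[i + 1L] - cc[i])
  aa[i] + frac * (aa[i + 1L] - aa[i])
}

#' Fit a logistic closure curve to a trace
#'
#' Least-squares fit of the symmetric sigmoid
#' `closure(t) = 100 / (1 + exp(-k (t - t0)))` to a trace, via [stats::nls()]
#' with starting values derived from the 20-80% crossing interval
#' (`k0 = 2 log(4) / (t80 - t20)`) and the midpoint time.
#'
#' @param trace A [ring_trace()] spanning 20% and 80% closure.
#' @return A list with `k` (per minute), `t0` (minutes) and the `nls` `fit`.
#' @export
fit_logistic <- function(trace) {
  stopifnot(inherits(trace, "ring_trace"))
  t20 <- crossing_time(trace, 20)
  t80 <- crossing_time(trace, 80)
  start <- list(k = 2 * log(4) / (t80 - t20),
                t0 = crossing_time(trace, 50))
  df <- data.frame(t = trace$time_min, c = trace$closure_pct)
  fit <- stats::nls(c ~ 100 / (1 + exp(-k * (t - t0))), data = df,
                    start = start)
  est <- stats::coef(fit)
  list(k = unname(est["k"]), t0 = unname(est["t0"]), fit = fit)
}
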