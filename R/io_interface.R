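# Annotation CSV reading/writing and the simulate -> quantify -> summarize
# pipeline driver. CSV files are comma-separated UTF-8 with '.' decimals and
# a '#'-prefixed header block echoing the configuration; coordinates are
# stored as 0-based pixels and converted to micrometres in memory.

.annotation_cols <- c("trace_id", "time_s",
                      "cx1", "cy1", "cx2", "cy2", "cx3", "cy3",
                      "rx1", "ry1", "rx2", "ry2", "rx3", "ry3",
                      "apical_x", "apical_y")

#' Pipeline run configuration
#'
#' Bundles the physical calibration and analysis parameters shared by the
#' pipeline stages. The defaults mirror a typical swept-field confocal
#' acquisition of dividing epithelial cells: 0.6 um z steps and 30 second
#' frame intervals.
#'
#' @param pixel_size_um Pixel size in micrometres.
#' @param z_step_um z-step size in micrometres (default 0.6).
#' @param frame_interval_s Frame interval in seconds (default 30).
#' @param smooth_window Odd moving-average window (frames) for speed
#'   estimation.
#' @param collinear_tol Collinearity tolerance for circle fits.
#' @param closure_tol Clamping tolerance on `r/R` above 1.
#' @param enrichment_k Threshold multiplier for [ring_breadth()].
#' @param grid_dt_min,grid_closure_pct Population-curve grid spacings.
#' @param n_traces Number of traces to simulate when no annotation file is
#'   supplied to [run_pipeline()].
#' @param seed Integer seed for simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 0.1, z_step_um = 0.6,
                       frame_interval_s = 30, smooth_window = 3,
                       collinear_tol = 1e-6, closure_tol = 0.02,
                       enrichment_k = 2, grid_dt_min = 0.5,
                       grid_closure_pct = 2, n_traces = 3, seed = 1L) {
  stopifnot(pixel_size_um > 0, z_step_um > 0, frame_interval_s > 0,
            smooth_window >= 1, n_traces >= 1)
  structure(
    list(pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         frame_interval_s = frame_interval_s,
         smooth_window = as.integer(smooth_window),
         collinear_tol = collinear_tol, closure_tol = closure_tol,
         enrichment_k = enrichment_k, grid_dt_min = grid_dt_min,
         grid_closure_pct = grid_closure_pct,
         n_traces = as.integer(n_traces), seed = as.integer(seed)),
    class = "run_config"
  )
}

config_header <- function(config, extra = character()) {
  vals <- config[!vapply(config, is.null, TRUE)]
  c(sprintf("# %s: %s", names(vals),
            vapply(vals, function(v) paste(format(v, digits = 15),
                                           collapse = " "), "")),
    extra)
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write annotated traces to an annotation CSV
#'
#' Serializes traces of three-point annotations to the annotation schema:
#' one row per frame with columns `trace_id`, `time_s`, the three cell
#' points `cx1..cy3`, the three ring points `rx1..ry3`, and the apical axis.
#' Coordinates are written as 0-based pixels (`um / pixel_size_um`); the
#' pixel size is recorded in the `#` header so files are self-describing.
#'
#' @param traces A [simulate_trace()] result, a list of such results, or a
#'   named list of [annotated_frame()] lists (names are trace ids).
#' @param path Output CSV path.
#' @param pixel_size_um Pixel size used for the micrometre-to-pixel
#'   conversion.
#' @return The path, invisibly.
#' @export
write_annotations <- function(traces, path, pixel_size_um = 0.1) {
  stopifnot(pixel_size_um > 0)
  if (inherits(traces, "simulated_trace")) traces <- list(traces)
  norm <- list()
  for (i in seq_along(traces)) {
    el <- traces[[i]]
    if (inherits(el, "simulated_trace")) {
      norm[[el$trace_id]] <- el$frames
    } else {
      id <- names(traces)[i] %||% sprintf("trace%02d", i)
      if (is.null(names(traces)) || !nzchar(id)) id <- sprintf("trace%02d", i)
      norm[[id]] <- el
    }
  }
  rows <- lapply(names(norm), function(id) {
    do.call(rbind, lapply(norm[[id]], function(fr) {
      stopifnot(inherits(fr, "annotated_frame"))
      cp <- fr$cell_points / pixel_size_um
      rp <- fr$ring_points / pixel_size_um
      data.frame(trace_id = id, time_s = fr$time,
                 cx1 = cp[1, 1], cy1 = cp[1, 2], cx2 = cp[2, 1],
                 cy2 = cp[2, 2], cx3 = cp[3, 1], cy3 = cp[3, 2],
                 rx1 = rp[1, 1], ry1 = rp[1, 2], rx2 = rp[2, 1],
                 ry2 = rp[2, 2], rx3 = rp[3, 1], ry3 = rp[3, 2],
                 apical_x = fr$apical_axis[1], apical_y = fr$apical_axis[2],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  write_csv_with_header(df, path,
                        sprintf("# pixel_size_um: %s",
                                format(pixel_size_um, digits = 15)))
}

#' Read an annotation CSV into annotated frames
#'
#' Parses the annotation schema written by [write_annotations()], validates
#' it (schema columns, finite values, strictly increasing times within each
#' trace), converts pixel coordinates to micrometres, and groups frames by
#' trace. The pixel size is taken from the `# pixel_size_um:` header unless
#' overridden.
#'
#' @param path Annotation CSV path.
#' @param pixel_size_um Optional pixel-size override; required when the file
#'   has no header.
#' @return A named list (one element per trace id) of [annotated_frame()]
#'   lists. A header-only file yields an empty list with a warning.
#' @export
read_annotations <- function(path, pixel_size_um = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("^#\\s*pixel_size_um:\\s*([0-9.eE+-]+)", hdr))
  ps_hdr <- unlist(lapply(m, function(x) if (length(x) == 2L) x[2L]))
  if (is.null(pixel_size_um)) {
    if (length(ps_hdr) == 0L)
      stop("missing pixel size: no 'pixel_size_um' header and no override",
           call. = FALSE)
    pixel_size_um <- as.numeric(ps_hdr[1L])
  }
  stopifnot(is.finite(pixel_size_um), pixel_size_um > 0)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.annotation_cols, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("annotation schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("annotation file contains a header but no rows", call. = FALSE)
    return(list())
  }
  num_cols <- setdiff(.annotation_cols, "trace_id")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop(sprintf("annotation schema error: column '%s' must be finite numeric",
                   cl), call. = FALSE)
  }
  out <- list()
  for (id in unique(df$trace_id)) {
    sub <- df[df$trace_id == id, , drop = FALSE]
    bad <- which(diff(sub$time_s) <= 0)
    if (length(bad) > 0L)
      stop(sprintf(
        "non-monotone time in trace '%s': row %d (time_s = %g) does not increase",
        id, which(df$trace_id == id)[bad[1L] + 1L], sub$time_s[bad[1L] + 1L]),
        call. = FALSE)
    out[[id]] <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      annotated_frame(
        time = r$time_s,
        cell_points = rbind(c(r$cx1, r$cy1), c(r$cx2, r$cy2),
                            c(r$cx3, r$cy3)) * pixel_size_um,
        ring_points = rbind(c(r$rx1, r$ry1), c(r$rx2, r$ry2),
                            c(r$rx3, r$ry3)) * pixel_size_um,
        apical_axis = c(r$apical_x, r$apical_y)
      )
    })
  }
  out
}

#' Run the full closure-kinetics pipeline
#'
#' Executes simulate (optional) -> quantify -> summarize -> population
#' averaging and writes the result CSVs: per-frame trace metrics
#' (`traces.csv`), per-trace kinetics summaries (`summary.csv`), and
#' population curves for closure, speed and asymmetry
#' (`population_<value>.csv`). When traces are simulated, a kymograph of the
#' first trace's division-plane movie is written as a 16-bit grayscale TIFF.
#' Every CSV carries the configuration in its `#` header, so a rerun with
#' the same inputs and seed is byte-identical. Traces that fail to quantify
#' or summarize are reported as warnings and skipped; the run fails only if
#' no trace survives.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param annotations Optional annotation CSV path; when `NULL`,
#'   `config$n_traces` traces are simulated from `model`.
#' @param model A [closure_model()] used in simulation mode; its seed is
#'   offset per trace from `config$seed`.
#' @return Invisibly, a list with the quantified `traces`, the `summary`
#'   table, the population `curves`, and the output `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         annotations = NULL, model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- NULL
  if (is.null(annotations)) {
    if (is.null(model)) model <- closure_model(seed = config$seed)
    simulated <- lapply(seq_len(config$n_traces), function(i) {
      mi <- model
      mi$seed <- config$seed + i - 1L
      simulate_trace(mi, trace_id = sprintf("sim%02d", i))
    })
    frame_sets <- stats::setNames(lapply(simulated, `[[`, "frames"),
                                  vapply(simulated, `[[`, "", "trace_id"))
  } else {
    frame_sets <- read_annotations(annotations,
                                   pixel_size_um = config$pixel_size_um)
    if (length(frame_sets) == 0L)
      stop("no traces found in annotation file", call. = FALSE)
  }
  traces <- list()
  for (id in names(frame_sets)) {
    tr <- tryCatch(
      quantify_trace(frame_sets[[id]], trace_id = id,
                     drop_bad_frames = TRUE,
                     collinear_tol = config$collinear_tol,
                     closure_tol = config$closure_tol),
      error = function(e) {
        warning(sprintf("skipping trace '%s': %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(tr)) traces[[id]] <- tr
  }
  if (length(traces) == 0L)
    stop("no trace could be quantified", call. = FALSE)
  summaries <- list()
  for (id in names(traces)) {
    sm <- tryCatch(kinetics_summary(traces[[id]], config$smooth_window),
                   error = function(e) {
                     warning(sprintf("no summary for trace '%s': %s", id,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(sm)) summaries[[id]] <- sm
  }
  summary_df <- if (length(summaries) > 0L) do.call(rbind, summaries)
                else data.frame()
  curves <- list(
    closure = population_average(traces, "closure",
                                 grid_dt = config$grid_dt_min,
                                 smooth_window = config$smooth_window),
    speed = population_average(traces, "speed",
                               grid_dt = config$grid_dt_min,
                               smooth_window = config$smooth_window),
    asymmetry = population_average(traces, "asymmetry",
                                   grid_dc = config$grid_closure_pct)
  )
  hdr <- config_header(config)
  trace_df <- do.call(rbind, lapply(names(traces), function(id) {
    cbind(trace_id = id, as.data.frame(traces[[id]]))
  }))
  paths <- list(traces = file.path(out_dir, "traces.csv"),
                summary = file.path(out_dir, "summary.csv"),
                population = stats::setNames(
                  file.path(out_dir, sprintf("population_%s.csv",
                                             names(curves))),
                  names(curves)))
  write_csv_with_header(trace_df, paths$traces, hdr)
  write_csv_with_header(summary_df, paths$summary, hdr)
  for (v in names(curves))
    write_csv_with_header(as.data.frame(curves[[v]]), paths$population[[v]],
                          hdr)
  if (!is.null(simulated)) {
    stack <- render_division_plane_movie(simulated[[1L]]$truth,
                                         image_model(seed = config$seed))
    kymo <- make_kymograph(stack, axis = "horizontal")
    paths$kymograph <- file.path(out_dir, "kymograph.tif")
    tiff::writeTIFF(kymo / max(kymo), paths$kymograph, bits.per.sample = 16L)
  }
  invisible(list(traces = traces, summary = summary_df, curves = curves,
                 paths = paths))
}
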