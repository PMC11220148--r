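# Pressure-mat recordings: reading, windowing, averaging, unit conversion
# and heatmap export. The mat is a 24x48 sensor grid (width x length) with
# 36.25 mm cell pitch; raw values are non-negative scalars in mmHg or N.

#' Construct a pressure-mat recording
#'
#' A recording is an ordered series of 24x48 frames with strictly increasing
#' timestamps. Values are scalar sensor readings, all non-negative, in
#' either mmHg (raw mat output) or Newtons per cell.
#'
#' @param frames list of 24x48 numeric matrices.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing, same length as `frames`.
#' @param units `"mmHg"` or `"N"`.
#' @return an object of class `pressure_recording`.
#' @export
pressure_recording <- function(frames, timestamps, units = c("mmHg", "N")) {
  units <- match.arg(units)
  if (length(frames) != length(timestamps))
    stop_vecforce("frames and timestamps must have equal length", "shape_error")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop_vecforce("timestamps must be strictly increasing", "validation_error")
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != GRID_NROW || ncol(f) != GRID_NCOL)
      stop_vecforce(sprintf("every frame must be %dx%d", GRID_NROW, GRID_NCOL),
                    "shape_error")
    if (any(!is.finite(f)) || any(f < 0))
      stop_vecforce("frame values must be finite and >= 0", "validation_error")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 units = units),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> %d frames, %.2f s, units %s\n",
              length(x$frames),
              if (length(x$timestamps)) diff(range(x$timestamps)) else 0,
              x$units))
  invisible(x)
}

#' Construct a pressure grid
#'
#' A single 24x48 matrix of per-cell scalar force, the time-averaged product
#' of a recording. Row index runs along the mat width (x), column index
#' along its length (y); the lower-left cell is `values[1, 1]` and the cell
#' centre of `values[i, j]` sits at `((i - 0.5) * pitch, (j - 0.5) * pitch)`
#' in the mat frame.
#'
#' @param values 24x48 non-negative numeric matrix.
#' @param units `"mmHg"` or `"N"`.
#' @param cell_pitch cell spacing in mm (default 36.25).
#' @param frame name of the planar coordinate frame the grid lives in.
#' @param origin origin convention; only `"lower_left"` is used by the
#'   pipeline, recorded explicitly to prevent silent flips.
#' @return an object of class `pressure_grid`.
#' @export
pressure_grid <- function(values, units = c("mmHg", "N"),
                          cell_pitch = CELL_PITCH_MM, frame = "mat",
                          origin = c("lower_left", "centroid")) {
  units <- match.arg(units)
  origin <- match.arg(origin)
  if (!is.matrix(values) || nrow(values) != GRID_NROW || ncol(values) != GRID_NCOL)
    stop_vecforce(sprintf("grid must be %dx%d", GRID_NROW, GRID_NCOL),
                  "shape_error")
  if (any(!is.finite(values)) || any(values < 0))
    stop_vecforce("grid values must be finite and >= 0", "validation_error")
  if (cell_pitch <= 0) stop_vecforce("cell_pitch must be > 0", "validation_error")
  structure(list(values = values, units = units, cell_pitch = cell_pitch,
                 frame = frame, origin = origin),
            class = "pressure_grid")
}

#' @export
print.pressure_grid <- function(x, ...) {
  cat(sprintf("<pressure_grid> %dx%d, pitch %.2f mm, units %s, total %.2f\n",
              nrow(x$values), ncol(x$values), x$cell_pitch, x$units,
              sum(x$values)))
  invisible(x)
}

#' Cell-centre coordinates of a pressure grid
#'
#' @param grid a [pressure_grid()].
#' @return data.frame with columns `row`, `col`, `x_mm`, `y_mm` for all
#'   24x48 cells (row-major over rows then columns).
#' @export
cell_centers <- function(grid) {
  ij <- expand.grid(row = seq_len(GRID_NROW), col = seq_len(GRID_NCOL))
  data.frame(row = ij$row, col = ij$col,
             x_mm = (ij$row - 0.5) * grid$cell_pitch,
             y_mm = (ij$col - 0.5) * grid$cell_pitch)
}

#' Read a pressure-mat recording from CSV or JSON
#'
#' The CSV layout carries one frame per 24 lines of 48 comma-separated
#' values, each frame preceded by a header line `# t=<seconds>`. The JSON
#' layout is `{"timestamps": [...], "frames": [[[...]]]}` with each frame a
#' 24-element list of 48-element rows.
#'
#' @param path file path.
#' @param units unit tag of the stored values, `"mmHg"` or `"N"`.
#' @return a [pressure_recording()].
#' @export
read_pressure_recording <- function(path, units = c("mmHg", "N")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_vecforce(paste("no such file:", path), "io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    frames <- lapply(seq_along(obj$timestamps), function(i) {
      f <- obj$frames[i, , ]
      matrix(as.numeric(f), nrow = GRID_NROW, ncol = GRID_NCOL)
    })
    return(pressure_recording(frames, obj$timestamps, units))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^#\\s*t\\s*=", lines)
  if (!length(hdr)) stop_vecforce("no frame headers '# t=<s>' found", "format_error")
  ts <- as.numeric(sub("^#\\s*t\\s*=\\s*", "", lines[hdr]))
  bounds <- c(hdr, length(lines) + 1L)
  frames <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(block, function(l) as.numeric(strsplit(l, ",")[[1]]))
    nc <- lengths(rows)
    if (length(rows) != GRID_NROW || any(nc != GRID_NCOL))
      stop_vecforce(sprintf(
        "frame %d is %dx%s, expected %dx%d", i, length(rows),
        paste(unique(nc), collapse = "/"), GRID_NROW, GRID_NCOL),
        "shape_error")
    frames[[i]] <- do.call(rbind, rows)
  }
  pressure_recording(frames, ts, units)
}

#' Write a pressure-mat recording as framed CSV
#'
#' Inverse of [read_pressure_recording()]'s CSV layout.
#'
#' @param rec a [pressure_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pressure_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rec$frames)) {
    writeLines(sprintf("# t=%.17g", rec$timestamps[i]), con)
    writeLines(apply(rec$frames[[i]], 1L,
                     function(r) paste(sprintf("%.17g", r), collapse = ",")),
               con)
  }
  invisible(path)
}

#' Read a pre-averaged pressure grid from a single-matrix CSV
#'
#' @param path CSV with 24 lines of 48 values (no header).
#' @param units unit tag.
#' @return a [pressure_grid()].
#' @export
read_pressure_grid <- function(path, units = c("mmHg", "N")) {
  units <- match.arg(units)
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  pressure_grid(m, units)
}

#' Write a pressure grid as a single-matrix CSV
#'
#' @param grid a [pressure_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pressure_grid <- function(grid, path) {
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Select the centred time window of a recording
#'
#' Steady-state analysis discards the settling transients at both ends of a
#' trial: frames are kept whose timestamps fall in the closed interval
#' `[t_mid - window_s/2, t_mid + window_s/2]`, with `t_mid` the midpoint of
#' the first and last timestamp. The study protocol records 30 s and keeps
#' the middle 10 s.
#'
#' @param rec a [pressure_recording()].
#' @param window_s window length in seconds.
#' @return a [pressure_recording()] restricted to the window.
#' @export
select_middle_window <- function(rec, window_s = 10) {
  dur <- diff(range(rec$timestamps))
  if (window_s > dur)
    stop_vecforce(sprintf("window %.3g s exceeds recording duration %.3g s",
                          window_s, dur), "range_error")
  t_mid <- (rec$timestamps[1] + rec$timestamps[length(rec$timestamps)]) / 2
  keep <- rec$timestamps >= t_mid - window_s / 2 &
    rec$timestamps <= t_mid + window_s / 2
  pressure_recording(rec$frames[keep], rec$timestamps[keep], rec$units)
}

#' Average the frames of a recording into a pressure grid
#'
#' Per-cell arithmetic mean over all frames; units are preserved.
#'
#' @param rec a [pressure_recording()] with at least one frame.
#' @return a [pressure_grid()].
#' @export
average_frames <- function(rec) {
  if (!length(rec$frames)) stop_vecforce("recording has no frames", "empty_error")
  acc <- Reduce(`+`, rec$frames)
  pressure_grid(acc / length(rec$frames), rec$units)
}

#' Convert a pressure grid from mmHg to per-cell force in Newtons
#'
#' Each sensor reading in mmHg is converted to the force on its full cell:
#' `F[N] = P[mmHg] * 133.322 Pa/mmHg * (pitch in m)^2`. With the default
#' 36.25 mm pitch one mmHg corresponds to about 0.17519 N. The conversion
#' constant is exposed for calibrated devices.
#'
#' @param grid a [pressure_grid()] in mmHg.
#' @param pa_per_mmhg pascals per mmHg (default 133.322).
#' @return a [pressure_grid()] in N.
#' @export
convert_to_newtons <- function(grid, pa_per_mmhg = 133.322) {
  if (grid$units != "mmHg")
    stop_vecforce("grid is already in N", "unit_error")
  area_m2 <- (grid$cell_pitch / 1000)^2
  pressure_grid(grid$values * pa_per_mmhg * area_m2, "N",
                cell_pitch = grid$cell_pitch, frame = grid$frame,
                origin = grid$origin)
}

#' Write a heatmap of a pressure grid to PNG
#'
#' Orientation follows the mat frame: the `values[1, 1]` cell is drawn at
#' the lower-left of the image, width (x) horizontal, length (y) vertical.
#'
#' @param grid a [pressure_grid()].
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
to_heatmap <- function(grid, path, width = 480, height = 820) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_vecforce(paste("no such directory:", dir), "io_error")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  # image() plots x along rows and y along columns, so the grid is drawn
  # directly: row 1 / col 1 ends up lower-left.
  zl <- range(grid$values)
  if (diff(zl) == 0) zl <- zl + c(0, 1)
  graphics::image(x = (seq_len(GRID_NROW) - 0.5) * grid$cell_pitch,
                  y = (seq_len(GRID_NCOL) - 0.5) * grid$cell_pitch,
                  z = grid$values, zlim = zl, col = pal, useRaster = TRUE,
                  xlab = "x (width, mm)", ylab = "y (length, mm)",
                  main = sprintf("pressure (%s)", grid$units), asp = 1)
  invisible(path)
}
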