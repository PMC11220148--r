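# From registered geometry to vector forces: bin scan points into sensor
# cells, average per-cell unit normals, and scale each cell's scalar force
# along its normal. The scalar a mat sensor reports acts perpendicular to
# the local (deformed) surface, so F_vec = F * n_hat recovers both the
# normal and the shear components in the mat frame.

#' Bin surface points into pressure-mat cells
#'
#' Each point is assigned to exactly one cell by half-open intervals
#' `[lo, lo + pitch)` on both axes from the grid's lower-left origin;
#' points outside the 24x48 footprint are discarded and counted.
#'
#' @param cloud a [surface_cloud()] in the grid's frame (post-registration).
#' @param grid a [pressure_grid()] supplying the geometry.
#' @return object of class `cell_bins`: list with `idx` (per-cell list of
#'   point row indices, 24x48), `counts` (24x48 matrix) and `discarded`
#'   (count of out-of-footprint points).
#' @export
bin_points_to_cells <- function(cloud, grid) {
  if (!identical(cloud$frame, grid$frame))
    stop_vecforce(sprintf("frame mismatch: cloud '%s' vs grid '%s'",
                          cloud$frame, grid$frame), "frame_error")
  pitch <- grid$cell_pitch
  i <- floor(cloud$points[, 1] / pitch) + 1L
  j <- floor(cloud$points[, 2] / pitch) + 1L
  inside <- i >= 1L & i <= GRID_NROW & j >= 1L & j <= GRID_NCOL
  lin <- (j[inside] - 1L) * GRID_NROW + i[inside]
  idx_all <- which(inside)
  idx <- split(idx_all, factor(lin, levels = seq_len(GRID_NROW * GRID_NCOL)))
  counts <- matrix(lengths(idx), GRID_NROW, GRID_NCOL)
  structure(list(idx = idx, counts = counts,
                 discarded = sum(!inside)),
            class = "cell_bins")
}

#' Mean unit normal of a set of point normals
#'
#' Componentwise mean of the per-point normals, then normalisation to unit
#' length. A near-zero mean (opposing normals cancelling) indicates a
#' registration failure and raises rather than silently returning vertical.
#'
#' @param normals n x 3 matrix of unit normals, n >= 1.
#' @return unit length-3 vector.
#' @export
cell_mean_unit_normal <- function(normals) {
  normals <- matrix(as.numeric(normals), ncol = 3)
  if (!nrow(normals)) stop_vecforce("no normals in cell", "degenerate_error")
  m <- colMeans(normals)
  len <- vnorm(m)
  if (len < 1e-9)
    stop_vecforce("mean normal has near-zero norm (opposing normals cancel)",
                  "degenerate_error")
  m / len
}

#' Per-cell mean unit normals over the sensor grid
#'
#' @param cloud a [surface_cloud()] with normals, already in the mat frame.
#' @param grid a [pressure_grid()] supplying the geometry.
#' @param bins optional precomputed [bin_points_to_cells()] result.
#' @return object of class `cell_normal_field`: `counts` (24x48), `nx`,
#'   `ny`, `nz` (24x48 unit-normal components, NA where a cell is empty),
#'   `discarded`, plus grid geometry.
#' @export
cell_normal_field <- function(cloud, grid, bins = NULL) {
  if (is.null(cloud$normals))
    stop_vecforce("cloud has no normals; run estimate_normals() first",
                  "validation_error")
  if (is.null(bins)) bins <- bin_points_to_cells(cloud, grid)
  nx <- ny <- nz <- matrix(NA_real_, GRID_NROW, GRID_NCOL)
  occ <- which(bins$counts > 0)
  for (lin in occ) {
    n <- cell_mean_unit_normal(cloud$normals[bins$idx[[lin]], , drop = FALSE])
    nx[lin] <- n[1]; ny[lin] <- n[2]; nz[lin] <- n[3]
  }
  structure(list(counts = bins$counts, nx = nx, ny = ny, nz = nz,
                 discarded = bins$discarded, cell_pitch = grid$cell_pitch,
                 frame = grid$frame),
            class = "cell_normal_field")
}

#' @export
print.cell_normal_field <- function(x, ...) {
  cat(sprintf("<cell_normal_field> %d/%d occupied cells, %d points discarded\n",
              sum(x$counts > 0), length(x$counts), x$discarded))
  invisible(x)
}

#' Vector force of one cell
#'
#' Scales the scalar sensor force along the cell's unit normal:
#' `F_vec = F * n_hat`, so the force magnitude equals the sensor reading
#' and the direction follows the deformed surface.
#'
#' @param F scalar force in N, >= 0.
#' @param n_hat unit normal (length-3).
#' @return length-3 force vector (fx, fy, fz) in N.
#' @export
compute_vector_force <- function(F, n_hat) {
  if (F < 0) stop_vecforce("scalar force must be >= 0", "validation_error")
  if (abs(vnorm(n_hat) - 1) > 1e-6)
    stop_vecforce("n_hat must be a unit vector within 1e-6", "validation_error")
  F * as.numeric(n_hat)
}

#' Assemble the vector force field over the grid
#'
#' Applies `F_vec = F * n_hat` per cell. Cells carrying force but no scan
#' points (scan shadows) are handled per `policy`:
#' \describe{
#'   \item{nearest}{borrow the mean unit normal of the `k` scan points
#'     nearest to the cell centre; fall back to vertical if none lie within
#'     two cell pitches (requires `cloud`).}
#'   \item{vertical}{use (0, 0, 1).}
#'   \item{strict}{raise a coverage error.}
#' }
#'
#' @param grid a [pressure_grid()] in N.
#' @param normals a [cell_normal_field()] sharing the grid geometry.
#' @param cloud the registered [surface_cloud()] with normals; needed for
#'   `policy = "nearest"`.
#' @param policy empty-cell policy.
#' @param k neighbour count for the nearest policy.
#' @return object of class `force_field`: data.frame with columns `row`,
#'   `col`, `x_mm`, `y_mm`, `F_N`, `fx_N`, `fy_N`, `fz_N`, `n_points` for
#'   every loaded cell, with attributes `filled_cells` (count handled by
#'   the policy) and `discarded_points`.
#' @export
compute_force_field <- function(grid, normals, cloud = NULL,
                                policy = c("nearest", "vertical", "strict"),
                                k = 8L) {
  policy <- match.arg(policy)
  if (grid$units != "N")
    stop_vecforce("grid must be in N (convert_to_newtons first)", "unit_error")
  cc <- cell_centers(grid)
  f <- grid$values[cbind(cc$row, cc$col)]
  loaded <- which(f > 0)
  lin <- (cc$col[loaded] - 1L) * GRID_NROW + cc$row[loaded]
  have_normal <- normals$counts[lin] > 0
  miss <- loaded[!have_normal]
  if (length(miss) && policy == "strict")
    stop_vecforce(sprintf(
      "%d loaded cells have no scan points (strict empty-cell policy)",
      length(miss)), "coverage_error")
  n_mat <- cbind(normals$nx[lin], normals$ny[lin], normals$nz[lin])
  if (length(miss)) {
    if (policy == "vertical" || is.null(cloud)) {
      if (policy == "nearest" && is.null(cloud))
        stop_vecforce("policy 'nearest' needs the registered cloud", "input_error")
      n_mat[!have_normal, ] <- matrix(c(0, 0, 1), length(miss), 3, byrow = TRUE)
    } else {
      if (is.null(cloud$normals))
        stop_vecforce("cloud has no normals", "validation_error")
      centers <- cbind(cc$x_mm[miss], cc$y_mm[miss], 0)
      kk <- min(k, nrow(cloud$points))
      nn <- RANN::nn2(cloud$points[, 1:2, drop = FALSE],
                      centers[, 1:2, drop = FALSE], k = kk)
      for (m in seq_along(miss)) {
        within <- nn$nn.dists[m, ] <= 2 * grid$cell_pitch
        n_mat[which(!have_normal)[m], ] <- if (any(within))
          cell_mean_unit_normal(cloud$normals[nn$nn.idx[m, within], , drop = FALSE])
        else c(0, 0, 1)
      }
    }
  }
  fvec <- n_mat * f[loaded]
  out <- data.frame(row = cc$row[loaded], col = cc$col[loaded],
                    x_mm = cc$x_mm[loaded], y_mm = cc$y_mm[loaded],
                    F_N = f[loaded],
                    fx_N = fvec[, 1], fy_N = fvec[, 2], fz_N = fvec[, 3],
                    n_points = normals$counts[lin])
  structure(out, class = c("force_field", "data.frame"),
            filled_cells = length(miss),
            discarded_points = normals$discarded)
}

#' Write / read a vector force field as CSV
#'
#' Columns: row, col, x_mm, y_mm, F_N, fx_N, fy_N, fz_N, n_points.
#'
#' @param field a [compute_force_field()] result.
#' @param path file path.
#' @return `path` (write) or a `force_field` (read).
#' @export
write_force_field <- function(field, path) {
  write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_field
#' @export
read_force_field <- function(path) {
  df <- read.csv(path)
  need <- c("row", "col", "x_mm", "y_mm", "F_N", "fx_N", "fy_N", "fz_N")
  if (!all(need %in% names(df)))
    stop_vecforce("force-field CSV lacks required columns", "format_error")
  if (!"n_points" %in% names(df)) df$n_points <- NA_integer_
  structure(df, class = c("force_field", "data.frame"))
}
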