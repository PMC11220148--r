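# End-to-end pipeline: pressure grid + mattress scan -> registered frames
# -> per-cell normals -> vector force field, plus the validation and
# region-reduction wrappers used by the command-line script in inst/cli.

#' Compute the interface vector force field
#'
#' Runs the whole measurement chain: expand the pressure grid into a point
#' cloud scaled to the scan's z extent, register it onto the scan (coarse
#' principal-axis alignment then point-to-point ICP), carry the scan back
#' into the mat frame with the inverse transform, estimate scan normals if
#' absent, bin scan points into sensor cells, average per-cell unit
#' normals, and scale each cell's scalar force along its normal.
#'
#' @param grid a [pressure_grid()] in N (use [convert_to_newtons()] first
#'   for raw mmHg grids).
#' @param scan a [surface_cloud()] of the deformed mattress surface.
#' @param init optional initial [rigid_transform()] (skips the automatic
#'   coarse alignment).
#' @param max_corr_dist,max_iter,tol ICP settings, see [icp_refine()].
#' @param policy empty-cell policy, see [compute_force_field()].
#' @param normal_k neighbour count for [estimate_normals()].
#' @return list with `field` (the `force_field`), `registration`
#'   (`registration_result`), `normals` (`cell_normal_field`), `cloud_mat`
#'   (the scan in the mat frame, with normals), and `log` (named counts:
#'   discarded points, policy-filled cells, ICP iterations).
#' @export
compute_interface_forces <- function(grid, scan, init = NULL,
                                     max_corr_dist = 2 * CELL_PITCH_MM,
                                     max_iter = 200L, tol = 1e-6,
                                     policy = c("nearest", "vertical", "strict"),
                                     normal_k = 12L) {
  policy <- match.arg(policy)
  if (grid$units != "N")
    stop_vecforce("stage expand: grid must be in N", "unit_error")
  zr <- range(scan$points[, 3])
  src <- expand_pressure_cloud(grid, z_max = zr[2], z_min = zr[1])
  reg <- register_clouds(src, scan, init = init,
                         max_corr_dist = max_corr_dist,
                         max_iter = max_iter, tol = tol)
  cloud_mat <- apply_transform(scan, invert_transform(reg$transform),
                               frame = grid$frame)
  if (is.null(cloud_mat$normals))
    cloud_mat <- estimate_normals(cloud_mat, k = normal_k)
  bins <- bin_points_to_cells(cloud_mat, grid)
  normals <- cell_normal_field(cloud_mat, grid, bins)
  field <- compute_force_field(grid, normals, cloud = cloud_mat,
                               policy = policy)
  list(field = field, registration = reg, normals = normals,
       cloud_mat = cloud_mat,
       log = c(discarded_points = normals$discarded,
               filled_cells = attr(field, "filled_cells"),
               icp_iterations = reg$iterations))
}

#' Validate a force field against body weight
#'
#' @param field a `force_field`.
#' @param body_weight G in N.
#' @param label optional trial label.
#' @return a [trial_summary()].
#' @export
validate_forces <- function(field, body_weight, label = NA_character_) {
  trial_summary(field, body_weight, label)
}

#' Reduce a force field to regional boundary conditions
#'
#' @param field a `force_field`.
#' @param regions a [region_spec()] (or path to a YAML/JSON region file).
#' @param posture posture label for the export.
#' @param path optional JSON output path.
#' @return the `regional_wrench_set` (invisibly if written).
#' @export
reduce_to_regions <- function(field, regions, posture = "supine",
                              path = NULL) {
  if (is.character(regions)) regions <- read_regions(regions)
  w <- region_wrenches(field, regions)
  if (!is.null(path)) {
    export_boundary_conditions(w, posture, path)
    return(invisible(w))
  }
  w
}
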