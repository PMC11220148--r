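# Regional wrench reduction: segment the force field into body regions
# (head, chest, waist, hips, legs), sum forces and moments about the mat
# origin, and solve for the application point in the sensor plane. The
# exported wrenches serve as boundary conditions for musculoskeletal
# models.

#' Region specifications
#'
#' A region is an inclusive rectangle of cell indices in the lower-left-
#' origin mat frame: begin `(x_b, y_b)` to end `(x_e, y_e)`, with x the row
#' index (1..24, mat width) and y the column index (1..48, mat length).
#' Regions within one layout may not overlap.
#'
#' @param df data.frame with columns `label`, `x_b`, `y_b`, `x_e`, `y_e`.
#' @return validated data.frame of class `region_spec`.
#' @export
region_spec <- function(df) {
  need <- c("label", "x_b", "y_b", "x_e", "y_e")
  if (!all(need %in% names(df)))
    stop_vecforce("region spec needs label, x_b, y_b, x_e, y_e", "config_error")
  bad <- df$x_b > df$x_e | df$y_b > df$y_e |
    df$x_b < 1 | df$x_e > GRID_NROW | df$y_b < 1 | df$y_e > GRID_NCOL
  if (any(bad))
    stop_vecforce(paste("region out of bounds or inverted:",
                        paste(df$label[bad], collapse = ", ")), "config_error")
  occ <- matrix(0L, GRID_NROW, GRID_NCOL)
  for (i in seq_len(nrow(df)))
    occ[df$x_b[i]:df$x_e[i], df$y_b[i]:df$y_e[i]] <-
      occ[df$x_b[i]:df$x_e[i], df$y_b[i]:df$y_e[i]] + 1L
  if (any(occ > 1L))
    stop_vecforce("regions overlap within one layout", "config_error")
  structure(df, class = c("region_spec", "data.frame"))
}

#' Read region definitions from YAML or JSON
#'
#' Expects a list of `{label, x_b, y_b, x_e, y_e}` records.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return a [region_spec()].
#' @export
read_regions <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  else {
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, as.data.frame))
  }
  region_spec(as.data.frame(obj))
}

#' Default editable region layouts
#'
#' Starting-point rectangles over the 24x48 grid for the five body regions
#' in each posture, intended to be adjusted per subject against the
#' pressure heatmap. The mat's column axis (y) runs from legs (low y) to
#' head (high y); the lateral layout narrows the rectangles toward the
#' loaded side.
#'
#' @param posture `"supine"` or `"lateral"`.
#' @return a [region_spec()].
#' @export
default_regions <- function(posture = c("supine", "lateral")) {
  posture <- match.arg(posture)
  df <- if (posture == "supine") data.frame(
    label = c("legs", "hips", "waist", "chest", "head"),
    x_b = c(5, 5, 6, 5, 9), y_b = c(1, 17, 25, 30, 40),
    x_e = c(20, 20, 19, 20, 16), y_e = c(16, 24, 29, 39, 46))
  else data.frame(
    label = c("legs", "hips", "waist", "chest", "head"),
    x_b = c(7, 8, 9, 8, 10), y_b = c(1, 17, 25, 30, 40),
    x_e = c(18, 19, 18, 19, 15), y_e = c(16, 24, 29, 39, 46))
  region_spec(df)
}

#' Moment of one cell force about the origin
#'
#' Right-handed cross product `r x F` of the cell-centre position (mm) and
#' the cell force (N), in N.mm.
#'
#' @param r position triple, mm.
#' @param F force triple, N.
#' @return moment triple, N.mm.
#' @export
cell_moment <- function(r, F) cross3(as.numeric(r), as.numeric(F))

#' Resultant force and couple of a region
#'
#' Sums the cell forces inside the region rectangle and their moments about
#' the mat origin. Cell positions are taken in the sensor plane (z = 0).
#'
#' @param field a `force_field`.
#' @param spec one row of a [region_spec()] (or a list with x_b, y_b, x_e,
#'   y_e, label).
#' @return list with `label`, `F_A` (N), `M_A` (N.mm), `n_cells`.
#' @export
region_resultant <- function(field, spec) {
  sel <- field$row >= spec$x_b & field$row <= spec$x_e &
    field$col >= spec$y_b & field$col <= spec$y_e
  if (!any(sel)) {
    warning(sprintf("region '%s' contains no loaded cells", spec$label))
    return(list(label = spec$label, F_A = c(0, 0, 0), M_A = c(0, 0, 0),
                n_cells = 0L))
  }
  f <- as.matrix(field[sel, c("fx_N", "fy_N", "fz_N")])
  r <- cbind(field$x_mm[sel], field$y_mm[sel], 0)
  M <- colSums(cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
                     r[, 3] * f[, 1] - r[, 1] * f[, 3],
                     r[, 1] * f[, 2] - r[, 2] * f[, 1]))
  list(label = spec$label, F_A = unname(colSums(f)), M_A = unname(M),
       n_cells = sum(sel))
}

#' Application point of a regional wrench
#'
#' A distributed planar load reduces to a resultant force `F_A`, a couple
#' `M_A` about the origin, and an application point. The naive route --
#' inverting the cross-product matrix of `F_A` -- fails because every such
#' matrix is singular (rank 2; see [cross_matrix()]). The physically
#' meaningful resolution for a planar contact constrains the application
#' point to the sensor plane z = 0 and splits off the component of `M_A`
#' parallel to `F_A` as a free (residual) moment that no pure-force
#' application point can produce. With `F_Az != 0`, the in-plane moment
#' equation `r_A x F_A = M_perp` then has an exact solution; it generalises
#' the centre of pressure.
#'
#' @param F_A resultant force triple, N.
#' @param M_A resultant couple triple about the origin, N.mm.
#' @param tol singularity tolerance on `|F_A|` (N).
#' @return list with `r_A` (mm, z = 0), `residual_moment` (scalar N.mm,
#'   signed along the unit `F_A`), and `perp_defect` (N.mm, the in-plane
#'   equation's leftover; 0 whenever `F_Az != 0`).
#' @export
solve_application_point <- function(F_A, M_A, tol = 1e-9) {
  F_A <- as.numeric(F_A); M_A <- as.numeric(M_A)
  nF <- vnorm(F_A)
  if (nF <= tol)
    stop_vecforce("resultant force is (near) zero: wrench has no application point",
                  "singular_wrench_error")
  f_hat <- F_A / nF
  m_par <- sum(M_A * f_hat)
  m_perp <- M_A - m_par * f_hat
  # r = (rx, ry, 0): r x F = rx*(0,-Fz,Fy) + ry*(Fz,0,-Fx); least squares
  A <- cbind(c(0, -F_A[3], F_A[2]), c(F_A[3], 0, -F_A[1]))
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  u <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% m_perp) / sv$d[pos])
  r_A <- c(u[1], if (nrow(u) > 1) u[2] else 0, 0)
  defect <- vnorm(cross3(r_A, F_A) - m_perp)
  list(r_A = r_A, residual_moment = m_par, perp_defect = defect)
}

#' Regional wrenches of a force field
#'
#' @param field a `force_field`.
#' @param specs a [region_spec()].
#' @return list of class `regional_wrench_set`; each element has `label`,
#'   `F_A` (N), `M_A` (N.mm), `r_A` (mm), `residual_moment` (N.mm),
#'   `n_cells`.
#' @export
region_wrenches <- function(field, specs) {
  out <- lapply(seq_len(nrow(specs)), function(i) {
    res <- region_resultant(field, specs[i, ])
    if (res$n_cells == 0L || vnorm(res$F_A) <= 1e-9)
      return(c(res, list(r_A = c(0, 0, 0), residual_moment = 0)))
    sol <- solve_application_point(res$F_A, res$M_A)
    c(res, list(r_A = sol$r_A, residual_moment = sol$residual_moment))
  })
  structure(out, class = "regional_wrench_set")
}

#' @export
print.regional_wrench_set <- function(x, ...) {
  for (w in x)
    cat(sprintf("%-6s F=(%.2f, %.2f, %.2f) N  r=(%.1f, %.1f) mm  Mres=%.1f N.mm  [%d cells]\n",
                w$label, w$F_A[1], w$F_A[2], w$F_A[3],
                w$r_A[1], w$r_A[2], w$residual_moment, w$n_cells))
  invisible(x)
}

#' Export regional wrenches as model boundary conditions
#'
#' Writes JSON in SI units -- forces in N, moments in N.m, positions in m
#' (the mm-native internal values are converted; the header records the
#' convention and the moment origin). Several postures can be exported into
#' one file by passing a list of wrench sets and a matching vector of
#' posture labels.
#'
#' @param wrenches a `regional_wrench_set`, or a list of them (nonempty).
#' @param posture posture label(s), one per wrench set.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_boundary_conditions <- function(wrenches, posture, path) {
  if (inherits(wrenches, "regional_wrench_set")) wrenches <- list(wrenches)
  if (!length(wrenches) || !length(wrenches[[1]]))
    stop_vecforce("no wrenches to export", "input_error")
  if (length(posture) != length(wrenches))
    stop_vecforce("one posture label per wrench set", "input_error")
  postures <- lapply(seq_along(wrenches), function(i) {
    blocks <- lapply(wrenches[[i]], function(w)
      list(label = w$label, F_A_N = w$F_A, M_A_Nm = w$M_A / 1000,
           r_A_m = w$r_A / 1000, residual_Nm = w$residual_moment / 1000,
           n_cells = w$n_cells))
    list(posture = posture[i], regions = blocks)
  })
  obj <- list(units = list(force = "N", moment = "N.m", position = "m"),
              moment_origin = "mat lower-left corner, sensor plane z=0",
              postures = postures)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read exported boundary conditions back
#'
#' @param path JSON path written by [export_boundary_conditions()].
#' @return list with `posture` and `regions` (values back in N / N.m / m).
#' @export
read_boundary_conditions <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}
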