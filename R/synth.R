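# Synthetic scenarios with analytic ground truth. An indentation surface is
# a sum of Gaussian lobes (closed-form normals), the pressure grid is built
# so the true vertical components sum exactly to body weight, and a known
# rigid transform separates the mat frame from the scan frame. Presets are
# caricatures of supine / lateral load patterns -- five lobes down the
# midline vs laterally offset lobes -- not anthropometric models.

MAT_W_MM <- GRID_NROW * CELL_PITCH_MM  # 870
MAT_L_MM <- GRID_NCOL * CELL_PITCH_MM  # 1740

lobe_presets <- function(preset) {
  if (preset == "supine") data.frame(
    label = c("head", "chest", "waist", "hips", "legs"),
    cx = c(435, 435, 435, 435, 435),
    cy = c(1530, 1230, 1000, 790, 380),
    depth = c(18, 32, 22, 42, 18),
    sx = c(70, 150, 130, 150, 120),
    sy = c(70, 120, 90, 110, 170),
    share = c(0.08, 0.32, 0.11, 0.34, 0.15))
  else data.frame(
    label = c("shoulder", "waist", "hips", "legs"),
    cx = c(390, 470, 400, 460),
    cy = c(1260, 1010, 780, 380),
    depth = c(45, 22, 50, 22),
    sx = c(90, 100, 95, 100),
    sy = c(110, 90, 100, 160),
    share = c(0.33, 0.12, 0.36, 0.19))
}

#' Generate a synthetic measurement scenario
#'
#' Builds a fully specified scenario: Gaussian indentation lobes (centres,
#' depths, widths, load shares summing to 1), body weight, a known rigid
#' mat-to-scan transform, noise levels, and the analytic ground truth
#' (per-cell true vector forces whose vertical components sum exactly to
#' the body weight). Deterministic for a given seed: lobe geometry is
#' jittered slightly around the preset and the true transform is drawn
#' within a realistic placement envelope (rotation about z up to ~6 deg,
#' in-plane shifts up to ~40 mm).
#'
#' @param preset `"supine"` or `"lateral"`.
#' @param seed integer seed.
#' @param body_weight body weight G in N.
#' @param point_sd additive Gaussian noise on scan points, mm (0 = clean).
#' @param pressure_sd additive Gaussian noise on the pressure grid, N.
#' @return object of class `synthetic_scenario` with fields `lobes`,
#'   `body_weight`, `true_transform`, `noise`, `seed`, `preset`, `truth`
#'   (list: `grid` clean [pressure_grid()] in N, `field` data.frame of true
#'   per-cell forces, `normal_fun(x, y)`).
#' @export
make_scenario <- function(preset = c("supine", "lateral"), seed = 1L,
                          body_weight = 600, point_sd = 0, pressure_sd = 0) {
  preset <- match.arg(preset)
  if (body_weight <= 0) stop_vecforce("body weight must be > 0", "parameter_error")
  set.seed(seed)
  lobes <- lobe_presets(preset)
  n <- nrow(lobes)
  lobes$cx <- lobes$cx + stats::rnorm(n, 0, 8)
  lobes$cy <- lobes$cy + stats::rnorm(n, 0, 12)
  lobes$depth <- lobes$depth * stats::runif(n, 0.9, 1.1)
  lobes$sx <- lobes$sx * stats::runif(n, 0.95, 1.05)
  lobes$sy <- lobes$sy * stats::runif(n, 0.95, 1.05)
  lobes$share <- lobes$share / sum(lobes$share)
  theta <- stats::runif(1, -6, 6) * pi / 180
  tr <- rigid_transform(rot_z(theta),
                        c(stats::runif(1, -40, 40), stats::runif(1, -40, 40),
                          stats::runif(1, -5, 5)))
  sc <- structure(list(lobes = lobes, body_weight = body_weight,
                       true_transform = tr,
                       noise = list(point_sd = point_sd,
                                    pressure_sd = pressure_sd),
                       seed = as.integer(seed), preset = preset),
                  class = "synthetic_scenario")
  sc$truth <- scenario_truth(sc)
  sc
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %s, %d lobes, G = %.0f N, seed %d\n",
              x$preset, nrow(x$lobes), x$body_weight, x$seed))
  invisible(x)
}

# depth of each lobe at (x, y): A_k * exp(-dx^2/2sx^2 - dy^2/2sy^2)
lobe_depths <- function(lobes, x, y) {
  vapply(seq_len(nrow(lobes)), function(k)
    lobes$depth[k] * exp(-(x - lobes$cx[k])^2 / (2 * lobes$sx[k]^2) -
                           (y - lobes$cy[k])^2 / (2 * lobes$sy[k]^2)),
    numeric(length(x)))
}

#' Surface height and analytic unit normal of a scenario (mat frame)
#'
#' The surface is `z(x, y) = -sum_k depth_k(x, y)`; the outward (upward)
#' unit normal is proportional to `(-dz/dx, -dz/dy, 1)`.
#'
#' @param scenario a [make_scenario()] result.
#' @param x,y coordinates in mm (vectors of equal length).
#' @return list with `z` (mm) and `normal` (n x 3 unit rows).
#' @export
surface_eval <- function(scenario, x, y) {
  lob <- scenario$lobes
  d <- matrix(lobe_depths(lob, x, y), nrow = length(x))
  z <- -rowSums(d)
  # dz/dx = sum_k d_k * (x - cx)/sx^2 (sign: z = -sum d_k)
  gx <- rowSums(matrix(vapply(seq_len(nrow(lob)), function(k)
    d[, k] * (x - lob$cx[k]) / lob$sx[k]^2, numeric(length(x))),
    nrow = length(x)))
  gy <- rowSums(matrix(vapply(seq_len(nrow(lob)), function(k)
    d[, k] * (y - lob$cy[k]) / lob$sy[k]^2, numeric(length(x))),
    nrow = length(x)))
  nrm <- cbind(-gx, -gy, 1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  list(z = z, normal = nrm)
}

# Analytic per-cell ground truth: vertical loads proportional to
# share-weighted lobe depth, then minimally redistributed so the load is in
# static equilibrium -- vertical components sum exactly to G and both net
# shear sums vanish, as they must for a resting body. The correction solves
# a 3x3 moment system for a multiplicative field 1 + a*tx + b*ty + c over
# the per-cell shear slopes tx = nx/nz, ty = ny/nz; it is tiny (the raw
# imbalance is only Gaussian-tail truncation at the mat edge).
scenario_truth <- function(scenario) {
  cc <- cell_centers(pressure_grid(matrix(0, GRID_NROW, GRID_NCOL), "N"))
  lob <- scenario$lobes
  d <- lobe_depths(lob, cc$x_mm, cc$y_mm)
  d <- matrix(d, nrow = nrow(cc))
  w <- sweep(d, 2, colSums(d), `/`)
  fz <- scenario$body_weight * as.vector(w %*% lob$share)
  se <- surface_eval(scenario, cc$x_mm, cc$y_mm)
  if (any(se$normal[, 3] < 0.1))
    stop_vecforce("scenario too steep: cell normal z-component < 0.1",
                  "geometry_error")
  tx <- se$normal[, 1] / se$normal[, 3]
  ty <- se$normal[, 2] / se$normal[, 3]
  M <- rbind(c(sum(fz), sum(fz * tx), sum(fz * ty)),
             c(sum(fz * tx), sum(fz * tx^2), sum(fz * tx * ty)),
             c(sum(fz * ty), sum(fz * tx * ty), sum(fz * ty^2)))
  coef <- solve(M, c(scenario$body_weight, 0, 0))
  fz <- fz * (coef[1] + coef[2] * tx + coef[3] * ty)
  if (any(fz < 0))
    stop_vecforce("equilibrium correction produced negative load; scenario too asymmetric",
                  "geometry_error")
  F <- fz / se$normal[, 3]
  vals <- matrix(0, GRID_NROW, GRID_NCOL)
  vals[cbind(cc$row, cc$col)] <- F
  field <- data.frame(row = cc$row, col = cc$col,
                      x_mm = cc$x_mm, y_mm = cc$y_mm, F_N = F,
                      fx_N = F * se$normal[, 1], fy_N = F * se$normal[, 2],
                      fz_N = fz, n_points = NA_integer_)
  field <- field[field$F_N > 0, ]
  list(grid = pressure_grid(vals, "N"),
       field = structure(field, class = c("force_field", "data.frame")),
       normal_fun = function(x, y) surface_eval(scenario, x, y)$normal)
}

#' Sample the scenario's scan cloud
#'
#' Samples the indentation surface on a regular lattice over the mat
#' footprint, applies the scenario's true transform into the scan frame,
#' then adds the scenario's Gaussian point noise (seeded). Normals are left
#' for the pipeline to estimate unless `with_normals = TRUE`, in which case
#' the analytic normals (rotated into the scan frame) are attached.
#'
#' @param scenario a [make_scenario()] result.
#' @param spacing lattice spacing in mm (default 9 mm, about 19k points).
#' @param with_normals attach analytic normals.
#' @return a [surface_cloud()] in frame `"scan"`.
#' @export
make_surface <- function(scenario, spacing = 9, with_normals = FALSE) {
  if (spacing <= 0) stop_vecforce("lattice spacing must be > 0", "parameter_error")
  gx <- seq(spacing / 2, MAT_W_MM - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, MAT_L_MM - spacing / 2, by = spacing)
  gg <- expand.grid(x = gx, y = gy)
  se <- surface_eval(scenario, gg$x, gg$y)
  cloud <- surface_cloud(cbind(gg$x, gg$y, se$z),
                         if (with_normals) se$normal, frame = "mat")
  cloud <- apply_transform(cloud, scenario$true_transform, frame = "scan")
  if (scenario$noise$point_sd > 0) {
    set.seed(scenario$seed + 1L)
    cloud$points <- cloud$points +
      matrix(stats::rnorm(length(cloud$points), 0, scenario$noise$point_sd),
             ncol = 3)
  }
  cloud
}

#' The scenario's measured pressure grid
#'
#' The clean ground-truth grid plus the scenario's Gaussian pressure noise
#' (seeded, truncated at zero since sensors cannot report negative load).
#'
#' @param scenario a [make_scenario()] result.
#' @return a [pressure_grid()] in N, frame `"mat"`.
#' @export
make_pressure <- function(scenario) {
  g <- scenario$truth$grid
  if (scenario$noise$pressure_sd > 0) {
    set.seed(scenario$seed + 2L)
    v <- g$values + matrix(stats::rnorm(length(g$values), 0,
                                        scenario$noise$pressure_sd),
                           GRID_NROW, GRID_NCOL)
    g <- pressure_grid(pmax(v, 0), "N")
  }
  g
}

#' Write a scenario's artifacts through the package's real writers
#'
#' Emits `pressure.csv` (single-matrix grid CSV), `scan.ply` (binary
#' little-endian PLY) and `scenario.yaml` (lobes, weight, transform, noise,
#' seed) into `dir`, so synthetic data exercises the same readers as real
#' data.
#'
#' @param scenario a [make_scenario()] result.
#' @param dir output directory (created if missing).
#' @param spacing lattice spacing forwarded to [make_surface()].
#' @return named character vector of the written paths.
#' @export
write_scenario_files <- function(scenario, dir, spacing = 9) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_csv <- file.path(dir, "pressure.csv")
  p_ply <- file.path(dir, "scan.ply")
  p_yaml <- file.path(dir, "scenario.yaml")
  write_pressure_grid(make_pressure(scenario), p_csv)
  write_ply(make_surface(scenario, spacing), p_ply)
  yaml::write_yaml(list(
    preset = scenario$preset, seed = scenario$seed,
    body_weight_N = scenario$body_weight,
    noise = scenario$noise,
    true_transform = list(
      rotation = as.vector(t(scenario$true_transform$rotation)),
      translation = scenario$true_transform$translation),
    lobes = lapply(seq_len(nrow(scenario$lobes)), function(i)
      as.list(scenario$lobes[i, ]))), p_yaml)
  c(pressure = p_csv, scan = p_ply, scenario = p_yaml)
}
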