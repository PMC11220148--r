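# Binning, per-cell mean normals and the scalar-to-vector force step.

test_that("binning follows the half-open lower-left convention", {
  g <- random_grid_N(seed = 1)
  # a point exactly on a cell's lower-left corner belongs to that cell
  pts <- rbind(c(36.25, 72.50, 0),      # corner of cell (2, 3)
               c(36.24, 72.49, -1),     # just inside cell (1, 2)
               c(-1, 10, 0),            # outside: x < 0
               c(870.01, 10, 0))        # outside: x beyond footprint
  bins <- bin_points_to_cells(surface_cloud(pts), g)
  expect_identical(bins$counts[2, 3], 1L)
  expect_identical(bins$counts[1, 2], 1L)
  expect_identical(bins$discarded, 2L)
  expect_identical(sum(bins$counts), 2L)

  expect_error(bin_points_to_cells(surface_cloud(pts, frame = "scan"), g),
               class = "frame_error")
})

test_that("uniform sampling gives near-equal per-cell counts", {
  g <- random_grid_N(seed = 2)
  xy <- expand.grid(x = seq(0.5, 869.5, by = 1), y = seq(0.5, 1739.5, by = 1))
  bins <- bin_points_to_cells(surface_cloud(cbind(xy$x, xy$y, 0)), g)
  expect_identical(bins$discarded, 0L)
  # 1 mm sampling of a 36.25 mm cell: 36 or 37 samples per axis
  expect_true(all(bins$counts %in% c(36^2, 36 * 37, 37^2)))
  expect_identical(sum(bins$counts), nrow(xy))
})

test_that("cell mean normals average then normalise, and cancelling sets raise", {
  expect_equal(cell_mean_unit_normal(rbind(c(0, 0, 1), c(0, 0, 1))),
               c(0, 0, 1))
  expect_equal(cell_mean_unit_normal(rbind(c(1, 0, 0), c(0, 0, 1))),
               c(sqrt(0.5), 0, sqrt(0.5)), tolerance = 1e-9)
  expect_error(cell_mean_unit_normal(rbind(c(1, 0, 0), c(-1, 0, 0))),
               class = "degenerate_error")
})

test_that("vector force preserves the scalar magnitude along the normal", {
  expect_equal(compute_vector_force(5.38, c(0, 0, 1)), c(0, 0, 5.38))
  expect_equal(compute_vector_force(0, c(0, 0, 1)), c(0, 0, 0))

  # decomposition of a printed worked-example vector: magnitude x direction
  v <- c(-4.91, 1.67, 6.50)
  F <- sqrt(sum(v^2))
  n_hat <- v / F
  expect_equal(compute_vector_force(F, n_hat), v, tolerance = 1e-12)

  expect_error(compute_vector_force(-1, c(0, 0, 1)), class = "validation_error")
  expect_error(compute_vector_force(1, c(0, 0, 2)), class = "validation_error")
})

test_that("force field reproduces analytic vector forces on a synthetic scene", {
  sc <- make_scenario("supine", seed = 6)
  grid <- sc$truth$grid
  mat_cloud <- apply_transform(make_surface(sc, spacing = 10),
                               invert_transform(sc$true_transform),
                               frame = "mat")
  mat_cloud <- estimate_normals(mat_cloud, k = 12)
  nf <- cell_normal_field(mat_cloud, grid)
  field <- compute_force_field(grid, nf, cloud = mat_cloud)

  # magnitude conservation per cell
  expect_equal(sqrt(field$fx_N^2 + field$fy_N^2 + field$fz_N^2), field$F_N,
               tolerance = 1e-9)
  expect_true(all(field$fz_N >= 0))
  # total magnitude dominates the vertical sum (shear mechanism)
  expect_gte(sum(field$F_N), sum(field$fz_N))

  m <- merge(field, as.data.frame(sc$truth$field), by = c("row", "col"),
             suffixes = c("", ".t"))
  err <- sqrt(mean((m$fx_N - m$fx_N.t)^2 + (m$fy_N - m$fy_N.t)^2 +
                     (m$fz_N - m$fz_N.t)^2))
  ref <- sqrt(mean(m$fx_N.t^2 + m$fy_N.t^2 + m$fz_N.t^2))
  expect_lt(err / ref, 0.02)
})

test_that("flat normals give purely vertical forces and zero grids empty fields", {
  g <- random_grid_N(seed = 3)
  flat <- estimate_normals(plane_cloud(0, 0, 0, n_side = 60, side = 869),
                           k = 8)
  flat$frame <- "mat"
  nf <- cell_normal_field(flat, g)
  field <- compute_force_field(g, nf, cloud = flat)
  expect_equal(field$fx_N, rep(0, nrow(field)), tolerance = 1e-9)
  expect_equal(field$fy_N, rep(0, nrow(field)), tolerance = 1e-9)
  expect_equal(field$fz_N, field$F_N, tolerance = 1e-9)

  zero <- pressure_grid(matrix(0, 24, 48), "N")
  zf <- compute_force_field(zero, nf, cloud = flat)
  expect_identical(nrow(zf), 0L)
})

test_that("empty-cell policies fill, verticalise or refuse", {
  v <- matrix(0, 24, 48)
  v[10, 10] <- 5   # covered by the cloud
  v[10, 40] <- 3   # far outside the cloud
  g <- pressure_grid(v, "N")
  # cloud covering only the low-y half, tilted so borrowed normals differ
  # from vertical
  xy <- expand.grid(x = seq(2, 868, by = 8), y = seq(2, 500, by = 8))
  cl <- estimate_normals(
    surface_cloud(cbind(xy$x, xy$y, 0.2 * xy$x), frame = "mat"), k = 8)
  nf <- cell_normal_field(cl, g)

  expect_error(compute_force_field(g, nf, cloud = cl, policy = "strict"),
               class = "coverage_error")

  vert <- compute_force_field(g, nf, cloud = cl, policy = "vertical")
  far <- vert[vert$col == 40, ]
  expect_equal(c(far$fx_N, far$fy_N, far$fz_N), c(0, 0, 3))
  expect_identical(attr(vert, "filled_cells"), 1L)

  near <- compute_force_field(g, nf, cloud = cl, policy = "nearest")
  far_n <- near[near$col == 40, ]
  # no scan point within two pitches of (344, 1432) -> vertical fallback
  expect_equal(far_n$fz_N, 3)

  # with a nearby cell the borrowed normal matches the local surface tilt
  v2 <- matrix(0, 24, 48); v2[10, 15] <- 4   # centre y=525.6: empty cell, but
                                             # cloud edge (y<=498) within 2 pitches
  g2 <- pressure_grid(v2, "N")
  nf2 <- cell_normal_field(cl, g2)
  n2 <- compute_force_field(g2, nf2, cloud = cl, policy = "nearest")
  expect_lt(n2$fx_N[1], 0)   # plane z = 0.2x leans normals toward -x
})

test_that("force-field CSV round trips", {
  sc <- make_scenario("lateral", seed = 8)
  field <- sc$truth$field
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_field(field, path)
  back <- read_force_field(path)
  expect_equal(back$fz_N, field$fz_N, tolerance = 1e-12)
  expect_equal(sum_components(back), sum_components(field), tolerance = 1e-10)
})
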