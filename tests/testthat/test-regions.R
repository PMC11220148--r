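# Regional wrench reduction: moments, resultants, application points and
# boundary-condition export.

random_wrench_field <- function(seed, n = 40) {
  set.seed(seed)
  rows <- sample(5:20, n, replace = TRUE)
  cols <- sample(5:44, n, replace = TRUE)
  structure(data.frame(row = rows, col = cols,
                       x_mm = (rows - 0.5) * 36.25,
                       y_mm = (cols - 0.5) * 36.25,
                       F_N = NA, fx_N = rnorm(n), fy_N = rnorm(n),
                       fz_N = runif(n, 0.5, 5), n_points = 1L),
            class = c("force_field", "data.frame"))
}

test_that("cell moments equal the determinant-expansion cross product", {
  expect_equal(cell_moment(c(100, 0, 0), c(0, 0, 10)), c(0, -1000, 0))
  expect_equal(cell_moment(c(3, 6, 9), c(1, 2, 3)), c(0, 0, 0))  # parallel

  # brute-force oracle: cofactor (determinant) expansion of the 2x2 minors
  det_cross <- function(r, F)
    c(det(rbind(r[c(2, 3)], F[c(2, 3)])),
      -det(rbind(r[c(1, 3)], F[c(1, 3)])),
      det(rbind(r[1:2], F[1:2])))
  set.seed(1)
  for (i in 1:25) {
    r <- rnorm(3); F <- rnorm(3)
    expect_equal(cell_moment(r, F), det_cross(r, F), tolerance = 1e-12)
  }
})

test_that("region resultants match a brute-force double loop", {
  field <- random_wrench_field(2)
  spec <- data.frame(label = "mid", x_b = 5, y_b = 5, x_e = 20, y_e = 44)
  res <- region_resultant(field, spec)

  F_ref <- c(0, 0, 0); M_ref <- c(0, 0, 0)
  for (i in seq_len(nrow(field))) {
    Fi <- c(field$fx_N[i], field$fy_N[i], field$fz_N[i])
    F_ref <- F_ref + Fi
    M_ref <- M_ref + cross3(c(field$x_mm[i], field$y_mm[i], 0), Fi)
  }
  expect_equal(res$F_A, F_ref, tolerance = 1e-12)
  expect_equal(res$M_A, M_ref, tolerance = 1e-12)

  # symmetric two-cell case: forces add, moments cancel
  f2 <- structure(data.frame(row = c(4, 12), col = c(8, 8),
                             x_mm = c(-100, 100), y_mm = 0, F_N = 5,
                             fx_N = 0, fy_N = 0, fz_N = 5, n_points = 1L),
                  class = c("force_field", "data.frame"))
  r2 <- region_resultant(f2, data.frame(label = "s", x_b = 1, y_b = 1,
                                        x_e = 24, y_e = 48))
  expect_equal(r2$F_A, c(0, 0, 10))
  expect_equal(r2$M_A, c(0, 0, 0))

  expect_warning(
    region_resultant(field, data.frame(label = "empty", x_b = 1, y_b = 46,
                                       x_e = 2, y_e = 48)),
    "no loaded cells")
})

test_that("region specs validate bounds and overlap", {
  expect_s3_class(default_regions("supine"), "region_spec")
  expect_s3_class(default_regions("lateral"), "region_spec")
  expect_error(region_spec(data.frame(label = "x", x_b = 5, y_b = 1,
                                      x_e = 3, y_e = 2)),
               class = "config_error")
  expect_error(region_spec(data.frame(label = c("a", "b"),
                                      x_b = c(1, 5), y_b = c(1, 3),
                                      x_e = c(10, 12), y_e = c(10, 8))),
               class = "config_error")
  # YAML and JSON round trip
  spec <- default_regions("supine")
  yp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ])),
                   yp)
  expect_equal(read_regions(yp)$label, spec$label)
})

test_that("the literal force-cross matrix is singular; plane solve resolves it", {
  set.seed(3)
  for (i in 1:20) {
    F_A <- rnorm(3)
    expect_lt(abs(det(cross_matrix(F_A))), 1e-12)
    expect_identical(qr(cross_matrix(F_A))$rank, 2L)
  }
})

test_that("application point solves the in-plane moment equation", {
  sol <- solve_application_point(c(0, 0, 10), c(500, 0, 0))
  expect_equal(sol$r_A, c(0, 50, 0), tolerance = 1e-9)
  expect_equal(sol$residual_moment, 0)
  expect_equal(cross3(sol$r_A, c(0, 0, 10)), c(500, 0, 0), tolerance = 1e-9)

  z <- solve_application_point(c(1, 2, 3), c(0, 0, 0))
  expect_equal(z$r_A, c(0, 0, 0))

  expect_error(solve_application_point(c(0, 0, 0), c(1, 0, 0)),
               class = "singular_wrench_error")
})

test_that("plane-constrained solve attains the lattice minimum and reconstructs", {
  set.seed(4)
  for (i in 1:100) {
    # wrench of a small planar field, like the pipeline produces
    n <- sample(3:8, 1)
    r <- cbind(runif(n, -200, 200), runif(n, -200, 200), 0)
    f <- cbind(rnorm(n), rnorm(n), runif(n, 0.5, 4))
    F_A <- colSums(f)
    M_A <- colSums(t(vapply(seq_len(n), function(j) cross3(r[j, ], f[j, ]),
                            numeric(3))))
    sol <- solve_application_point(F_A, M_A)

    # reconstruction: r_A x F_A + residual along unit F_A recovers M_A
    rec <- cross3(sol$r_A, F_A) + sol$residual_moment * F_A / sqrt(sum(F_A^2))
    expect_equal(rec, M_A, tolerance = 1e-6 * max(1, sqrt(sum(M_A^2))))

    # brute force on a 1 mm lattice around the solution
    gr <- expand.grid(x = sol$r_A[1] + seq(-25, 25, by = 1),
                      y = sol$r_A[2] + seq(-25, 25, by = 1))
    obj <- vapply(seq_len(nrow(gr)), function(j)
      sum((cross3(c(gr$x[j], gr$y[j], 0), F_A) - M_A)^2), numeric(1))
    best <- sqrt(min(obj))
    ours <- sqrt(sum((cross3(sol$r_A, F_A) - M_A)^2))
    expect_lte(ours, best + 1e-9)
  }
})

test_that("moments are conserved when regions tile all loaded cells", {
  sc <- make_scenario("supine", seed = 5)
  field <- sc$truth$field
  specs <- region_spec(data.frame(
    label = c("low", "mid", "high"),
    x_b = 1, y_b = c(1, 17, 33), x_e = 24, y_e = c(16, 32, 48)))
  ws <- region_wrenches(field, specs)

  whole <- region_resultant(field, data.frame(label = "all", x_b = 1,
                                              y_b = 1, x_e = 24, y_e = 48))
  F_sum <- Reduce(`+`, lapply(ws, `[[`, "F_A"))
  M_sum <- Reduce(`+`, lapply(ws, `[[`, "M_A"))
  expect_equal(F_sum, whole$F_A, tolerance = 1e-9)
  expect_equal(M_sum, whole$M_A, tolerance = 1e-6 * sqrt(sum(whole$M_A^2)))

  # each region's own wrench reconstructs its moment
  for (w in ws) {
    rec <- cross3(w$r_A, w$F_A) +
      w$residual_moment * w$F_A / sqrt(sum(w$F_A^2))
    expect_equal(rec, w$M_A, tolerance = 1e-6 * sqrt(sum(w$M_A^2)))
  }
})

test_that("boundary-condition export round trips in SI units", {
  sc <- make_scenario("lateral", seed = 6)
  ws <- region_wrenches(sc$truth$field, default_regions("lateral"))
  path <- withr::local_tempfile(fileext = ".json")
  export_boundary_conditions(ws, "lateral", path)
  back <- read_boundary_conditions(path)
  expect_identical(back$postures[[1]]$posture, "lateral")
  b1 <- back$postures[[1]]$regions[[1]]
  expect_equal(unlist(b1$F_A_N), ws[[1]]$F_A, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unlist(b1$M_A_Nm) * 1000, ws[[1]]$M_A, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unlist(b1$r_A_m) * 1000, ws[[1]]$r_A, tolerance = 1e-9,
               ignore_attr = TRUE)

  # two postures in one file
  ws2 <- region_wrenches(make_scenario("supine", seed = 6)$truth$field,
                         default_regions("supine"))
  p2 <- withr::local_tempfile(fileext = ".json")
  export_boundary_conditions(list(ws2, ws), c("supine", "lateral"), p2)
  both <- read_boundary_conditions(p2)
  expect_identical(vapply(both$postures, `[[`, "", "posture"),
                   c("supine", "lateral"))

  expect_error(export_boundary_conditions(list(), "supine", path),
               class = "input_error")
})
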