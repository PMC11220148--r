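# Force-balance sums, per-trial ratios and cohort statistics.

test_that("componentwise sums and total pressure are plain sums", {
  f <- structure(data.frame(row = 1:2, col = 1:2, x_mm = 0, y_mm = 0,
                            F_N = c(sqrt(14), sqrt(54)),
                            fx_N = c(1, -1), fy_N = c(2, -2),
                            fz_N = c(3, 7), n_points = 1L),
                 class = c("force_field", "data.frame"))
  expect_equal(unname(sum_components(f)), c(0, 0, 10))
  expect_equal(total_pressure(f), sqrt(14) + sqrt(54))

  g <- random_grid_N(seed = 1)
  expect_equal(total_pressure(g), sum(g$values))
  expect_error(total_pressure(pressure_grid(matrix(1, 24, 48), "mmHg")),
               class = "unit_error")

  empty <- structure(f[0, ], class = c("force_field", "data.frame"))
  expect_equal(unname(sum_components(empty)), c(0, 0, 0))
})

test_that("noise-free synthetic scenes balance gravity to machine precision", {
  for (preset in c("supine", "lateral")) {
    sc <- make_scenario(preset, seed = 3, body_weight = 600)
    s <- sum_components(sc$truth$field)
    expect_equal(unname(s["F_z"]), 600, tolerance = 1e-9)
    # static equilibrium: net shear vanishes by construction
    expect_lt(abs(s["F_x"]) / 600, 1e-6)
    expect_lt(abs(s["F_y"]) / 600, 1e-6)
  }
})

test_that("trial ratios reproduce the reference table rows", {
  t1 <- trial_summary(list(total_pressure = 460.66, F_x = 8.76,
                           F_y = -5.72, F_z = 349.06), G = 343.00)
  expect_equal(round_half_away(t1$vertical_pct, 2), 101.77)
  expect_equal(round_half_away(t1$total_pressure_pct, 2), 134.30)
  expect_equal(round_half_away(t1$lateral_pct, 2), 2.55)
  expect_equal(round_half_away(t1$axial_pct, 2), -1.67)

  t5 <- trial_summary(list(total_pressure = 1020.84, F_x = -5.43,
                           F_y = -49.22, F_z = 607.53), G = 735.00)
  expect_equal(round_half_away(t5$axial_pct, 2), -6.70)

  ident <- trial_summary(list(total_pressure = 500, F_x = 0, F_y = 0,
                              F_z = 500), G = 500)
  expect_equal(ident$vertical_pct, 100)

  expect_error(trial_summary(list(total_pressure = 1, F_x = 0, F_y = 0,
                                  F_z = 1), G = 0), class = "input_error")
})

test_that("every derived ratio cell of the reference table reproduces", {
  df <- reference_trials()
  trials <- summarize_trials(df)
  printed <- rbind(
    c(134.30, 101.77, 2.55, -1.67),
    c(132.24, 95.12, 0.37, 0.99),
    c(131.92, 100.36, 2.07, -0.12),
    c(124.69, 96.93, -1.31, 1.26),
    c(121.40, 97.26, 0.28, 1.71),
    c(129.95, 97.28, 0.38, -3.83),
    c(127.85, 107.26, 0.86, -2.48),
    c(141.27, 111.11, -4.13, -1.76),
    c(123.81, 96.93, -1.31, 1.26),
    c(138.89, 82.66, -0.74, -6.70))
  got <- cbind(round_half_away(trials$total_pressure_pct, 2),
               round_half_away(trials$vertical_pct, 2),
               round_half_away(trials$lateral_pct, 2),
               round_half_away(trials$axial_pct, 2))
  expect_equal(unname(got), unname(printed))
})

test_that("cohort statistics use the population SD and unrounded ratios", {
  trials <- reference_summaries()

  vert <- cohort_summary(trials, "vertical_pct")
  expect_equal(round_half_away(vert$mean, 2), 98.67)
  expect_equal(round_half_away(vert$sd, 2), 7.21)
  expect_identical(vert$sd_mode, "population")

  tp <- cohort_summary(trials, "total_pressure_pct")
  expect_equal(round_half_away(tp$mean, 2), 130.63)
  expect_equal(round_half_away(tp$sd, 2), 6.12)

  lat <- cohort_summary(trials, "lateral_pct", absolute = TRUE)
  expect_equal(round_half_away(lat$mean, 2), 1.40)
  expect_equal(round_half_away(lat$sd, 2), 1.15)

  ax <- cohort_summary(trials, "axial_pct", absolute = TRUE)
  expect_equal(round_half_away(ax$mean, 2), 2.18)
  expect_equal(round_half_away(ax$sd, 2), 1.77)

  # identical trials -> zero spread
  same <- rbind(trials[1, ], trials[1, ])
  expect_equal(cohort_summary(same, "vertical_pct")$sd, 0)
  expect_error(cohort_summary(trials[1, , drop = FALSE], "vertical_pct"),
               class = "input_error")
})

test_that("posture-stratified shear means match the reported values", {
  trials <- reference_summaries()
  sup <- trials[1:5, ]
  lat <- trials[6:10, ]
  expect_equal(round_half_away(
    cohort_summary(sup, "lateral_pct", absolute = TRUE)$mean, 2), 1.32)
  expect_equal(round_half_away(
    cohort_summary(sup, "axial_pct", absolute = TRUE)$mean, 2), 1.15)
  expect_equal(round_half_away(
    cohort_summary(lat, "lateral_pct", absolute = TRUE)$mean, 2), 1.49)
  expect_equal(round_half_away(
    cohort_summary(lat, "axial_pct", absolute = TRUE)$mean, 2), 3.21)
  expect_equal(round_half_away(max(abs(sup$lateral_pct)), 2), 2.55)
  # total pressure always dominates the vertical component
  expect_true(all(trials$total_pressure_pct >= trials$vertical_pct))
})

test_that("validation report writes the table and cohort block", {
  trials <- reference_summaries()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  rep <- validation_report(trials, csv_path = csv, json_path = js)
  expect_true(file.exists(csv) && file.exists(js))
  tab <- read.csv(csv)
  expect_equal(tab$vertical_pct[1], 101.77)
  blk <- jsonlite::fromJSON(js)
  expect_equal(blk$vertical_pct$mean, mean(trials$vertical_pct))
  expect_identical(blk$vertical_pct$sd_mode, "population")
})
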