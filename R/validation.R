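# Force-balance validation: componentwise sums of the vector force field,
# per-trial ratios against body weight, and cohort statistics. Gravity must
# be matched by the summed vertical components; the summed scalar forces
# (total pressure) exceed body weight whenever normals tilt, because each
# cell's full magnitude contributes regardless of direction.

#' Componentwise sums of a force field
#'
#' Sums fx, fy, fz over all cells. The vertical sum is the quantity
#' compared against body weight; the horizontal sums are the net lateral
#' (x, mat width) and axial (y, mat length) shear.
#'
#' @param field a `force_field`.
#' @return named numeric vector `c(F_x, F_y, F_z)` in N.
#' @export
sum_components <- function(field) {
  c(F_x = sum(field$fx_N), F_y = sum(field$fy_N), F_z = sum(field$fz_N))
}

#' Total pressure of a grid or field
#'
#' Sum of all per-cell scalar forces, in N. Always at least the vertical
#' component sum, with equality only when every loaded cell's normal is
#' exactly vertical.
#'
#' @param x a [pressure_grid()] in N or a `force_field`.
#' @return scalar N.
#' @export
total_pressure <- function(x) {
  if (inherits(x, "pressure_grid")) {
    if (x$units != "N") stop_vecforce("grid must be in N", "unit_error")
    return(sum(x$values))
  }
  if (inherits(x, "force_field")) return(sum(x$F_N))
  stop_vecforce("x must be a pressure_grid or force_field", "input_error")
}

#' Per-trial force-balance summary
#'
#' Computes the forces and their ratios to body weight, the derived columns
#' of a trial comparison table: total pressure / G, vertical / G, lateral
#' (x) / G and axial (y) / G, each as a percentage. Ratios are carried
#' unrounded; `round_half_away(x, 2)` matches reported tables.
#'
#' @param x a `force_field`, or a named list/vector with entries
#'   `total_pressure`, `F_x`, `F_y`, `F_z` (N) for pre-summed inputs.
#' @param G body weight in N (> 0).
#' @param label optional trial label.
#' @return object of class `trial_summary`: one-row data.frame with the
#'   forces (N) and ratio columns (percent, unrounded).
#' @export
trial_summary <- function(x, G, label = NA_character_) {
  if (G <= 0) stop_vecforce("body weight G must be > 0", "input_error")
  if (inherits(x, "force_field")) {
    comp <- sum_components(x)
    tp <- total_pressure(x)
  } else {
    x <- as.list(x)
    need <- c("total_pressure", "F_x", "F_y", "F_z")
    if (!all(need %in% names(x)))
      stop_vecforce("need total_pressure, F_x, F_y, F_z", "input_error")
    comp <- c(F_x = x$F_x, F_y = x$F_y, F_z = x$F_z)
    tp <- x$total_pressure
  }
  out <- data.frame(label = label, body_weight_N = G,
                    total_pressure_N = tp,
                    total_pressure_pct = 100 * tp / G,
                    F_z_N = unname(comp["F_z"]),
                    vertical_pct = 100 * unname(comp["F_z"]) / G,
                    F_x_N = unname(comp["F_x"]),
                    lateral_pct = 100 * unname(comp["F_x"]) / G,
                    F_y_N = unname(comp["F_y"]),
                    axial_pct = 100 * unname(comp["F_y"]) / G)
  structure(out, class = c("trial_summary", "data.frame"))
}

#' @export
print.trial_summary <- function(x, ...) {
  df <- as.data.frame(x)
  pct <- grep("_pct$", names(df))
  df[pct] <- lapply(df[pct], round_half_away, digits = 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Cohort mean and spread of a ratio quantity over trials
#'
#' Mean and population standard deviation (divide by n, recorded in the
#' output) of one ratio column across trials, optionally of its absolute
#' values. Statistics are computed from the unrounded per-trial ratios.
#'
#' @param trials a list of [trial_summary()] rows or a data.frame of them
#'   (e.g. `do.call(rbind, ...)`), >= 2 trials.
#' @param quantity one of `"total_pressure_pct"`, `"vertical_pct"`,
#'   `"lateral_pct"`, `"axial_pct"`.
#' @param absolute take absolute values first (shear magnitudes).
#' @return object of class `cohort_summary`: list with `mean`, `sd`, `n`,
#'   `sd_mode = "population"`, `quantity`, `absolute`.
#' @export
cohort_summary <- function(trials,
                           quantity = c("vertical_pct", "total_pressure_pct",
                                        "lateral_pct", "axial_pct"),
                           absolute = FALSE) {
  quantity <- match.arg(quantity)
  if (is.list(trials) && !is.data.frame(trials))
    trials <- do.call(rbind, lapply(trials, as.data.frame))
  if (nrow(trials) < 2)
    stop_vecforce("cohort statistics need >= 2 trials", "input_error")
  v <- trials[[quantity]]
  if (absolute) v <- abs(v)
  structure(list(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
                 n = length(v), sd_mode = "population",
                 quantity = quantity, absolute = absolute),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s%s: %.2f%% +/- %.2f%% (n=%d, %s SD)\n",
              if (x$absolute) "|" else "", x$quantity,
              round_half_away(x$mean, 2), round_half_away(x$sd, 2),
              x$n, x$sd_mode))
  invisible(x)
}

#' Bundled reference force-balance trials
#'
#' Published per-trial Newton values (body weight, total pressure, vector
#' force component sums) for five adults measured in supine and lateral
#' postures, as printed; used to exercise the ratio and cohort machinery on
#' real numbers. Columns: `position`, `subject`, `body_weight_N`,
#' `total_pressure_N`, `F_z_N`, `F_x_N`, `F_y_N`.
#'
#' @return data.frame of 10 trials.
#' @export
reference_trials <- function() {
  path <- system.file("extdata", "reference_trials.csv", package = "vecforce",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Trial summaries for a table of measured forces
#'
#' @param df data.frame with the [reference_trials()] columns.
#' @return data.frame of stacked [trial_summary()] rows.
#' @export
summarize_trials <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i)
    trial_summary(list(total_pressure = df$total_pressure_N[i],
                       F_x = df$F_x_N[i], F_y = df$F_y_N[i],
                       F_z = df$F_z_N[i]),
                  G = df$body_weight_N[i],
                  label = paste0(df$position[i], df$subject[i])))
  out <- do.call(rbind, rows)
  structure(out, class = c("trial_summary", "data.frame"))
}

#' Validation report for one or more trials
#'
#' Emits the per-trial ratio table (CSV columns mirroring the published
#' comparison table) plus, when there are >= 2 trials, a JSON cohort block
#' per ratio quantity.
#'
#' @param trials data.frame of stacked trial summaries.
#' @param csv_path,json_path optional output paths.
#' @return list with `table` (rounded to 2 decimals for report) and
#'   `cohort` (list of cohort summaries), invisibly when writing.
#' @export
validation_report <- function(trials, csv_path = NULL, json_path = NULL) {
  tab <- as.data.frame(trials)
  pct <- grep("_pct$", names(tab))
  tab[pct] <- lapply(tab[pct], round_half_away, digits = 2)
  cohort <- NULL
  if (nrow(trials) >= 2) {
    qs <- c("total_pressure_pct", "vertical_pct", "lateral_pct", "axial_pct")
    cohort <- lapply(qs, function(q)
      unclass(cohort_summary(trials, q, absolute = q %in%
                               c("lateral_pct", "axial_pct"))))
    names(cohort) <- qs
  }
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(cohort))
    jsonlite::write_json(cohort, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, cohort = cohort))
}
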