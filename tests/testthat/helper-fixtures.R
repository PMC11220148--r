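# Shared fixture builders; everything is generated in code.

# a recording of n frames at 1 Hz starting at t = 0, each frame constant
const_recording <- function(n, value = 0, units = "mmHg") {
  frames <- replicate(n, matrix(value, 24, 48), simplify = FALSE)
  pressure_recording(frames, seq(0, n - 1), units)
}

random_recording <- function(n, seed = 1, units = "mmHg") {
  set.seed(seed)
  frames <- replicate(n, matrix(runif(24 * 48, 0, 80), 24, 48),
                      simplify = FALSE)
  pressure_recording(frames, seq(0, n - 1), units)
}

random_grid_N <- function(seed = 1, scale = 5) {
  set.seed(seed)
  pressure_grid(matrix(runif(24 * 48, 0, scale), 24, 48), "N")
}

# points sampled from the plane z = a*x + b*y + c over a square
plane_cloud <- function(a = 0, b = 0, c = 0, n_side = 15, side = 100) {
  g <- expand.grid(x = seq(0, side, length.out = n_side),
                   y = seq(0, side, length.out = n_side))
  surface_cloud(cbind(g$x, g$y, a * g$x + b * g$y + c))
}

# the bundled reference trials, summarised
reference_summaries <- function() summarize_trials(reference_trials())
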