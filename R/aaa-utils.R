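#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Sensor grid constants: 24 cells across the mat width (x), 48 along its
# length (y), 36.25 mm pitch.
GRID_NROW <- 24L
GRID_NCOL <- 48L
CELL_PITCH_MM <- 36.25

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported ratio tables use the
#' conventional half-away-from-zero rule so that e.g. 101.775 prints as 101.78
#' and -1.675 as -1.68.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross product of two 3-vectors
#'
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector `a x b` (right-handed).
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Skew-symmetric cross-product matrix of a 3-vector
#'
#' Returns the matrix `[v]x` such that `[v]x %*% w == v x w`. Every such
#' matrix is singular (rank 2), which is why the application point of a
#' wrench cannot be found by a plain matrix inverse; see
#' [solve_application_point()].
#'
#' @param v numeric length-3 vector.
#' @return 3x3 numeric matrix.
#' @export
cross_matrix <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

vnorm <- function(v) sqrt(sum(v^2))

stop_vecforce <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vecforce_error")))
}
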