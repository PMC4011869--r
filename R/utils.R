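#' Geometric and angular tolerances
#'
#' Central tolerance block used by all geometric operations. Lengths are in
#' millimetres, angles in radians.
#'
#' @param geometric Length tolerance in mm (default `1e-6`).
#' @param angular Angular tolerance in radians (default `1e-9`).
#' @return A named list with elements `geometric` and `angular`.
#' @export
mg_tolerances <- function(geometric = 1e-6, angular = 1e-9) {
  stopifnot(geometric > 0, angular > 0)
  list(geometric = geometric, angular = angular)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product for n x 3 matrices
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
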