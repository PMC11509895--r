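## Internal numerical helpers.

## Wrap angles (degrees) into (-180, 180].  180 stays 180, -180 maps to 180.
wrap_angle <- function(x) 180 - ((180 - x) %% 360)

## Squared wrapped angular differences, elementwise.
sq_ang_diff <- function(a, b) wrap_angle(a - b)^2

## 3-vector cross product for row-matrices (n x 3) or plain vectors.
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a^2))

## Run code with a temporary RNG seed without disturbing the caller's stream.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

## Validate a frequency/probability vector: non-negative, sums to 1.
check_normalized <- function(f, what = "frequency vector", tol = 1e-6) {
  if (!is.numeric(f) || anyNA(f)) {
    abort(paste0(what, " must be numeric with no missing values"))
  }
  if (any(f < -1e-12)) {
    abort(paste0(what, " has negative entries"))
  }
  if (abs(sum(f) - 1) > tol) {
    abort(sprintf("%s is not normalized: sum = %.8f (expected 1)", what, sum(f)))
  }
  invisible(f)
}
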