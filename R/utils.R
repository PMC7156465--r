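# Internal geometry and error helpers. All coordinates are millimetres.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

vec3 <- function(x, what = "point") {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 3L || anyNA(x) || !all(is.finite(x)))
    stopf("%s must be a finite numeric vector of length 3", what)
  x
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stopf("cannot normalise a (near) zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' The rounding convention of printed summary tables (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Rodrigues rotation matrix about a unit axis, angle in degrees.
rotation_about <- function(axis, angle_deg) {
  u <- unit3(vec3(axis, "rotation axis"))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Uniform random rotation from a random unit quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  a <- q[1]; b <- q[2]; d <- q[3]; e <- q[4]
  matrix(c(
    1 - 2 * (d^2 + e^2), 2 * (b * d + a * e),     2 * (b * e - a * d),
    2 * (b * d - a * e), 1 - 2 * (b^2 + e^2),     2 * (d * e + a * b),
    2 * (b * e + a * d), 2 * (d * e - a * b),     1 - 2 * (b^2 + d^2)), 3, 3)
}

## Evaluate `code` under a fixed seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
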