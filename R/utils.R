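# Small vector helpers shared across the package.

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop("degenerate ", what, ": zero length", call. = FALSE)
  }
  v / n
}

## Clamp into [-1, 1] before acos so rounding never produces NaN.
clamp_unit <- function(x) pmin(1, pmax(-1, x))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Deterministic child seed, kept well inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + 10007 * (i + 1)) %% 2147483629
  as.integer(s)
}
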