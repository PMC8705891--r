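# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise versions for F x 3 matrices.
row_norms <- function(m) sqrt(rowSums(m^2))

row_unit <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-12)) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  m / n
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

other_side <- function(side) if (side == "left") "right" else "left"

check_side <- function(side) {
  assert_that(is.character(side) && length(side) == 1L &&
                side %in% c("left", "right"),
              "`side` must be \"left\" or \"right\"")
  side
}
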