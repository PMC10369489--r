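# Internal vector helpers shared across modules. All angles are degrees at the
# API surface; radians never leak out of a function.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v, what = "vector") {
  n <- .vnorm(v)
  if (n < 1e-12) {
    stop("degenerate geometry: zero-length ", what, call. = FALSE)
  }
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees, clamped against acos() domain noise.
.angle_deg <- function(u, v, what = "vector") {
  cu <- .unit(u, what)
  cv <- .unit(v, what)
  .rad2deg(acos(max(-1, min(1, sum(cu * cv)))))
}

.as_coord3 <- function(x, name) {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    stop("'", name, "' must be a finite 3-vector", call. = FALSE)
  }
  x
}

.as_coord_matrix <- function(x, name = "coordinates") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) %% 3L == 0L) {
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 3L) {
    stop("'", name, "' must be an n x 3 coordinate matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("'", name, "' contains non-finite coordinates", call. = FALSE)
  x
}
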