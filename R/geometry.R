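# Internal 3D vector helpers. All geometry is in millimetres, double precision.

vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(v) == 3)
  v
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation by `degrees` about a unit axis through the origin (Rodrigues).
rotation_about_axis <- function(axis, degrees) {
  u <- unitize(axis)
  th <- degrees * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate rows of an n x 3 matrix about a vertical (Z) axis through (cx, cy).
rotate_about_vertical <- function(pts, degrees, cx, cy) {
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  x <- pts[, 1] - cx; y <- pts[, 2] - cy
  cbind(cx + co * x - si * y, cy + si * x + co * y, pts[, 3])
}
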