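# Internal 3-vector helpers.  All geometry in the package runs through
# these; angles are returned in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dot3 <- function(a, b) sum(a * b)

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

clamp1 <- function(x) pmin(1, pmax(-1, x))

# angle (degrees, in [0, 180]) between two vectors at a common origin
vec_angle <- function(a, b) {
  deg(atan2(vnorm(cross3(a, b)), dot3(a, b)))
}

# rotation matrix about a unit axis (Rodrigues)
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# deterministic rotation matrix from three uniform variates (for seeded
# random poses in the synthetic module); uses the quaternion construction
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
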