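# Low-level 3-D geometry used by structure building and side-chain rotation.
# All coordinates are in Angstrom, all angles in degrees unless noted.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure a dihedral angle
#'
#' Returns the torsion angle defined by four points using the IUPAC sign
#' convention, wrapped to (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) / DEG)
}

#' Wrap angles to (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

angle_between <- function(a, b, c) {
  # a-b-c bond angle in degrees
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

# Natural extension reference frame: place atom D so that |C-D| = bond,
# angle(B,C,D) = ang and dihedral(A,B,C,D) = tors (degrees).
place_atom <- function(a, b, c, bond, ang, tors) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- ang * DEG
  ph <- tors * DEG
  d <- -bond * cos(th) * bc +
    bond * sin(th) * cos(ph) * m -
    bond * sin(th) * sin(ph) * n
  c + d
}

# Rotate points (matrix n x 3) about the axis through p1 -> p2 by angle deg.
rotate_about_axis <- function(pts, p1, p2, deg) {
  k <- unit(p2 - p1)
  th <- deg * DEG
  ct <- cos(th)
  st <- sin(th)
  # Rodrigues rotation, vectorized over rows
  v <- sweep(pts, 2, p1)
  kv <- v %*% k                      # n x 1, dot products
  kxv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
               k[3] * v[, 1] - k[1] * v[, 3],
               k[1] * v[, 2] - k[2] * v[, 1])
  vr <- v * ct + kxv * st + outer(as.vector(kv), k) * (1 - ct)
  sweep(vr, 2, p1, `+`)
}

# Random rigid-body transform (rotation + translation), for invariance tests.
random_rigid_transform <- function(pts, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ax <- unit(stats::rnorm(3))
  ang <- stats::runif(1, 0, 360)
  tr <- stats::rnorm(3, sd = 20)
  out <- rotate_about_axis(pts, c(0, 0, 0), ax, ang)
  sweep(out, 2, tr, `+`)
}
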