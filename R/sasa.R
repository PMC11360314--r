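# Shrake-Rupley solvent accessible surface area with a deterministic
# generalized-spiral (Fibonacci) sphere lattice, so SASA values -- and the
# node attributes derived from them -- are bit-reproducible.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Deterministic Fibonacci spiral lattice on the unit sphere
sphere_lattice <- function(n_points) {
  k <- seq_len(n_points)
  z <- 1 - (2 * k - 1) / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Express coordinates in a canonical molecular frame (centroid origin,
# principal axes with deterministic sign fix) so the quadrature rotates
# with the molecule and SASA is rigid-transform invariant.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3) return(xc)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  if (min(abs(diff(ev$values))) < 1e-9) return(xc)  # degenerate axes: keep as-is
  proj <- xc %*% ev$vectors
  # orient each axis by its extreme projection (a rigid-transform invariant)
  for (k in 1:3) {
    j <- which.max(abs(proj[, k]))
    if (proj[j, k] < 0) proj[, k] <- -proj[, k]
  }
  proj
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley quadrature over a deterministic spiral point set with
#' element van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 A. The point
#' set is laid out in the molecule's principal-axis frame, making the
#' result invariant under rigid rotation and translation.
#'
#' @param structure A `ProteinStructure` (or a flat atom table).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param n_points Quadrature points per atom (>= 12).
#' @return Numeric vector, one SASA value (A^2) per heavy atom in
#'   `atom_table()` order.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 100L) {
  if (n_points < 12) stop("n_points must be >= 12")
  tab <- if (is.data.frame(structure)) structure else atom_table(structure)
  xyz <- canonical_frame(as.matrix(tab[, c("x", "y", "z")]))
  rad <- VDW_RADII[tab$element] + probe_radius
  n <- nrow(xyz)
  pts <- sphere_lattice(n_points)
  out <- numeric(n)
  # neighbor search via squared distances (n is modest for single chains)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    Ri <- rad[i]
    nb <- which(d2[i, ] < (Ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * Ri^2
      next
    }
    P <- sweep(pts * Ri, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      free <- free & (dj2 >= rad[j]^2)
    }
    out[i] <- 4 * pi * Ri^2 * sum(free) / n_points
  }
  out
}
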