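# Small geometry helpers shared by the surface, ESP and pose modules.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section (Fibonacci) spiral. Used as the quadrature point set for
#' Shrake-Rupley surface areas and for electrostatic-potential surface scans;
#' the set is deterministic so every surface quantity is reproducible without
#' a seed.
#'
#' @param n number of points (>= 1).
#' @return an `n x 3` numeric matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    x = sin(phi) * cos(theta),
    y = sin(phi) * sin(theta),
    z = cos(phi)
  )
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 numeric, need not be normalized.
#' @param angle rotation angle in radians.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
    uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s,
    uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}

#' Random rigid transform (rotation + translation)
#'
#' Draws a uniformly random rotation axis/angle and a translation; used by the
#' invariance property tests and exported so users can stress their own
#' measurements.
#'
#' @param max_translation largest translation component (Angstrom).
#' @return list with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
random_rigid_transform <- function(max_translation = 20) {
  ax <- stats::rnorm(3)
  list(
    R = rotation_matrix(ax, stats::runif(1, 0, 2 * pi)),
    t = stats::runif(3, -max_translation, max_translation)
  )
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @keywords internal
apply_rigid <- function(xyz, transform) {
  sweep(xyz %*% t(transform$R), 2, -transform$t)
}

# Euclidean distance between two length-3 points.
dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Angle a-b-c at vertex b, degrees.
angle3 <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Position of point A such that dist(D, A) = d_da and angle(D, H, A) = ang
# (degrees), constructed in the plane spanned by the D->H direction and
# `perp`. Used to build hydrogen-bond fixtures with exact geometry.
place_by_distance_angle <- function(D, H, d_da, ang, perp = c(0, 0, 1)) {
  d_dh <- dist3(D, H)
  ang_r <- ang * pi / 180
  # law of cosines in triangle D-H-A for the H-A edge
  disc <- d_dh^2 * cos(ang_r)^2 - (d_dh^2 - d_da^2)
  if (disc < 0) {
    stop("geometrically infeasible hydrogen-bond distance/angle combination",
         call. = FALSE)
  }
  d_ha <- d_dh * cos(ang_r) + sqrt(disc)
  u_hd <- (D - H) / d_dh
  # unit vector orthogonal to u_hd in the construction plane
  w <- perp - sum(perp * u_hd) * u_hd
  if (sum(w^2) < 1e-12) stop("degenerate construction plane", call. = FALSE)
  w <- w / sqrt(sum(w^2))
  v <- cos(ang_r) * u_hd + sin(ang_r) * w
  H + d_ha * v
}
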