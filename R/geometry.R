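#' Internal 3D geometry helpers
#'
#' Small vector utilities shared by the backbone builder, the torsion
#' measurement code and the superposition routines.  All coordinates are in
#' Angstrom, all angles in degrees unless noted.
#'
#' @name geometry-helpers
#' @keywords internal
NULL

DEG <- pi / 180

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector", call. = FALSE)
  a / n
}

#' Wrap an angle to the half-open interval [-180, 180)
#' @param x angle(s) in degrees
#' @return normalized angle(s)
#' @keywords internal
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Dihedral angle of four points
#'
#' Standard signed dihedral (IUPAC convention) of the points `p1-p2-p3-p4`
#' about the `p2-p3` axis, in degrees in `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (Angstrom)
#' @return dihedral angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("degenerate geometry: colinear atoms in dihedral", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- vnorm(b2) * sum(b1 * n2)
  wrap180(atan2(y, x) / DEG)
}

#' Bond angle of three points
#' @param p1,p2,p3 numeric xyz vectors; the angle is at `p2`
#' @return angle in degrees in (0, 180)
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  v1 <- vunit(p1 - p2)
  v2 <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) / DEG
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms `a`, `b`, `c`, place a new atom `d` at
#' distance `length` from `c`, with bond angle `angle` at `c` (b-c-d) and
#' dihedral `torsion` about b-c (a-b-c-d).
#'
#' @param a,b,c xyz of the three reference atoms
#' @param length bond length c-d, Angstrom
#' @param angle bond angle b-c-d, degrees
#' @param torsion dihedral a-b-c-d, degrees
#' @return xyz of the new atom
#' @keywords internal
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * DEG
  tor <- torsion * DEG
  d2 <- c(length * cos(pi - ang),
          length * sin(pi - ang) * cos(tor),
          length * sin(pi - ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.vector(m %*% d2) + c
}

#' Random proper rotation matrix
#' @param n unused, kept for symmetry
#' @return 3x3 rotation matrix with determinant +1
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @param xyz n x 3 matrix
#' @param rotation 3 x 3 proper rotation
#' @param translation length-3 vector
#' @return transformed n x 3 matrix
#' @export
transform_coords <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}
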