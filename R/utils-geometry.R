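## Small 3-vector helpers. Coordinates are plain numeric length-3 vectors
## or n x 3 matrices; angles are degrees at every exported interface and
## radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle into (-180, 180]
#'
#' Circular reduction used for all dihedral arithmetic.
#'
#' @param x Angle(s) in degrees.
#' @return Angle(s) in degrees, wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; keep the (-180, 180] convention
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Signed circular difference a - b in (-180, 180]
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

## Fold an angle difference into the 180-degree equivalence class used by
## symmetric chi angles (chi == chi + 180): result in (-90, 90].
fold_180 <- function(x) {
  w <- x - 180 * floor((x + 90) / 180)
  w[w <= -90] <- w[w <= -90] + 180
  w
}

#' Measure a dihedral angle from four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a positive angle
#' is a clockwise rotation of the `p3`-`p4` bond relative to the
#' `p1`-`p2` bond. The value is invariant under reversal of the four
#' points.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstroms).
#' @return Angle in degrees in `(-180, 180]`.
#' @export
#' @examples
#' measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))  # +90
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    stop("degenerate dihedral: two consecutive points coincide", call. = FALSE)
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("degenerate dihedral: three consecutive points are collinear",
         call. = FALSE)
  }
  m <- vcross(n1, n2)
  x <- sum(n1 * n2)
  y <- sum(m * b2) / vnorm(b2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## NeRF-style internal-coordinate placement: position atom D given three
## reference atoms so that |D-A| = r, angle(D,A,B) = theta and
## measure_dihedral(D, A, B, C) = phi (degrees).
place_atom <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  e1 <- vunit(B - A)
  n <- vcross(B - A, C - B)
  if (vnorm(n) < 1e-9) stop("collinear reference atoms in place_atom", call. = FALSE)
  e3 <- vunit(n)
  e2 <- vcross(e3, e1)
  # local direction: at phi = 0 the new bond eclipses the B->C direction
  d <- cos(th) * e1 + sin(th) * (cos(ph) * e2 - sin(ph) * e3)
  A + r * d
}

## Rotation matrix about an arbitrary axis (Rodrigues), angle in radians.
rotation_about_axis <- function(axis, angle) {
  u <- vunit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Homogeneous 4x4 rigid transform helpers.
hom_transform <- function(R, t) {
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}

hom_inverse <- function(M) {
  R <- t(M[1:3, 1:3])
  hom_transform(R, -R %*% M[1:3, 4])
}

## Rotation about the local Z axis as a homogeneous matrix.
hom_rz <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  hom_transform(matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3), c(0, 0, 0))
}

## World -> bond frame: origin at `b`, +Z along b -> c, +X chosen from the
## direction of `a` projected off the axis (a is the dihedral reference).
bond_frame <- function(a, b, c) {
  z <- vunit(c - b)
  xraw <- (a - b) - sum((a - b) * z) * z
  if (vnorm(xraw) < 1e-9) {
    # reference collinear with the axis: any perpendicular will do
    xraw <- vcross(z, if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  }
  x <- vunit(xraw)
  y <- vcross(z, x)
  R <- rbind(x, y, z)
  hom_transform(R, -R %*% b)
}

## Apply a homogeneous transform to an n x 3 coordinate matrix.
hom_apply <- function(M, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  h <- cbind(xyz, 1) %*% t(M)
  h[, 1:3, drop = FALSE]
}

## Kahan-free deterministic sum: sort by value first so the result does not
## depend on the order the contributions were produced in.
stable_sum <- function(x) {
  if (length(x) == 0) return(0)
  sum(sort(x, method = "radix"))
}

res_key <- function(asym_id, seq_id, alt_loc = "") {
  alt <- ifelse(is.na(alt_loc) | alt_loc == ".", "", alt_loc)
  paste0(asym_id, ":", seq_id, ifelse(alt == "", "", paste0(":", alt)))
}
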