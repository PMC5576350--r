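# Elementary 3-D vector and plane operations. Everything downstream (reference
# frames, acetabular axis, angle definitions) reduces to these primitives.
#
# Conventions:
#   * points and vectors are plain numeric length-3 vectors, millimetres;
#   * a plane is an oriented object A x + B y + C z + D = 0 with (A,B,C) a
#     unit normal (class "plane");
#   * angles are in degrees throughout the public interface.

# Norm threshold below which a direction is treated as degenerate. Landmarks
# are mm-scale with ~0.1 mm precision, so 1e-8 is far below signal.
.DEGENERATE_TOL <- 1e-8

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (!is.finite(n) || n < .DEGENERATE_TOL) {
    stop_degenerate("cannot normalize a (near-)zero vector (norm = ", format(n), ")")
  }
  v / n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Degenerate-geometry error
#'
#' Signalled whenever an operation meets geometry it cannot resolve (zero
#' vectors, parallel planes, collinear point clouds, orientation ambiguity).
#' Catch with `tryCatch(..., acetorient_degenerate = ...)`.
#'
#' @param ... message parts, pasted together.
#' @return Does not return; raises a condition of class
#'   `acetorient_degenerate`.
#' @export
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("acetorient_degenerate", "error")))
}

#' Construct an oriented plane
#'
#' A plane is stored as unit-normalized coefficients `(A, B, C, D)` of
#' `Ax + By + Cz + D = 0`; `(A, B, C)` is the oriented unit normal. The sign
#' of the normal is meaningful and preserved: anteversion vs retroversion and
#' the perpendicularity audit both depend on orientation.
#'
#' @param A,B,C,D plane coefficients (any overall scale; rescaled so the
#'   normal is unit).
#' @return An object of class `plane`: numeric `c(A, B, C, D)`.
#' @examples
#' plane(0, 0, 1, 0)           # the plane z = 0
#' plane(2, 0, 0, -6)          # x = 3, normal (1, 0, 0)
#' @export
plane <- function(A, B, C, D = 0) {
  coef <- c(A, B, C, D)
  if (!all(is.finite(coef))) stop_degenerate("non-finite plane coefficients")
  n <- vec_norm(coef[1:3])
  if (n < .DEGENERATE_TOL) stop_degenerate("plane normal is (near-)zero")
  structure(coef / n, names = c("A", "B", "C", "D"), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> %.6f x + %.6f y + %.6f z + %.6f = 0\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Plane through a point with a given normal
#'
#' @param normal direction of the oriented normal (normalized internally).
#' @param point a point on the plane.
#' @return A `plane`.
#' @export
plane_from_normal_point <- function(normal, point) {
  n <- unit_vec(normal)
  plane(n[1], n[2], n[3], -sum(n * point))
}

plane_normal <- function(p) unname(p[1:3])

#' Signed distance from a point to a plane
#'
#' Positive on the side the oriented normal points to.
#'
#' @param point numeric length-3 point (mm).
#' @param plane a `plane`.
#' @return Signed distance in mm.
#' @export
plane_signed_distance <- function(point, plane) {
  sum(plane[1:3] * point) + plane[4]
}

#' Angle between two vectors
#'
#' The inverse-cosine formula `theta = acos(u . v / (|u| |v|))`, returned in
#' degrees on `[0, 180]`. The cosine argument is clamped to `[-1, 1]` so that
#' rounding near parallel/anti-parallel inputs cannot produce `NaN`.
#'
#' @param u,v non-zero numeric length-3 vectors.
#' @return Angle in degrees in `[0, 180]`.
#' @examples
#' angle_between_vectors(c(1, 0, 0), c(0, 1, 0))  # 90
#' angle_between_vectors(c(1, 1, 0), c(1, 0, 0))  # 45
#' @export
angle_between_vectors <- function(u, v) {
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < .DEGENERATE_TOL || nv < .DEGENERATE_TOL) {
    stop_degenerate("angle undefined for a zero-length vector")
  }
  cosang <- sum(u * v) / (nu * nv)
  .deg(acos(max(-1, min(1, cosang))))
}

#' Angle between two oriented planes
#'
#' The angle between the oriented unit normals, in degrees on `[0, 180]`.
#' Deliberately NOT folded to the acute range: the perpendicularity audit
#' compares plane angles against 90 degrees, which distinguishes 88 from 92
#' only under an orientation convention.
#'
#' @param p,q objects of class `plane`.
#' @return Angle in degrees in `[0, 180]`.
#' @export
angle_between_planes <- function(p, q) {
  angle_between_vectors(plane_normal(p), plane_normal(q))
}

#' Orthogonal projection of a point onto a plane
#'
#' The foot of the perpendicular: with `t = (Ax + By + Cz + D)/(A^2+B^2+C^2)`,
#' the projection is `(x - A t, y - B t, z - C t)`. For a point at the origin
#' this reduces to `t = D / (A^2+B^2+C^2)`, the origin special case of the
#' same formula.
#'
#' @param point numeric length-3 point.
#' @param plane a `plane`.
#' @return The projected point (numeric length 3), satisfying the plane
#'   equation to machine precision.
#' @export
project_point_to_plane <- function(point, plane) {
  t <- plane_signed_distance(point, plane)  # normal is unit, so A^2+B^2+C^2 = 1
  unname(point - plane[1:3] * t)
}

#' Projection of a vector onto a plane
#'
#' Implemented as the point projection applied to both endpoints of the
#' vector, equivalently `v - (v . n) n` for the unit normal `n`.
#'
#' @param v non-zero numeric length-3 vector.
#' @param plane a `plane`.
#' @return The in-plane component of `v`. Raises a degenerate-geometry error
#'   when `v` is parallel to the plane normal (zero projection).
#' @export
project_vector_to_plane <- function(v, plane) {
  if (vec_norm(v) < .DEGENERATE_TOL) stop_degenerate("cannot project a zero vector")
  p1 <- project_point_to_plane(c(0, 0, 0), plane)
  p2 <- project_point_to_plane(v, plane)
  w <- p2 - p1
  if (vec_norm(w) < .DEGENERATE_TOL) {
    stop_degenerate("vector is parallel to the plane normal; projection is zero")
  }
  w
}

#' Direction of the intersection line of two planes
#'
#' The unit vector along the cross product of the two plane normals. Used to
#' realize the body axes (longitudinal, transverse) as intersections of
#' reference planes.
#'
#' @param p,q objects of class `plane`, not (near-)parallel.
#' @return Unit numeric length-3 vector along the intersection line.
#' @export
plane_intersection_direction <- function(p, q) {
  d <- cross3(plane_normal(p), plane_normal(q))
  if (vec_norm(d) < .DEGENERATE_TOL) {
    stop_degenerate("planes are (near-)parallel; no unique intersection direction")
  }
  unit_vec(d)
}
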