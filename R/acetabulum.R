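# Acetabular axis from the rim landmarks.
#
# The acetabular face is approximated by the total-least-squares plane of the
# rim points; its normal is the acetabular axis. The fit itself leaves the
# normal's sign arbitrary; `orient_axis()` resolves it laterally (out of the
# socket) using the reference frame, since anteversion is meaningless without
# a sign convention.

#' Fit the acetabular face plane to rim landmarks
#'
#' Total-least-squares plane through the rim points. The reported center is
#' the rim centroid projected onto the fitted plane, so it lies on the
#' acetabular face and serves as the pivot for the angle constructions. The
#' arc coverage (angular span of the rim points around the center, in the
#' fitted plane) is recorded because the transverse-acetabular-ligament gap
#' leaves part of the rim unlabelled.
#'
#' @param rim n x 3 matrix of rim points (mm), n >= 3 non-collinear
#'   (labelling protocol asks n >= 30; enforce via [validate_landmarks()]).
#' @return A list: `plane` (unoriented), `center` (on the plane), `axis`
#'   (unoriented unit normal), `rms_residual` (mm), `n_points`,
#'   `arc_coverage_deg`.
#' @export
fit_acetabular_plane <- function(rim) {
  rim <- as.matrix(rim)
  fit <- fit_plane_least_squares(rim)
  center <- project_point_to_plane(fit$centroid, fit$plane)
  axis <- plane_normal(fit$plane)

  # angular arc spanned by the rim points around the center, in-plane
  e1 <- unit_vec(project_vector_to_plane(
    if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0), fit$plane))
  e2 <- cross3(axis, e1)
  rel <- sweep(rim, 2, center)
  ang <- sort(atan2(rel %*% e2, rel %*% e1))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  arc <- 2 * pi - max(gaps)

  list(plane = fit$plane, center = center, axis = axis,
       rms_residual = fit$rms_residual, n_points = fit$n_points,
       arc_coverage_deg = .deg(arc))
}

#' Orient the acetabular axis laterally
#'
#' Chooses the sign of the fitted rim-plane normal so the axis points out of
#' the socket: positive component along the frame's transverse axis towards
#' the fitted side (rightwards for a right hip, leftwards for a left hip).
#' For normal anatomy the oriented axis then also points anteriorly and
#' caudally. An axis orthogonal to the lateral direction cannot be oriented
#' and raises a degenerate-geometry error rather than being resolved
#' silently.
#'
#' @param fit result of [fit_acetabular_plane()].
#' @param frame a `reference_frame`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `acetabulum_fit`: `side`, `center`, `axis`
#'   (oriented unit), `rms_residual`, `n_points`, `arc_coverage_deg`.
#' @export
orient_axis <- function(fit, frame, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(frame, "reference_frame"))
  lateral <- if (side == "right") frame$transverse_axis else -frame$transverse_axis
  comp <- sum(fit$axis * lateral)
  if (abs(comp) < .DEGENERATE_TOL) {
    stop_degenerate("acetabular axis has no lateral component; ",
                    "orientation is ambiguous for the ", side, " hip")
  }
  axis <- if (comp > 0) fit$axis else -fit$axis
  structure(list(side = side, center = fit$center, axis = axis,
                 rms_residual = fit$rms_residual, n_points = fit$n_points,
                 arc_coverage_deg = fit$arc_coverage_deg),
            class = "acetabulum_fit")
}

#' @export
print.acetabulum_fit <- function(x, ...) {
  cat(sprintf("<acetabulum_fit> %s hip: axis (%.3f, %.3f, %.3f), rms %.3f mm, %d rim pts, arc %.0f deg\n",
              x$side, x$axis[1], x$axis[2], x$axis[3],
              x$rms_residual, x$n_points, x$arc_coverage_deg))
  invisible(x)
}
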