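# Patient-specific reference planes and body axes.
#
# The coronal plane is taken as the anterior pelvic plane (APP) through the
# bilateral ASIS and pubic tubercles (supine position assumed). The sagittal
# plane passes through the ASIS midpoint and the sacral-crest points. The
# transverse plane is constructed perpendicular to both by default (normal =
# coronal normal x sagittal normal); the alternative "literal" construction
# crosses the ASIS-to-ASIS vector with the sagittal normal and is exposed for
# comparison only, because that vector is nearly parallel to the sagittal
# normal and the cross product is close to degenerate.
#
# Orientation conventions (the angle signs depend on these):
#   * coronal normal points anteriorly (away from the sacral-crest centroid);
#   * sagittal normal points to the patient's right (right ASIS on the
#     positive side);
#   * longitudinal axis points cranially (sacral points lie caudal to the
#     ASIS level);
#   * transverse axis points from the left ASIS towards the right.

#' Build the anterior pelvic plane (coronal surrogate)
#'
#' Total-least-squares plane through the two ASIS and two pubic tubercles
#' (generically non-coplanar). The normal is oriented anteriorly: the
#' sacral-crest centroid gets a negative signed distance.
#'
#' @param set a `landmark_set`.
#' @return A list: `plane` (oriented), `rms_residual` (mm).
#' @export
build_app <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  pts <- rbind(set$asis_left, set$asis_right, set$pubic_left, set$pubic_right)
  fit <- fit_plane_least_squares(pts)
  p <- fit$plane
  if (nrow(set$sacral_crest) == 0) {
    stop("cannot orient the coronal normal without sacral-crest points")
  }
  sacral_centroid <- colMeans(set$sacral_crest)
  if (plane_signed_distance(sacral_centroid, p) > 0) {
    p <- plane(-p[1], -p[2], -p[3], -p[4])
  }
  list(plane = p, rms_residual = fit$rms_residual)
}

#' Build the sagittal plane
#'
#' Total-least-squares plane through the ASIS midpoint and all sacral-crest
#' points. The normal is oriented towards the patient's right (positive
#' signed distance at the right ASIS).
#'
#' @param set a `landmark_set`.
#' @return A list: `plane` (oriented), `rms_residual` (mm).
#' @export
build_sagittal <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  if (nrow(set$sacral_crest) < 3) {
    stop("sagittal plane needs >= 3 sacral-crest points, got ",
         nrow(set$sacral_crest))
  }
  mid <- (set$asis_left + set$asis_right) / 2
  fit <- fit_plane_least_squares(rbind(mid, set$sacral_crest))
  p <- fit$plane
  if (plane_signed_distance(set$asis_right, p) < 0) {
    p <- plane(-p[1], -p[2], -p[3], -p[4])
  }
  list(plane = p, rms_residual = fit$rms_residual)
}

#' Build the transverse plane
#'
#' Default (`mode = "orthogonal"`): the transverse normal is the cross
#' product of the coronal and sagittal normals, making the transverse plane
#' exactly perpendicular to the sagittal plane and perpendicular to the
#' coronal plane to machine precision. `mode = "literal"` instead crosses the
#' left-to-right ASIS vector with the sagittal normal; those directions are
#' nearly parallel, so this mode raises a degenerate-geometry error whenever
#' the cross product is too small to normalize reliably — it exists to make
#' the difference between the two constructions inspectable.
#'
#' @param coronal,sagittal oriented `plane`s.
#' @param origin point the transverse plane passes through (the ASIS
#'   midpoint; every downstream angle uses only the normal, so this choice is
#'   inert but fixed).
#' @param asis_vector left-ASIS to right-ASIS vector, required for
#'   `mode = "literal"`.
#' @param mode `"orthogonal"` (default) or `"literal"`.
#' @return A `plane` (orientation resolved by [build_frame()]).
#' @export
build_transverse <- function(coronal, sagittal, origin,
                             asis_vector = NULL,
                             mode = c("orthogonal", "literal")) {
  mode <- match.arg(mode)
  if (mode == "orthogonal") {
    n <- cross3(plane_normal(coronal), plane_normal(sagittal))
    if (vec_norm(n) < .DEGENERATE_TOL) {
      stop_degenerate("coronal and sagittal planes are (near-)parallel")
    }
  } else {
    if (is.null(asis_vector)) stop("literal mode needs the ASIS vector")
    n <- cross3(asis_vector, plane_normal(sagittal))
    if (vec_norm(n) < .DEGENERATE_TOL * max(vec_norm(asis_vector), 1)) {
      stop_degenerate("ASIS vector is (near-)parallel to the sagittal normal; ",
                      "the literal transverse construction is degenerate")
    }
  }
  plane_from_normal_point(n, origin)
}

#' Build the full patient-specific reference frame
#'
#' Composes the three plane builders and derives the body axes:
#' the longitudinal (cranio-caudal) axis is the intersection direction of the
#' coronal and sagittal planes, oriented cranially (sacral points caudal to
#' the ASIS level); the transverse (left-right) axis is the intersection of
#' the coronal and transverse planes, oriented towards the right ASIS. The
#' origin is the ASIS midpoint.
#'
#' @param set a `landmark_set`.
#' @param transverse_mode passed to [build_transverse()].
#' @return An object of class `reference_frame`: list with `coronal`,
#'   `sagittal`, `transverse` (planes), `longitudinal_axis`,
#'   `transverse_axis` (unit vectors), `origin`, and the two plane-fit rms
#'   residuals.
#' @export
build_frame <- function(set, transverse_mode = c("orthogonal", "literal")) {
  transverse_mode <- match.arg(transverse_mode)
  stopifnot(inherits(set, "landmark_set"))
  origin <- (set$asis_left + set$asis_right) / 2
  app <- build_app(set)
  sag <- build_sagittal(set)

  long_axis <- plane_intersection_direction(app$plane, sag$plane)
  sacral_centroid <- colMeans(set$sacral_crest)
  # cranial orientation: sacral crest sits caudal (and posterior) to the ASIS
  if (sum(long_axis * (sacral_centroid - origin)) > 0) long_axis <- -long_axis

  trans <- build_transverse(app$plane, sag$plane, origin,
                            asis_vector = set$asis_right - set$asis_left,
                            mode = transverse_mode)
  # orient the transverse normal cranially, matching the longitudinal axis
  if (sum(plane_normal(trans) * long_axis) < 0) {
    trans <- plane(-trans[1], -trans[2], -trans[3], -trans[4])
  }

  trans_axis <- plane_intersection_direction(app$plane, trans)
  if (sum(trans_axis * (set$asis_right - set$asis_left)) < 0) {
    trans_axis <- -trans_axis
  }

  structure(list(coronal = app$plane,
                 sagittal = sag$plane,
                 transverse = trans,
                 longitudinal_axis = long_axis,
                 transverse_axis = trans_axis,
                 origin = unname(origin),
                 app_rms = app$rms_residual,
                 sagittal_rms = sag$rms_residual),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  rep <- perpendicularity_report(x)
  cat(sprintf(paste0("<reference_frame> origin (%.1f, %.1f, %.1f) mm; ",
                     "plane angles cor-sag %.2f, cor-trans %.2f, sag-trans %.2f deg\n"),
              x$origin[1], x$origin[2], x$origin[3],
              rep$angle_coronal_sagittal, rep$angle_coronal_transverse,
              rep$angle_sagittal_transverse))
  invisible(x)
}

#' Reference-plane perpendicularity audit
#'
#' The three pairwise angles between the oriented plane normals, in degrees.
#' The sagittal-transverse entry is 90 degrees by construction (the
#' transverse normal is a cross product involving the sagittal normal); the
#' other two measure how far the landmark-derived planes deviate from
#' mutually perpendicular.
#'
#' @param frame a `reference_frame`.
#' @return A list with `angle_coronal_sagittal`, `angle_coronal_transverse`,
#'   `angle_sagittal_transverse` (degrees).
#' @export
perpendicularity_report <- function(frame) {
  stopifnot(inherits(frame, "reference_frame"))
  list(angle_coronal_sagittal = angle_between_planes(frame$coronal, frame$sagittal),
       angle_coronal_transverse = angle_between_planes(frame$coronal, frame$transverse),
       angle_sagittal_transverse = angle_between_planes(frame$sagittal, frame$transverse))
}
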