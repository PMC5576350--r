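# The six orientation angles under Murray's taxonomy, measured strictly by
# definition from an oriented acetabular axis and a patient-specific
# reference frame:
#
#   anatomical inclination  AI: axis vs the longitudinal axis;
#   anatomical anteversion  AA: axis projected onto the transverse plane vs
#                               the transverse (left-right) axis;
#   operative inclination   OI: axis vs the sagittal plane (line-plane);
#   operative anteversion   OA: axis projected onto the sagittal plane vs the
#                               longitudinal axis;
#   radiographic inclination RI: axis projected onto the coronal plane vs the
#                               longitudinal axis;
#   radiographic anteversion RA: axis vs the coronal plane (line-plane).
#
# Reporting conventions (fixed, documented):
#   * An infero-laterally pointing axis makes the raw axis-vs-longitudinal
#     angle obtuse (~140 for a 40-degree cup). Inclinations are therefore
#     reported folded, min(theta, 180 - theta), so canonical anatomy lands in
#     the clinical 30-60 range; the raw oriented angle is kept in a
#     diagnostic field (AI_raw, RI_raw).
#   * Anteversions are signed: positive = anterior (anteversion), negative =
#     posterior (retroversion), never clamped.
#   * A projection within 1e-8 of degenerate (axis along a plane normal)
#     yields NA with a degeneracy flag, never a silent 0.

.fold <- function(theta) pmin(theta, 180 - theta)

.anterior_sign <- function(component) if (component < 0) -1 else 1

#' Anatomical inclination and anteversion
#'
#' @param axis oriented unit acetabular axis (from [orient_axis()]).
#' @param frame a `reference_frame`.
#' @param side `"left"` or `"right"` (fixes the lateral direction).
#' @param fold report inclination folded to the acute range (default TRUE).
#' @return List with `AI`, `AA` (degrees), `AI_raw`, and `AA_degenerate`.
#' @export
anatomical_angles <- function(axis, frame, side = c("left", "right"),
                              fold = TRUE) {
  side <- match.arg(side)
  AI_raw <- angle_between_vectors(axis, frame$longitudinal_axis)
  AI <- if (fold) .fold(AI_raw) else AI_raw
  lateral <- if (side == "right") frame$transverse_axis else -frame$transverse_axis
  anterior <- plane_normal(frame$coronal)
  res <- tryCatch({
    proj <- project_vector_to_plane(axis, frame$transverse)
    theta <- angle_between_vectors(proj, lateral)
    list(AA = .anterior_sign(sum(proj * anterior)) * theta, degen = FALSE)
  }, acetorient_degenerate = function(e) list(AA = NA_real_, degen = TRUE))
  list(AI = AI, AA = res$AA, AI_raw = AI_raw, AA_degenerate = res$degen)
}

#' Operative inclination and anteversion
#'
#' OI is the line-plane angle between the axis and the sagittal plane,
#' signed positive laterally; OA is the angle between the axis projected
#' onto the sagittal plane and the longitudinal axis, folded and signed
#' positive anteriorly.
#'
#' @inheritParams anatomical_angles
#' @return List with `OI`, `OA` (degrees) and `OA_degenerate`.
#' @export
operative_angles <- function(axis, frame, side = c("left", "right")) {
  side <- match.arg(side)
  # the lateral reference for OI is the sagittal normal (the plane in the
  # definition), side-adjusted so OI is positive for a laterally open cup
  lateral <- if (side == "right") plane_normal(frame$sagittal) else -plane_normal(frame$sagittal)
  anterior <- plane_normal(frame$coronal)
  OI <- 90 - angle_between_vectors(axis, lateral)
  res <- tryCatch({
    proj <- project_vector_to_plane(axis, frame$sagittal)
    theta <- angle_between_vectors(proj, frame$longitudinal_axis)
    list(OA = .anterior_sign(sum(proj * anterior)) * .fold(theta), degen = FALSE)
  }, acetorient_degenerate = function(e) list(OA = NA_real_, degen = TRUE))
  list(OI = OI, OA = res$OA, OA_degenerate = res$degen)
}

#' Radiographic inclination and anteversion
#'
#' RI is the angle between the axis projected onto the coronal plane and the
#' longitudinal axis (reported folded, raw kept in `RI_raw`); RA is the
#' line-plane angle between the axis and the coronal plane, signed positive
#' anteriorly.
#'
#' @inheritParams anatomical_angles
#' @return List with `RI`, `RA` (degrees), `RI_raw` and `RI_degenerate`.
#' @export
radiographic_angles <- function(axis, frame, side = c("left", "right"),
                                fold = TRUE) {
  side <- match.arg(side)
  anterior <- plane_normal(frame$coronal)
  RA <- 90 - angle_between_vectors(axis, anterior)
  res <- tryCatch({
    proj <- project_vector_to_plane(axis, frame$coronal)
    theta <- angle_between_vectors(proj, frame$longitudinal_axis)
    list(RI_raw = theta, degen = FALSE)
  }, acetorient_degenerate = function(e) list(RI_raw = NA_real_, degen = TRUE))
  RI <- if (fold && !res$degen) .fold(res$RI_raw) else res$RI_raw
  list(RI = RI, RA = RA, RI_raw = res$RI_raw, RI_degenerate = res$degen)
}

#' Closed-form angles from the axis components
#'
#' Independent trigonometric route to the six angles: writing the oriented
#' unit axis in frame components `(l, a, c)` along the (lateral, anterior,
#' cranial) directions, the definitions reduce to
#' `AI = acos(|c|)` (folded), `AA = sign(a) * acos(l / sqrt(l^2 + a^2))`,
#' `OI = asin(l)`, `OA = sign(a) * atan(|a| / |c|)`,
#' `RI = atan(|l| / |c|)` (folded), `RA = asin(a)`.
#' Used for synthetic ground truth and as the cross-check against the
#' projection-based pipeline.
#'
#' @param lateral,anterior,cranial components of the unit axis along the
#'   frame directions (renormalized internally).
#' @return Named list `AI, AA, OI, OA, RI, RA` in degrees.
#' @export
closed_form_angles <- function(lateral, anterior, cranial) {
  v <- c(lateral, anterior, cranial) / vec_norm(c(lateral, anterior, cranial))
  l <- v[1]; a <- v[2]; cc <- v[3]
  sa <- .anterior_sign(a)
  list(AI = .deg(acos(min(1, abs(cc)))),
       AA = sa * .deg(acos(max(-1, min(1, l / sqrt(l^2 + a^2))))),
       OI = .deg(asin(max(-1, min(1, l)))),
       OA = sa * .deg(atan2(abs(a), abs(cc))),
       RI = .deg(atan2(abs(l), abs(cc))),
       RA = .deg(asin(max(-1, min(1, a)))))
}

#' Axis implied by anatomical inclination and anteversion
#'
#' Inverse of the closed forms for the anatomical pair: the oriented unit
#' axis with components `(cos AA sin AI, sin AA sin AI, -cos AI)` along the
#' (lateral, anterior, cranial) directions. This is the infero-laterally
#' pointing axis of normal anatomy.
#'
#' @param AI,AA anatomical inclination/anteversion in degrees
#'   (`0 < AI < 90`).
#' @return Unit numeric length-3 vector `(lateral, anterior, cranial)`.
#' @export
axis_from_anatomical <- function(AI, AA) {
  c(cos(.rad(AA)) * sin(.rad(AI)),
    sin(.rad(AA)) * sin(.rad(AI)),
    -cos(.rad(AI)))
}

# ---- conversion-formula residuals -------------------------------------------

#' Conversion-formula residuals between the three measurement systems
#'
#' Evaluates, in degrees,
#' `r1 = OA - atan(sin RI * cos RA)`,
#' `r2 = AA - atan(cos OI * cos OA)`,
#' `r3 = RA - asin(tan OI * cos OA)`,
#' exactly as these conversions are printed in the clinical literature this
#' package follows; `r3` is flagged undefined when `|tan OI * cos OA| > 1`.
#' These printed formulas are not the geometrically consistent identities
#' (see `consistent = TRUE`), so the residuals are generically non-zero even
#' for exactly consistent angle sets — which is precisely the point of
#' computing them.
#'
#' With `consistent = TRUE` the geometrically exact conversions implied by
#' the axis parametrization are added for comparison:
#' `OA = atan(tan RA / cos RI)`, `AA = atan(tan OA / tan RI)`,
#' `RA = asin(sin AA * sin AI)`; their residuals vanish on exact geometry.
#'
#' @param angles named list or one-row data.frame with `AI, AA, OI, OA, RI,
#'   RA` in degrees (non-degenerate).
#' @param consistent also return the geometrically consistent residuals.
#' @return Named list `r1, r2, r3`, `r3_defined`, and (when requested)
#'   `c1, c2, c3`.
#' @export
murray_residuals <- function(angles, consistent = FALSE) {
  a <- lapply(angles[c("AI", "AA", "OI", "OA", "RI", "RA")], as.numeric)
  if (any(vapply(a, function(x) !is.finite(x), logical(1)))) {
    stop("murray_residuals needs all six angles finite and non-degenerate")
  }
  sind <- function(x) sin(.rad(x)); cosd <- function(x) cos(.rad(x))
  tand <- function(x) tan(.rad(x))
  r1 <- a$OA - .deg(atan(sind(a$RI) * cosd(a$RA)))
  r2 <- a$AA - .deg(atan(cosd(a$OI) * cosd(a$OA)))
  arg3 <- tand(a$OI) * cosd(a$OA)
  r3_defined <- is.finite(arg3) && abs(arg3) <= 1
  r3 <- if (r3_defined) a$RA - .deg(asin(arg3)) else NA_real_
  out <- list(r1 = r1, r2 = r2, r3 = r3, r3_defined = r3_defined)
  if (consistent) {
    out$c1 <- a$OA - .deg(atan(tand(a$RA) / cosd(a$RI)))
    out$c2 <- a$AA - .deg(atan(tand(a$OA) / tand(a$RI)))
    out$c3 <- a$RA - .deg(asin(max(-1, min(1, sind(a$AA) * sind(a$AI)))))
  }
  out
}

# ---- per-case measurement ---------------------------------------------------

#' Measure all six orientation angles for every labelled hip of a case
#'
#' Runs the full pipeline: build the reference frame, fit each hip's rim
#' plane, orient the axis laterally, and evaluate the three angle pairs plus
#' the conversion-formula residuals and the frame perpendicularity audit.
#' A hip whose geometry fails (degenerate rim, ambiguous orientation) is
#' reported as a flagged row rather than aborting the case.
#'
#' @param set a `landmark_set` with at least one labelled hip.
#' @param transverse_mode passed to [build_frame()].
#' @param fold report folded inclinations (default TRUE; raw values are kept
#'   in `AI_raw`/`RI_raw` either way).
#' @param strict validate the labelling protocol strictly before measuring.
#' @return A data.frame with one row per labelled hip: identifiers
#'   (`case_id`, `side`, `age`, `sex`), the six angles, raw inclinations,
#'   residuals `r1`-`r3`, rim-fit quality (`rim_rms`, `n_rim`,
#'   `arc_coverage_deg`), the three frame-audit angles, and `error`
#'   (NA on success).
#' @export
measure_all <- function(set, transverse_mode = c("orthogonal", "literal"),
                        fold = TRUE, strict = FALSE) {
  transverse_mode <- match.arg(transverse_mode)
  stopifnot(inherits(set, "landmark_set"))
  validate_landmarks(set, strict = strict)
  if (length(set$hips) == 0) stop("case ", set$case_id, " has no labelled hips")
  frame <- build_frame(set, transverse_mode = transverse_mode)
  audit <- perpendicularity_report(frame)

  rows <- lapply(names(set$hips), function(side) {
    base <- data.frame(case_id = set$case_id, side = side,
                       age = set$age, sex = set$sex,
                       AI = NA_real_, AA = NA_real_, OI = NA_real_,
                       OA = NA_real_, RI = NA_real_, RA = NA_real_,
                       AI_raw = NA_real_, RI_raw = NA_real_,
                       r1 = NA_real_, r2 = NA_real_, r3 = NA_real_,
                       rim_rms = NA_real_, n_rim = nrow(set$hips[[side]]),
                       arc_coverage_deg = NA_real_,
                       angle_coronal_sagittal = audit$angle_coronal_sagittal,
                       angle_coronal_transverse = audit$angle_coronal_transverse,
                       angle_sagittal_transverse = audit$angle_sagittal_transverse,
                       degenerate = FALSE, error = NA_character_,
                       stringsAsFactors = FALSE)
    tryCatch({
      fit <- fit_acetabular_plane(set$hips[[side]])
      ori <- orient_axis(fit, frame, side)
      an <- anatomical_angles(ori$axis, frame, side, fold = fold)
      op <- operative_angles(ori$axis, frame, side)
      ra <- radiographic_angles(ori$axis, frame, side, fold = fold)
      base$AI <- an$AI; base$AA <- an$AA
      base$OI <- op$OI; base$OA <- op$OA
      base$RI <- ra$RI; base$RA <- ra$RA
      base$AI_raw <- an$AI_raw; base$RI_raw <- ra$RI_raw
      base$degenerate <- an$AA_degenerate || op$OA_degenerate || ra$RI_degenerate
      if (!base$degenerate) {
        res <- murray_residuals(list(AI = an$AI, AA = an$AA, OI = op$OI,
                                     OA = op$OA, RI = ra$RI, RA = ra$RA))
        base$r1 <- res$r1; base$r2 <- res$r2; base$r3 <- res$r3
      }
      base$rim_rms <- ori$rms_residual
      base$arc_coverage_deg <- ori$arc_coverage_deg
      base
    }, acetorient_degenerate = function(e) {
      base$error <- conditionMessage(e)
      base$degenerate <- TRUE
      base
    })
  })
  do.call(rbind, rows)
}
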