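# Seeded synthetic-pelvis generator with known ground truth.
#
# Canonical frame convention (before any pose is applied):
#   x = left -> right, y = posterior -> anterior, z = caudal -> cranial.
# Pelvic landmarks are laid out so the canonical reference frame is exact:
# the ASIS pair and pubic tubercles lie in the plane y = 0 (the APP), the
# ASIS midpoint and sacral-crest points lie in x = 0, and the sacral points
# sit posterior and caudal to the ASIS level. Rim points are placed on a
# circle whose normal realizes the requested anatomical (AI, AA), with an
# arc left empty for the transverse acetabular ligament gap. Noise (rim
# out-of-plane offsets, isotropic landmark jitter) and a rigid-body pose are
# applied last; ground truth records the pre-noise values.

#' Specification for one synthetic pelvis
#'
#' Defaults encode the labelling protocol's geometry: 30 rim points on a
#' 25-mm rim with a 60-degree ligament gap, plausible adult pelvic
#' dimensions, exact (noise-free) landmarks, identity pose.
#'
#' @param true_AI,true_AA ground-truth anatomical inclination/anteversion in
#'   degrees (`0 < true_AI < 90`).
#' @param sides hips to label, subset of `c("left", "right")`.
#' @param rim_radius rim circle radius, mm.
#' @param n_rim rim points per hip.
#' @param rim_gap_degrees arc omitted for the transverse acetabular ligament.
#' @param rim_out_of_plane_sd sd of out-of-plane rim offsets, mm.
#' @param landmark_jitter_sd sd of isotropic jitter on every landmark, mm.
#' @param pose_rotation_deg length-3 xyz Euler angles (degrees) of the
#'   rigid-body pose applied to all landmarks (pelvic tilt / rotation).
#' @param pose_translation length-3 translation, mm.
#' @param asis_width,pelvis_depth distances controlling pelvic landmark
#'   geometry, mm (`pelvis_depth` is how far posterior the sacrum sits).
#' @param age,sex optional case metadata.
#' @param seed integer RNG seed; every stochastic draw is derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(true_AI = 40, true_AA = 15,
                           sides = c("left", "right"),
                           rim_radius = 25, n_rim = 30, rim_gap_degrees = 60,
                           rim_out_of_plane_sd = 0, landmark_jitter_sd = 0,
                           pose_rotation_deg = c(0, 0, 0),
                           pose_translation = c(0, 0, 0),
                           asis_width = 240, pelvis_depth = 90,
                           age = NA_real_, sex = NA_character_,
                           seed = 1L) {
  stopifnot(n_rim >= 3, rim_radius > 0,
            rim_gap_degrees >= 0, rim_gap_degrees < 360,
            rim_out_of_plane_sd >= 0, landmark_jitter_sd >= 0,
            true_AI > 0, true_AI < 90,
            all(sides %in% c("left", "right")), length(sides) >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# rotation matrix from xyz Euler angles in degrees (applied as Rz Ry Rx)
rotation_matrix <- function(angles_deg) {
  a <- .rad(angles_deg)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to every landmark of a set
#'
#' @param set a `landmark_set`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(set, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(set, "landmark_set"))
  tp <- function(p) as.numeric(rotation %*% p + translation)
  tm <- function(m) {
    if (nrow(m) == 0) return(m)
    t(apply(m, 1, tp))
  }
  set$asis_left <- tp(set$asis_left)
  set$asis_right <- tp(set$asis_right)
  set$pubic_left <- tp(set$pubic_left)
  set$pubic_right <- tp(set$pubic_right)
  set$sacral_crest <- tm(set$sacral_crest)
  set$hips <- lapply(set$hips, tm)
  set
}

#' Generate one synthetic pelvis with known ground truth
#'
#' Deterministic given the spec's seed. Ground truth records the exact
#' (pre-noise, pre-pose) acetabular axes and all six angles implied by
#' `(true_AI, true_AA)` through the closed-form parametrization, in the
#' canonical frame.
#'
#' @param spec a [synthetic_spec()].
#' @param case_id case identifier.
#' @return A list with `landmarks` (a `landmark_set`) and `truth` (list:
#'   `angles` = the six true angles in degrees, `axes` = per-side true unit
#'   axes in the canonical frame, `planes` = the canonical reference planes,
#'   plus the generating `spec`).
#' @export
generate_pelvis <- function(spec, case_id = "synthetic-1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- .seeded_rng(spec$seed)

  hw <- spec$asis_width / 2
  asis_left <- c(-hw, 0, 0)
  asis_right <- c(hw, 0, 0)
  pubic_left <- c(-30, 0, -90)
  pubic_right <- c(30, 0, -90)
  sacral <- rbind(c(0, -spec$pelvis_depth, -10),
                  c(0, -spec$pelvis_depth - 6, -35),
                  c(0, -spec$pelvis_depth + 2, -55))

  # per-side true axis in canonical (x right, y anterior, z cranial) coords
  comp <- axis_from_anatomical(spec$true_AI, spec$true_AA)
  axes <- list(right = c(comp[1], comp[2], comp[3]),
               left = c(-comp[1], comp[2], comp[3]))
  centers <- list(right = c(0.35 * spec$asis_width, -15, -75),
                  left = c(-0.35 * spec$asis_width, -15, -75))

  hips <- list()
  for (side in spec$sides) {
    ax <- axes[[side]]
    # in-plane basis perpendicular to the axis
    e1 <- unit_vec(cross3(ax, c(0, 0, 1)))
    e2 <- cross3(ax, e1)
    gap <- .rad(spec$rim_gap_degrees)
    phi <- seq(gap / 2, 2 * pi - gap / 2, length.out = spec$n_rim)
    rim <- t(vapply(phi, function(p) {
      centers[[side]] + spec$rim_radius * (cos(p) * e1 + sin(p) * e2)
    }, numeric(3)))
    if (spec$rim_out_of_plane_sd > 0) {
      off <- rng$rnorm(spec$n_rim, 0, spec$rim_out_of_plane_sd)
      rim <- rim + outer(off, ax)
    }
    hips[[side]] <- rim
  }

  set <- landmark_set(case_id = case_id,
                      asis_left = asis_left, asis_right = asis_right,
                      pubic_left = pubic_left, pubic_right = pubic_right,
                      sacral_crest = sacral, hips = hips,
                      age = spec$age, sex = spec$sex)
  if (spec$landmark_jitter_sd > 0) {
    set <- perturb_rater(set, sd_mm = spec$landmark_jitter_sd,
                         seed = rng$derive_seed())
  }
  R <- rotation_matrix(spec$pose_rotation_deg)
  set <- transform_landmarks(set, R, spec$pose_translation)

  truth <- list(
    angles = closed_form_angles(comp[1], comp[2], comp[3]),
    axes = axes[spec$sides],
    planes = list(coronal = plane(0, 1, 0, 0),
                  sagittal = plane(1, 0, 0, 0),
                  transverse = plane(0, 0, 1, 0)),
    spec = spec)
  list(landmarks = set, truth = truth)
}

#' Simulate a second rater's labelling
#'
#' Adds isotropic Gaussian jitter to every landmark (named points, sacral
#' and rim points alike); `sd_mm = 0` returns the set unchanged. Drives the
#' 2-mm two-rater agreement check.
#'
#' @param set a `landmark_set`.
#' @param sd_mm per-coordinate jitter sd, mm.
#' @param seed integer seed.
#' @return A jittered `landmark_set`.
#' @export
perturb_rater <- function(set, sd_mm, seed = 1L) {
  stopifnot(inherits(set, "landmark_set"), sd_mm >= 0)
  if (sd_mm == 0) return(set)
  rng <- .seeded_rng(seed)
  jp <- function(p) p + rng$rnorm(3, 0, sd_mm)
  jm <- function(m) {
    if (nrow(m) == 0) return(m)
    m + matrix(rng$rnorm(length(m), 0, sd_mm), nrow = nrow(m))
  }
  set$asis_left <- jp(set$asis_left)
  set$asis_right <- jp(set$asis_right)
  set$pubic_left <- jp(set$pubic_left)
  set$pubic_right <- jp(set$pubic_right)
  set$sacral_crest <- jm(set$sacral_crest)
  set$hips <- lapply(set$hips, jm)
  set
}

#' Generate a synthetic cohort with known truths
#'
#' Draws per-case true anatomical angles, demographics and poses, and builds
#' one bilateral pelvis per case (two hips mirror the same true angles, as
#' both sides share the drawn orientation). Defaults mirror the study
#' cohort's structure: 49 cases, 57% male, age-bin proportions
#' 18/8/19/4 over bins <30, [30,40), [40,50), >=50, ages spanning 18-56
#' years, and true-angle distributions centered on the cohort's anatomical
#' means (AI ~ N(37.5, 11^2) clamped to (5, 85), AA ~ N(18, 7.6^2)).
#'
#' @param n_cases number of cases (each contributes both hips).
#' @param AI_mean,AI_sd,AA_mean,AA_sd true-angle distribution parameters,
#'   degrees.
#' @param prop_male probability a case is male.
#' @param age_bin_probs probabilities of the four age bins `<30, [30,40),
#'   [40,50), >=50`.
#' @param landmark_jitter_sd,rim_out_of_plane_sd noise levels passed to each
#'   case's spec, mm.
#' @param random_pose draw a random rigid pose per case (rotations up to
#'   +/- 20 degrees per axis, translations up to +/- 50 mm).
#' @param seed integer seed for the whole cohort.
#' @return A list of per-case results as returned by [generate_pelvis()].
#' @export
generate_cohort <- function(n_cases = 49,
                            AI_mean = 37.5, AI_sd = 11,
                            AA_mean = 18, AA_sd = 7.6,
                            prop_male = 28 / 49,
                            age_bin_probs = c(18, 8, 19, 4) / 49,
                            landmark_jitter_sd = 0,
                            rim_out_of_plane_sd = 0,
                            random_pose = TRUE,
                            seed = 1L) {
  stopifnot(n_cases >= 1, length(age_bin_probs) == 4)
  rng <- .seeded_rng(seed)
  age_bins <- list(c(18, 30), c(30, 40), c(40, 50), c(50, 57))
  lapply(seq_len(n_cases), function(i) {
    AI <- min(85, max(5, rng$rnorm(1, AI_mean, AI_sd)))
    AA <- rng$rnorm(1, AA_mean, AA_sd)
    bin <- age_bins[[rng$sample_int(4, prob = age_bin_probs)]]
    age <- floor(rng$runif(1, bin[1], bin[2]))
    sex <- if (rng$runif(1) < prop_male) "M" else "F"
    rot <- if (random_pose) rng$runif(3, -20, 20) else c(0, 0, 0)
    trans <- if (random_pose) rng$runif(3, -50, 50) else c(0, 0, 0)
    spec <- synthetic_spec(true_AI = AI, true_AA = AA,
                           landmark_jitter_sd = landmark_jitter_sd,
                           rim_out_of_plane_sd = rim_out_of_plane_sd,
                           pose_rotation_deg = rot, pose_translation = trans,
                           age = age, sex = sex,
                           seed = rng$derive_seed())
    generate_pelvis(spec, case_id = sprintf("case-%03d", i))
  })
}

# Self-contained RNG stream: isolates the generator from the caller's
# .Random.seed so generation is reproducible regardless of surrounding code.
.seeded_rng <- function(seed) {
  env <- new.env()
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    env$state <- state
  })
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       sample_int = with_state(function(n, prob = NULL) sample.int(n, 1, prob = prob)),
       derive_seed = with_state(function() sample.int(.Machine$integer.max - 1, 1)))
}
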