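# Landmark data model and I/O.
#
# A landmark set is all labelled bony points for one case, in millimetres in
# one shared (arbitrary, right-handed) scanner frame:
#   * bilateral anterior superior iliac spines (ASIS),
#   * bilateral pubic tubercles,
#   * >= 3 sacral-crest points,
#   * per labelled hip, >= 30 acetabular-rim points (the transverse
#     acetabular ligament gap is simply an arc with no points).

.as_point <- function(x, what) {
  v <- as.numeric(x)
  if (length(v) != 3 || !all(is.finite(v))) {
    stop("malformed coordinates for ", what, ": expected 3 finite numbers")
  }
  v
}

.as_point_matrix <- function(x, what) {
  if (is.null(x) || length(x) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  m <- as.matrix(x)
  if (ncol(m) != 3 || !all(is.finite(m))) {
    stop("malformed coordinates for ", what, ": expected an n x 3 numeric matrix")
  }
  unname(m)
}

#' Construct a landmark set
#'
#' @param case_id case identifier (character).
#' @param asis_left,asis_right left/right anterior superior iliac spine,
#'   numeric xyz in mm.
#' @param pubic_left,pubic_right left/right pubic tubercle, xyz in mm.
#' @param sacral_crest matrix (>= 3 x 3) of sacral-crest points.
#' @param hips named list with elements `"left"` and/or `"right"`, each an
#'   n x 3 matrix of acetabular-rim points (protocol asks >= 30 per hip).
#' @param age optional age in years.
#' @param sex optional `"M"`/`"F"`.
#' @param validate validate the protocol rules on construction (non-strict:
#'   violations become warnings only if `warn`).
#' @param warn emit warnings for protocol violations at construction.
#' @return An object of class `landmark_set`.
#' @seealso [validate_landmarks()], [read_landmarks()]
#' @export
landmark_set <- function(case_id, asis_left, asis_right, pubic_left,
                         pubic_right, sacral_crest, hips = list(),
                         age = NA_real_, sex = NA_character_,
                         validate = TRUE, warn = FALSE) {
  stopifnot(is.character(case_id), length(case_id) == 1)
  hips <- hips[!vapply(hips, is.null, logical(1))]
  if (length(hips) && !all(names(hips) %in% c("left", "right"))) {
    stop("hip sides must be named 'left' and/or 'right'")
  }
  set <- structure(list(
    case_id = case_id,
    asis_left = .as_point(asis_left, "asis_left"),
    asis_right = .as_point(asis_right, "asis_right"),
    pubic_left = .as_point(pubic_left, "pubic_left"),
    pubic_right = .as_point(pubic_right, "pubic_right"),
    sacral_crest = .as_point_matrix(sacral_crest, "sacral_crest"),
    hips = lapply(hips, .as_point_matrix, what = "rim"),
    age = as.numeric(age),
    sex = as.character(sex)
  ), class = "landmark_set")
  if (validate && warn) {
    rep <- validate_landmarks(set)
    for (m in rep$message[rep$severity == "violation"]) warning(m, call. = FALSE)
  }
  set
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> case %s: %d sacral points, hips: %s\n",
              x$case_id, nrow(x$sacral_crest),
              if (length(x$hips)) {
                paste(sprintf("%s (%d rim pts)", names(x$hips),
                              vapply(x$hips, nrow, integer(1))),
                      collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Validate a landmark set against the labelling protocol
#'
#' Checks the labelling rules: at least 30 rim points per labelled hip, at
#' least 3 sacral-crest points, ASIS pair separated by more than 1 mm,
#' near-coincident pelvic landmarks, and grossly non-uniform rim spacing
#' (adjacent rim points are supposed to be roughly evenly spaced; a high
#' coefficient of variation of nearest-neighbour spacing trips a warning-level
#' finding).
#'
#' @param set a `landmark_set`.
#' @param strict if `TRUE`, any violation raises an error.
#' @param min_rim_points required rim count per hip (default 30).
#' @param min_sacral_points required sacral count (default 3).
#' @return A data.frame with columns `rule`, `side`, `severity`
#'   (`"violation"` or `"warning"`), `message`; zero rows when fully
#'   compliant.
#' @export
validate_landmarks <- function(set, strict = FALSE, min_rim_points = 30,
                               min_sacral_points = 3) {
  stopifnot(inherits(set, "landmark_set"))
  out <- list()
  add <- function(rule, side, severity, message) {
    out[[length(out) + 1]] <<- data.frame(rule = rule, side = side,
                                          severity = severity,
                                          message = message,
                                          stringsAsFactors = FALSE)
  }

  if (nrow(set$sacral_crest) < min_sacral_points) {
    add("sacral_count", NA_character_, "violation",
        sprintf("case %s: %d sacral-crest points, protocol requires >= %d",
                set$case_id, nrow(set$sacral_crest), min_sacral_points))
  }
  if (vec_norm(set$asis_left - set$asis_right) <= 1) {
    add("asis_separation", NA_character_, "violation",
        sprintf("case %s: ASIS pair separated by <= 1 mm", set$case_id))
  }
  if (vec_norm(set$pubic_left - set$pubic_right) <= 1) {
    add("pubic_separation", NA_character_, "violation",
        sprintf("case %s: pubic tubercles separated by <= 1 mm", set$case_id))
  }
  for (side in names(set$hips)) {
    rim <- set$hips[[side]]
    if (nrow(rim) < min_rim_points) {
      add("rim_count", side, "violation",
          sprintf("case %s %s hip: %d rim points, protocol requires >= %d",
                  set$case_id, side, nrow(rim), min_rim_points))
    }
    if (nrow(rim) >= 4) {
      # nearest-neighbour spacing uniformity ("coincident manner" rule)
      d <- as.matrix(stats::dist(rim))
      diag(d) <- Inf
      nn <- apply(d, 1, min)
      if (any(nn < .DEGENERATE_TOL)) {
        add("rim_duplicates", side, "warning",
            sprintf("case %s %s hip: duplicated rim points", set$case_id, side))
      }
      cv <- stats::sd(nn) / mean(nn)
      if (is.finite(cv) && cv > 0.75) {
        add("rim_spacing", side, "warning",
            sprintf("case %s %s hip: grossly non-uniform rim spacing (CV %.2f)",
                    set$case_id, side, cv))
      }
    }
  }
  report <- if (length(out)) do.call(rbind, out) else {
    data.frame(rule = character(), side = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  if (strict && any(report$severity == "violation")) {
    stop("landmark validation failed:\n  ",
         paste(report$message[report$severity == "violation"], collapse = "\n  "))
  }
  report
}

# ---- file I/O ---------------------------------------------------------------

#' Read a landmark set from JSON or CSV
#'
#' Two dialects are supported. JSON: an object with `case_id`, a `landmarks`
#' object keyed by role (`asis_left`, `asis_right`, `pubic_left`,
#' `pubic_right`, `sacral_crest` as a point list), a `hips` object keyed by
#' side, and optional `age`/`sex`. CSV: long format with columns
#' `case_id, role, side, index, x_mm, y_mm, z_mm` where `role` is one of
#' `asis`, `pubic`, `sacral_crest`, `rim`. Coordinates are millimetres.
#'
#' @param path file to read.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   missing.
#' @return A validated `landmark_set`.
#' @export
read_landmarks <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") .read_landmarks_json(path) else .read_landmarks_csv(path)
}

.required_roles <- c("asis_left", "asis_right", "pubic_left", "pubic_right",
                     "sacral_crest")

.read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- obj$landmarks
  missing <- setdiff(.required_roles, names(lm))
  if (length(missing)) {
    stop("landmark file ", path, " is missing required role(s): ",
         paste(missing, collapse = ", "))
  }
  hips <- obj$hips
  if (is.null(hips)) hips <- list()
  landmark_set(case_id = as.character(obj$case_id),
               asis_left = lm$asis_left, asis_right = lm$asis_right,
               pubic_left = lm$pubic_left, pubic_right = lm$pubic_right,
               sacral_crest = lm$sacral_crest,
               hips = hips,
               age = if (is.null(obj$age)) NA_real_ else obj$age,
               sex = if (is.null(obj$sex)) NA_character_ else obj$sex)
}

.read_landmarks_csv <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1))
  # text columns read as character so a sex of "F" is not parsed as logical
  classes <- ifelse(hdr %in% c("case_id", "role", "side", "sex"),
                    "character", NA)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
  need <- c("case_id", "role", "side", "index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("landmark CSV ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  grab_one <- function(role, side) {
    r <- df[df$role == role & df$side == side, , drop = FALSE]
    if (nrow(r) == 0) stop("landmark CSV ", path, " is missing ", role, "_", side)
    if (nrow(r) > 1) stop("landmark CSV ", path, " has duplicate ", role, "_", side)
    c(r$x_mm, r$y_mm, r$z_mm)
  }
  grab_many <- function(role, side = NA) {
    r <- if (is.na(side)) df[df$role == role, , drop = FALSE]
         else df[df$role == role & df$side == side, , drop = FALSE]
    r <- r[order(r$index), , drop = FALSE]
    as.matrix(r[, c("x_mm", "y_mm", "z_mm")])
  }
  hips <- list()
  for (side in c("left", "right")) {
    rim <- grab_many("rim", side)
    if (nrow(rim)) hips[[side]] <- rim
  }
  age <- if ("age" %in% names(df)) df$age[1] else NA_real_
  sex <- if ("sex" %in% names(df)) df$sex[1] else NA_character_
  landmark_set(case_id = as.character(df$case_id[1]),
               asis_left = grab_one("asis", "left"),
               asis_right = grab_one("asis", "right"),
               pubic_left = grab_one("pubic", "left"),
               pubic_right = grab_one("pubic", "right"),
               sacral_crest = grab_many("sacral_crest"),
               hips = hips, age = age, sex = sex)
}

#' Write a landmark set to JSON or CSV
#'
#' Inverse of [read_landmarks()]; `read_landmarks(write_landmarks(x))`
#' reproduces `x` up to numeric print precision.
#'
#' @param set a `landmark_set`.
#' @param path output file.
#' @param format `"json"` or `"csv"` (inferred from the extension by default).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(set, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(set, "landmark_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(
      case_id = set$case_id,
      landmarks = list(asis_left = set$asis_left, asis_right = set$asis_right,
                       pubic_left = set$pubic_left, pubic_right = set$pubic_right,
                       sacral_crest = set$sacral_crest),
      hips = set$hips)
    if (!is.na(set$age)) obj$age <- set$age
    if (!is.na(set$sex)) obj$sex <- set$sex
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- list(
      data.frame(role = "asis", side = "left", index = 1L,
                 x_mm = set$asis_left[1], y_mm = set$asis_left[2], z_mm = set$asis_left[3]),
      data.frame(role = "asis", side = "right", index = 1L,
                 x_mm = set$asis_right[1], y_mm = set$asis_right[2], z_mm = set$asis_right[3]),
      data.frame(role = "pubic", side = "left", index = 1L,
                 x_mm = set$pubic_left[1], y_mm = set$pubic_left[2], z_mm = set$pubic_left[3]),
      data.frame(role = "pubic", side = "right", index = 1L,
                 x_mm = set$pubic_right[1], y_mm = set$pubic_right[2], z_mm = set$pubic_right[3]))
    sc <- set$sacral_crest
    if (nrow(sc)) {
      rows[[length(rows) + 1]] <- data.frame(
        role = "sacral_crest", side = NA_character_, index = seq_len(nrow(sc)),
        x_mm = sc[, 1], y_mm = sc[, 2], z_mm = sc[, 3])
    }
    for (side in names(set$hips)) {
      rim <- set$hips[[side]]
      rows[[length(rows) + 1]] <- data.frame(
        role = "rim", side = side, index = seq_len(nrow(rim)),
        x_mm = rim[, 1], y_mm = rim[, 2], z_mm = rim[, 3])
    }
    df <- do.call(rbind, rows)
    df <- cbind(case_id = set$case_id, df)
    if (!is.na(set$age)) df$age <- set$age
    if (!is.na(set$sex)) df$sex <- set$sex
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# ---- two-rater agreement ----------------------------------------------------

# symmetric max nearest-neighbour distance between two point sets (Hausdorff);
# computed from coordinate differences so identical sets give exactly zero
.set_distance <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  nn <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      min(sqrt(colSums((t(q) - p[i, ])^2)))
    }, numeric(1))
  }
  max(nn(a, b), nn(b, a))
}

#' Two-rater landmark agreement (2-mm rule)
#'
#' Compares two independent labellings of the same case. Named pelvic
#' landmarks are compared directly; sacral and rim points carry no stable
#' identity across raters and are compared by symmetric nearest-neighbour
#' (Hausdorff) distance. The labelling is accepted when every per-role
#' distance is below the tolerance (default 2 mm).
#'
#' @param a,b two `landmark_set`s for the same case with the same roles
#'   labelled.
#' @param tolerance_mm acceptance tolerance in mm (default 2).
#' @return An object of class `rater_agreement`: list with `distances`
#'   (named numeric, mm), `max_distance`, `tolerance_mm`, `pass`, and
#'   `failed_roles`.
#' @export
rater_agreement <- function(a, b, tolerance_mm = 2) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  if (!identical(sort(names(a$hips)), sort(names(b$hips)))) {
    stop("the two landmark sets label different hips: ",
         paste(names(a$hips), collapse = "/"), " vs ",
         paste(names(b$hips), collapse = "/"))
  }
  d <- c(
    asis_left = vec_norm(a$asis_left - b$asis_left),
    asis_right = vec_norm(a$asis_right - b$asis_right),
    pubic_left = vec_norm(a$pubic_left - b$pubic_left),
    pubic_right = vec_norm(a$pubic_right - b$pubic_right),
    sacral_crest = .set_distance(a$sacral_crest, b$sacral_crest))
  for (side in names(a$hips)) {
    d[paste0("rim_", side)] <- .set_distance(a$hips[[side]], b$hips[[side]])
  }
  structure(list(distances = d,
                 max_distance = max(d),
                 tolerance_mm = tolerance_mm,
                 pass = max(d) < tolerance_mm,
                 failed_roles = names(d)[d >= tolerance_mm]),
            class = "rater_agreement")
}

#' @export
print.rater_agreement <- function(x, ...) {
  cat(sprintf("<rater_agreement> max %.3f mm vs %.1f mm tolerance: %s\n",
              x$max_distance, x$tolerance_mm, if (x$pass) "PASS" else "FAIL"))
  if (!x$pass) cat("  failed roles:", paste(x$failed_roles, collapse = ", "), "\n")
  invisible(x)
}
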