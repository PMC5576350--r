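test_that("hand-parametrized axis reproduces the textbook trigonometry", {
  frame <- canonical_frame()
  # right-hip axis with anatomical truth (AI, AA) = (40, 15)
  axis <- axis_from_anatomical(40, 15)  # canonical frame: (lateral=x, ant=y, cran=z)
  an <- anatomical_angles(axis, frame, "right")
  expect_equal(an$AI, 40, tolerance = 1e-9)
  expect_equal(an$AI_raw, 140, tolerance = 1e-9)
  expect_equal(an$AA, 15, tolerance = 1e-9)
  op <- operative_angles(axis, frame, "right")
  expect_equal(op$OI, (180 / pi) * asin(cos(pi * 15 / 180) * sin(pi * 40 / 180)),
               tolerance = 1e-9)
  ra <- radiographic_angles(axis, frame, "right")
  expect_equal(ra$RA, (180 / pi) * asin(sin(pi * 15 / 180) * sin(pi * 40 / 180)),
               tolerance = 1e-9)
})

test_that("axis aligned with frame directions hits the degenerate corners", {
  frame <- canonical_frame()
  # axis = longitudinal: AI = 0, transverse projection degenerate
  an <- anatomical_angles(c(0, 0, 1), frame, "right")
  expect_equal(an$AI, 0, tolerance = 1e-12)
  expect_true(an$AA_degenerate)
  expect_true(is.na(an$AA))
  # axis = transverse axis (pure lateral): AI = 90, AA = 0, OI = 90, OA degenerate
  an2 <- anatomical_angles(c(1, 0, 0), frame, "right")
  expect_equal(an2$AI, 90, tolerance = 1e-12)
  expect_equal(an2$AA, 0, tolerance = 1e-12)
  op <- operative_angles(c(1, 0, 0), frame, "right")
  expect_equal(op$OI, 90, tolerance = 1e-12)
  expect_true(op$OA_degenerate)
  # axis in the sagittal plane: OI = 0
  op2 <- operative_angles(c(0, 0.6, -0.8), frame, "right")
  expect_equal(op2$OI, 0, tolerance = 1e-12)
  # axis = coronal normal: RA = 90, RI degenerate; axis in coronal plane: RA = 0
  ra <- radiographic_angles(c(0, 1, 0), frame, "right")
  expect_equal(ra$RA, 90, tolerance = 1e-12)
  expect_true(ra$RI_degenerate)
  ra2 <- radiographic_angles(c(0.6, 0, -0.8), frame, "right")
  expect_equal(ra2$RA, 0, tolerance = 1e-12)
})

test_that("pipeline angles equal the independent closed forms on random axes", {
  frame <- canonical_frame()
  set.seed(71)
  for (i in 1:200) {
    v <- random_unit_vector()
    v[1] <- abs(v[1])  # laterally oriented, as after orient_axis()
    if (v[1] < 1e-3 || abs(v[2]) < 1e-6 || abs(v[3]) < 1e-6) next
    oracle <- oracle_six_angles(v[1], v[2], v[3])
    an <- anatomical_angles(v, frame, "right")
    op <- operative_angles(v, frame, "right")
    ra <- radiographic_angles(v, frame, "right")
    expect_equal(an$AI, oracle$AI, tolerance = 1e-9)
    expect_equal(an$AA, oracle$AA, tolerance = 1e-9)
    expect_equal(op$OI, oracle$OI, tolerance = 1e-9)
    expect_equal(op$OA, oracle$OA, tolerance = 1e-9)
    expect_equal(ra$RI, oracle$RI, tolerance = 1e-9)
    expect_equal(ra$RA, oracle$RA, tolerance = 1e-9)
  }
})

test_that("measure_all recovers truth, is mirror-symmetric, and survives rotation", {
  g <- generate_pelvis(synthetic_spec(true_AI = 47, true_AA = 22))
  m <- measure_all(g$landmarks)
  truth <- unlist(g$truth$angles)
  for (i in 1:2) {
    expect_equal(unlist(m[i, angle_cols]), truth,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # left and right hips of a bilateral pelvis give identical magnitudes
  expect_equal(unlist(m[m$side == "left", angle_cols]),
               unlist(m[m$side == "right", angle_cols]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # a rotated-and-translated copy measures identically
  set.seed(81)
  moved <- transform_landmarks(g$landmarks, random_rotation(), rnorm(3, sd = 70))
  m2 <- measure_all(moved)
  expect_equal(as.matrix(m2[, angle_cols]), as.matrix(m[, angle_cols]),
               tolerance = 1e-9)
})

test_that("a degenerate hip is flagged without killing the case", {
  g <- generate_pelvis(synthetic_spec())
  set <- g$landmarks
  set$hips$left <- cbind(1:30, 2 * (1:30), 3 * (1:30))  # collinear rim
  m <- measure_all(set)
  expect_equal(nrow(m), 2)
  left <- m[m$side == "left", ]
  expect_true(left$degenerate)
  expect_true(is.na(left$AI))
  expect_false(m[m$side == "right", ]$degenerate)
})

test_that("printed conversion residuals evaluate exactly as written", {
  zero <- list(AI = 0, AA = 0, OI = 0, OA = 0, RI = 0, RA = 0)
  r <- murray_residuals(zero)
  expect_identical(r$r1, 0)
  expect_equal(r$r2, -45, tolerance = 1e-12)
  expect_identical(r$r3, 0)
  # tan^-1(sin 90 * cos 0) = 45, so OA = 45 gives r1 = 0
  r2 <- murray_residuals(list(AI = 10, AA = 5, OI = 10, OA = 45, RI = 90, RA = 0))
  expect_equal(r2$r1, 0, tolerance = 1e-12)
  # tan(80) > 1 puts the arcsin argument out of domain
  r3 <- murray_residuals(list(AI = 10, AA = 5, OI = 80, OA = 0, RI = 30, RA = 10))
  expect_false(r3$r3_defined)
  expect_true(is.na(r3$r3))
  expect_error(murray_residuals(list(AI = 1, AA = 2, OI = 3, OA = NA, RI = 5, RA = 6)),
               "finite")
})

test_that("printed conversions fail on exact geometry while consistent ones hold", {
  set.seed(91)
  nonzero <- 0
  for (i in 1:25) {
    a <- closed_form_angles(runif(1, 0.3, 0.9), runif(1, 0.05, 0.5),
                            -runif(1, 0.3, 0.9))
    r <- murray_residuals(a, consistent = TRUE)
    if (abs(r$r1) > 0.5) nonzero <- nonzero + 1
    # the geometrically consistent identities do hold
    expect_equal(r$c1, 0, tolerance = 1e-9)
    expect_equal(r$c2, 0, tolerance = 1e-9)
    expect_equal(r$c3, 0, tolerance = 1e-9)
  }
  expect_gt(nonzero, 15)  # the printed formulas are generically wrong
})
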