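test_that("canonical synthetic pelvis yields the canonical frame", {
  set <- generate_pelvis(synthetic_spec())$landmarks
  frame <- build_frame(set)
  # anterior = +y, right = +x, cranial = +z in the generator's convention
  expect_equal(unname(frame$coronal[1:3]), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(unname(frame$sagittal[1:3]), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(frame$longitudinal_axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(frame$transverse_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(frame$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(frame$app_rms, 0, tolerance = 1e-9)
  expect_equal(frame$sagittal_rms, 0, tolerance = 1e-9)
})

test_that("sagittal plane passes through the ASIS midpoint and sacral points", {
  mid_set <- landmark_set("t", asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
                          pubic_left = c(-30, 0, -90), pubic_right = c(30, 0, -90),
                          sacral_crest = rbind(c(0, -50, 0), c(0, -60, 10), c(0, -55, 20)))
  sag <- build_sagittal(mid_set)$plane
  expect_equal(unname(sag[1:4]), c(1, 0, 0, 0), tolerance = 1e-12)
  two <- mid_set
  two$sacral_crest <- two$sacral_crest[1:2, , drop = FALSE]
  expect_error(build_sagittal(two), "sacral")
})

test_that("APP orientation points anteriorly and degenerate ASIS errors", {
  set <- generate_pelvis(synthetic_spec())$landmarks
  app <- build_app(set)$plane
  sacral_centroid <- colMeans(set$sacral_crest)
  expect_lt(plane_signed_distance(sacral_centroid, app), 0)
  bad <- set
  bad$asis_right <- bad$asis_left
  bad$pubic_right <- bad$pubic_left
  expect_error(build_app(bad), class = "acetorient_degenerate")
})

test_that("frame axes are orthogonal and the axes lie in their planes", {
  set <- generate_pelvis(synthetic_spec(pose_rotation_deg = c(9, -4, 17)))$landmarks
  frame <- build_frame(set)
  expect_lt(abs(sum(plane_normal(frame$transverse) * plane_normal(frame$sagittal))), 1e-9)
  expect_lt(abs(sum(frame$longitudinal_axis * plane_normal(frame$coronal))), 1e-9)
  expect_lt(abs(sum(frame$longitudinal_axis * plane_normal(frame$sagittal))), 1e-9)
  for (pl in list(frame$coronal, frame$sagittal, frame$transverse)) {
    expect_equal(sum(pl[1:3]^2), 1, tolerance = 1e-12)
  }
})

test_that("the sagittal-transverse angle is 90 degrees for any input", {
  set.seed(31)
  for (i in 1:10) {
    spec <- synthetic_spec(true_AI = runif(1, 25, 55), true_AA = runif(1, 5, 30),
                           landmark_jitter_sd = runif(1, 0, 2),
                           pose_rotation_deg = runif(3, -25, 25),
                           pose_translation = runif(3, -80, 80),
                           seed = i)
    frame <- build_frame(generate_pelvis(spec)$landmarks)
    rep <- perpendicularity_report(frame)
    expect_lt(abs(rep$angle_sagittal_transverse - 90), 1e-12)
    expect_lt(abs(rep$angle_coronal_transverse - 90), 1e-12)
  }
})

test_that("noisy landmarks push only the coronal-sagittal angle off 90", {
  set.seed(41)
  devs <- sapply(1:40, function(i) {
    frame <- build_frame(generate_pelvis(
      synthetic_spec(landmark_jitter_sd = 1.5, seed = i))$landmarks)
    perpendicularity_report(frame)$angle_coronal_sagittal
  })
  expect_lt(abs(mean(devs) - 90), 2)   # centered near perpendicular
  expect_gt(stats::sd(devs), 0)        # but spread by the noise
})

test_that("frame construction is equivariant under rigid transforms", {
  set.seed(51)
  set <- generate_pelvis(synthetic_spec())$landmarks
  f0 <- build_frame(set)
  for (i in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 100)
    f1 <- build_frame(transform_landmarks(set, R, tr))
    expect_equal(f1$longitudinal_axis, as.numeric(R %*% f0$longitudinal_axis),
                 tolerance = 1e-9)
    expect_equal(f1$transverse_axis, as.numeric(R %*% f0$transverse_axis),
                 tolerance = 1e-9)
    expect_equal(unname(f1$coronal[1:3]),
                 as.numeric(R %*% plane_normal(f0$coronal)), tolerance = 1e-9)
    expect_equal(f1$origin, as.numeric(R %*% f0$origin + tr), tolerance = 1e-9)
  }
})

test_that("the literal transverse construction is degenerate for a symmetric pelvis", {
  set <- generate_pelvis(synthetic_spec())$landmarks
  # ASIS vector is exactly parallel to the sagittal normal here
  expect_error(build_frame(set, transverse_mode = "literal"),
               class = "acetorient_degenerate")
  app <- build_app(set)$plane
  sag <- build_sagittal(set)$plane
  expect_error(build_transverse(app, sag, c(0, 0, 0),
                                asis_vector = set$asis_right - set$asis_left,
                                mode = "literal"),
               class = "acetorient_degenerate")
})
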