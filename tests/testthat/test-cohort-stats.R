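test_that("normality test behaves under null and a bimodal alternative", {
  set.seed(131)
  null_p <- replicate(60, ks_normality(rnorm(500, 40, 10))$p_value)
  expect_gte(mean(null_p > 0.05), 0.9)
  bimodal_p <- replicate(30, {
    x <- c(rnorm(250, 20, 3), rnorm(250, 60, 3))
    ks_normality(x)$p_value
  })
  expect_true(all(bimodal_p < 0.05))
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
  st <- ks_normality(rnorm(98))$statistic
  expect_gte(st, 0); expect_lte(st, 1)
})

test_that("Blom scores match direct evaluation and preserve order", {
  x <- c(12, 3, 47, 20, 8)
  z <- blom_transform(x)
  r <- rank(x)
  expect_equal(z, qnorm((r - 0.375) / 5.25), tolerance = 1e-12)
  expect_identical(order(z), order(x))
  # middle of three distinct values scores exactly zero
  expect_equal(blom_transform(c(5, 1, 9))[1], 0, tolerance = 1e-12)
  expect_warning(ztied <- blom_transform(rep(2, 6)), "tied")
  expect_true(all(ztied == 0))
  # rescaled variant keeps the sample's mean and sd
  zr <- blom_transform(x, rescale = TRUE)
  expect_equal(mean(zr), mean(x), tolerance = 1e-9)
  expect_equal(sd(zr), sd(x), tolerance = 1e-9)
})

test_that("vs-90 t-test is calibrated and has power", {
  set.seed(141)
  null_p <- replicate(200, t_test_vs_90(rnorm(49, 90, 5))$p_value)
  expect_gt(mean(null_p > 0.05), 0.85)
  alt_p <- replicate(100, t_test_vs_90(rnorm(49, 80, 5))$p_value)
  expect_gte(mean(alt_p < 0.01), 0.95)
  expect_error(t_test_vs_90(rep(90, 10)), "zero-variance")
})

test_that("sex and age-bin comparisons run their declared tests", {
  set.seed(151)
  rec <- data.frame(case_id = sprintf("c%02d", 1:60), side = "right",
                    age = sample(18:56, 60, TRUE),
                    sex = rep(c("M", "F"), 30),
                    AI = rnorm(60, 37, 11), OI = rnorm(60, 45, 14),
                    RI = rnorm(60, 49, 14), AA = rnorm(60, 18, 8),
                    OA = rnorm(60, 25, 10), RA = rnorm(60, 14, 6))
  sex <- group_compare(rec, by = "sex")
  expect_identical(nrow(sex), 6L)
  expect_true(all(sex$p_value >= 0 & sex$p_value <= 1))
  # identical groups give t = 0, p = 1
  rec2 <- rec
  rec2$AI <- rep(c(30, 40, 50), 20)  # identical distribution across sexes
  s2 <- group_compare(rec2, by = "sex")
  expect_equal(s2$statistic[s2$measurement == "AI"], 0, tolerance = 1e-9)
  expect_equal(s2$p_value[s2$measurement == "AI"], 1, tolerance = 1e-9)

  ages <- group_compare(rec, by = "age_bin")
  expect_identical(nrow(ages), 12L)  # chi-square + ANOVA per measurement
  expect_setequal(unique(ages$test), c("chisq_age_bins", "anova_age_bins"))

  # a strong sex separation is detected
  rec3 <- rec
  rec3$AI <- rnorm(60, 37, 5) + ifelse(rec3$sex == "M", 10, 0)
  expect_lt(group_compare(rec3, "sex")$p_value[1], 0.01)
})

test_that("chi-square on a table with no association gives statistic 0", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(unname(chisq.test(tab)$statistic), 0)
  # the same property through group_compare: angles perfectly balanced
  rec <- data.frame(case_id = sprintf("c%02d", 1:40), side = "right",
                    age = rep(c(25, 45), each = 20), sex = "M",
                    AI = rep(c(30, 50), 20), OI = rep(c(30, 50), 20),
                    RI = rep(c(30, 50), 20), AA = rep(c(10, 20), 20),
                    OA = rep(c(10, 20), 20), RA = rep(c(10, 20), 20))
  ages <- group_compare(rec, by = "age_bin")
  chi <- ages[ages$test == "chisq_age_bins" & ages$measurement == "AI", ]
  expect_equal(chi$statistic, 0, tolerance = 1e-9)
})

test_that("LSD contrasts equal pooled-variance t-tests and detect the pattern", {
  set.seed(161)
  g <- list(anatomical = rnorm(98, 37, 12), operative = rnorm(98, 45, 12),
            radiographic = rnorm(98, 49, 12))
  res <- anova_lsd(g)
  expect_lt(res$p_value, 0.01)
  # algebraic identity: with equal group variances pooled over 3 groups,
  # the LSD t for a pair uses MSE; recompute by hand
  mse <- res$ms_error
  d <- mean(g$anatomical) - mean(g$operative)
  t_hand <- d / sqrt(mse * (2 / 98))
  p_hand <- 2 * pt(-abs(t_hand), 3 * 98 - 3)
  pw <- res$pairwise
  row <- pw[pw$group1 == "anatomical" & pw$group2 == "operative", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p_value, p_hand, tolerance = 1e-12)
  # three identical samples: F = 0
  same <- rnorm(30)
  res0 <- anova_lsd(list(a = same, b = same, c = same))
  expect_equal(res0$F, 0, tolerance = 1e-9)
  # bonferroni never lowers a p-value
  resb <- anova_lsd(g, adjust = "bonferroni")
  expect_true(all(resb$pairwise$p_value >= pw$p_value - 1e-12))
})

test_that("two identical groups of three give that pair an LSD p near 1", {
  set.seed(171)
  x <- rnorm(300, 45, 12)
  res <- anova_lsd(list(a = x, b = x, c = rnorm(300, 37, 12)))
  pw <- res$pairwise
  expect_gt(pw$p_value[pw$group1 == "a" & pw$group2 == "b"], 0.95)
})

test_that("cohort summary reproduces brute-force means and handles subgroups", {
  set.seed(181)
  cohort <- generate_cohort(n_cases = 30, landmark_jitter_sd = 0.5, seed = 3)
  records <- do.call(rbind, lapply(cohort, function(cs) measure_all(cs$landmarks)))
  sm <- summarize_cohort(records)
  tot <- sm$summary[sm$summary$group == "total", ]
  expect_equal(tot$mean[tot$measurement == "AI"], mean(records$AI),
               tolerance = if (sm$ri_transformed) 1e-9 else 1e-9)
  expect_equal(tot$sd[tot$measurement == "OA"], sd(records$OA), tolerance = 1e-9)
  expect_true(all(tot$n == nrow(records)))
  # subgroup n's sum to the total for sex
  sexn <- sm$summary[grepl("^sex:", sm$summary$group) &
                       sm$summary$measurement == "AI", "n"]
  expect_equal(sum(sexn), sm$n_hips)
  agen <- sm$summary[grepl("^age:", sm$summary$group) &
                       sm$summary$measurement == "AI", "n"]
  expect_equal(sum(agen), sm$n_hips)
  expect_true(all(sm$normality$p_value >= 0 & sm$normality$p_value <= 1,
                  na.rm = TRUE))
  # perpendicularity audit present (per case)
  expect_false(is.null(sm$perpendicularity))
  expect_identical(sm$perpendicularity$coronal_sagittal$n, 30L)
  expect_output(print(sm), "hips")
})

test_that("single records and degenerate rows are handled explicitly", {
  one <- data.frame(case_id = "c1", side = "right", age = 30, sex = "M",
                    AI = 40, OI = 38, RI = 39, AA = 15, OA = 12, RA = 10)
  sm <- summarize_cohort(one)
  tot <- sm$summary[sm$summary$group == "total", ]
  expect_equal(tot$mean[tot$measurement == "AI"], 40)
  expect_true(all(is.na(tot$sd)))

  two <- rbind(one, one)
  two$AI[2] <- NA
  expect_message(sm2 <- summarize_cohort(two), "excluded")
  expect_identical(sm2$n_excluded, 1L)
})
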