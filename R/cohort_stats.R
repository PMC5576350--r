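# Cohort-level statistics over per-hip orientation measurements: normality
# testing, Blom rank-based normal scores, subgroup comparisons by sex and
# age bin, the vs-90-degrees perpendicularity t-test, and one-way ANOVA with
# Fisher LSD pairwise contrasts across the three measurement systems.
#
# The sampling unit is the hip; within-patient correlation between the two
# sides of one case is ignored (a documented limitation of this analysis
# design, not corrected here).

.MEASUREMENTS <- c("AI", "OI", "RI", "AA", "OA", "RA")

#' Age bins used for subgroup summaries
#'
#' Bins `<30, [30,40), [40,50), >=50` years.
#'
#' @param age numeric ages in years.
#' @return Factor with levels `"<30", "[30,40)", "[40,50)", ">=50"`.
#' @export
age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, 50, Inf),
      labels = c("<30", "[30,40)", "[40,50)", ">=50"),
      right = FALSE)
}

#' Normality test with estimated parameters (Lilliefors-corrected KS)
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution whose
#' mean and sd are estimated from the sample, with the Lilliefors correction
#' for that estimation (the uncorrected KS p-value would be grossly
#' conservative). Statistic is the KS D in `[0, 1]`.
#'
#' @param values numeric sample, n >= 5.
#' @return List with `statistic`, `p_value`, `n`, `normal`
#'   (p >= 0.05).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("normality test needs n >= 5, got ", length(values))
  if (stats::sd(values) == 0) stop("normality test undefined for zero-variance sample")
  ht <- nortest::lillie.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(values), normal = ht$p.value >= 0.05)
}

#' Blom rank-based normal scores
#'
#' `qnorm((rank - 3/8) / (n + 1/4))` with average ranks for ties. Monotone
#' in the input with mean approximately zero. With `rescale = TRUE` the
#' scores are mapped back to the sample's original mean and sd so the
#' transformed variable keeps its units (degrees).
#'
#' @param values numeric vector, n >= 2.
#' @param rescale rescale scores to the input mean/sd (default FALSE:
#'   standard normal scores).
#' @return Numeric vector of scores (NA preserved).
#' @export
blom_transform <- function(values, rescale = FALSE) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("Blom transformation needs n >= 2 finite values")
  x <- values[ok]
  if (length(unique(x)) == 1) {
    warning("all values tied; Blom scores are all zero")
    out <- values
    out[ok] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  if (rescale) z <- mean(x) + stats::sd(x) * z / stats::sd(z)
  out <- values
  out[ok] <- z
  out
}

#' One-sample t-test of plane angles against 90 degrees
#'
#' Tests whether a sample of reference-plane angles is centered on
#' perpendicularity (mu = 90). The comparison is against a constant, so a
#' one-sample t-test is the applicable form.
#'
#' @param plane_angles numeric angles in degrees, n >= 2 with nonzero
#'   variance.
#' @return List with `statistic`, `p_value`, `mean`, `n`.
#' @export
t_test_vs_90 <- function(plane_angles) {
  x <- plane_angles[is.finite(plane_angles)]
  if (length(x) < 2) stop("t-test needs n >= 2")
  if (stats::sd(x) == 0) stop("t-test undefined for zero-variance sample")
  ht <- stats::t.test(x, mu = 90)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean = mean(x), n = length(x))
}

#' Subgroup comparisons of each measurement by sex or age bin
#'
#' By sex: two-sample pooled-variance (Student) t-test per measurement. By
#' age bin: the continuous angles are compared two ways — a chi-square test
#' on the bins-by-(above/below cohort median) contingency table (the
#' categorical reading of "age groups examined by chi-square"), and a
#' one-way ANOVA across bins.
#'
#' @param records data.frame with the six angle columns plus `sex` and
#'   `age`.
#' @param by `"sex"` or `"age_bin"`.
#' @return data.frame with one row per measurement (and per test for age):
#'   `measurement`, `test`, `statistic`, `p_value`, `n`.
#' @export
group_compare <- function(records, by = c("sex", "age_bin")) {
  by <- match.arg(by)
  rows <- list()
  for (m in .MEASUREMENTS) {
    v <- records[[m]]
    if (by == "sex") {
      g <- factor(records$sex)
      ok <- is.finite(v) & !is.na(g)
      if (nlevels(droplevels(g[ok])) < 2 || min(table(droplevels(g[ok]))) < 2) {
        stop("sex comparison for ", m, " needs two groups with n >= 2")
      }
      ht <- stats::t.test(v[ok] ~ droplevels(g[ok]), var.equal = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        measurement = m, test = "t_sex", statistic = unname(ht$statistic),
        p_value = ht$p.value, n = sum(ok))
    } else {
      g <- age_bin(records$age)
      ok <- is.finite(v) & !is.na(g)
      gg <- droplevels(g[ok])
      if (nlevels(gg) < 2) stop("age comparison for ", m, " needs >= 2 bins")
      above <- factor(v[ok] > stats::median(v[ok]), levels = c(FALSE, TRUE))
      ht_chi <- suppressWarnings(stats::chisq.test(table(gg, above)))
      fit <- stats::aov(v[ok] ~ gg)
      sm <- summary(fit)[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        measurement = m, test = "chisq_age_bins",
        statistic = unname(ht_chi$statistic), p_value = ht_chi$p.value,
        n = sum(ok))
      rows[[length(rows) + 1]] <- data.frame(
        measurement = m, test = "anova_age_bins",
        statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
        n = sum(ok))
    }
  }
  do.call(rbind, rows)
}

#' One-way ANOVA with Fisher LSD pairwise contrasts
#'
#' Compares the three measurement systems (anatomical, operative,
#' radiographic readings of the same quantity). Pairwise contrasts are
#' Fisher's least significant difference: t-tests using the pooled
#' within-group mean square and its residual degrees of freedom, with
#' unadjusted p-values — that is what LSD means. `adjust = "bonferroni"`
#' multiplies the pairwise p-values by the number of pairs for modern
#' practice.
#'
#' @param groups named list of (at least two) numeric samples, each n >= 2;
#'   canonically `list(anatomical = ..., operative = ..., radiographic =
#'   ...)`.
#' @param adjust `"none"` (LSD proper) or `"bonferroni"`.
#' @return List with `F`, `p_value`, `df`, `ms_error`, and `pairwise`
#'   (data.frame: `group1`, `group2`, `diff`, `t`, `p_value`).
#' @export
anova_lsd <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(x) x[is.finite(x)])
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs n >= 2 finite values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (stats::sd(y) == 0) stop("degenerate (zero-variance) data")
  fit <- stats::aov(y ~ g)
  sm <- summary(fit)[[1]]
  mse <- sm[["Mean Sq"]][2]
  df_err <- sm[["Df"]][2]

  pairs <- utils::combn(names(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    d <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tval <- d / se
    p <- 2 * stats::pt(-abs(tval), df_err)
    if (adjust == "bonferroni") p <- min(1, p * ncol(pairs))
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, t = tval,
               p_value = p, stringsAsFactors = FALSE)
  })
  list(F = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
       df = c(sm[["Df"]][1], df_err), ms_error = mse,
       pairwise = do.call(rbind, pw))
}

#' Full cohort summary
#'
#' Mean, sd and n of each measurement overall and by sex and age bin;
#' normality tests (with the RI rule: if RI fails normality, a Blom
#' transformation rescaled to RI's units replaces it in the parametric
#' comparisons); sex and age subgroup tests; ANOVA + LSD across the three
#' inclination systems and across the three anteversion systems; and, when
#' frame-audit columns are present, the vs-90-degrees t-tests of the
#' coronal-sagittal and coronal-transverse plane angles. Hips flagged
#' degenerate or with missing angles are excluded with a logged count.
#'
#' @param records data.frame as produced by [measure_all()] (rows bound over
#'   cases), or any data.frame with `case_id`, `side`, `age`, `sex` and the
#'   six angle columns.
#' @param lsd_adjust passed to [anova_lsd()].
#' @return An object of class `cohort_summary`: list with `summary`
#'   (long data.frame of mean/sd/n by measurement and group), `normality`,
#'   `sex_tests`, `age_tests`, `anova_inclination`, `anova_anteversion`,
#'   `perpendicularity`, `n_hips`, `n_excluded`, `ri_transformed`.
#' @export
summarize_cohort <- function(records, lsd_adjust = c("none", "bonferroni")) {
  lsd_adjust <- match.arg(lsd_adjust)
  stopifnot(is.data.frame(records), all(.MEASUREMENTS %in% names(records)))
  n_in <- nrow(records)
  ok <- rowSums(!is.finite(as.matrix(records[.MEASUREMENTS]))) == 0
  if ("degenerate" %in% names(records)) ok <- ok & !records$degenerate
  rec <- records[ok, , drop = FALSE]
  n_excluded <- n_in - nrow(rec)
  if (nrow(rec) < 1) stop("no valid hip records after exclusions")
  if (n_excluded > 0) {
    message(n_excluded, " of ", n_in, " hip records excluded (degenerate or incomplete)")
  }

  normality <- do.call(rbind, lapply(.MEASUREMENTS, function(m) {
    ht <- if (nrow(rec) >= 5 && stats::sd(rec[[m]]) > 0) ks_normality(rec[[m]])
          else list(statistic = NA_real_, p_value = NA_real_,
                    n = nrow(rec), normal = NA)
    data.frame(measurement = m, statistic = ht$statistic, p_value = ht$p_value,
               n = ht$n, normal = ht$normal)
  }))

  # RI rule: if RI fails the normality test, use rescaled Blom scores of RI
  # in the parametric comparisons
  ri_transformed <- isTRUE(!normality$normal[normality$measurement == "RI"])
  if (ri_transformed) {
    rec$RI <- blom_transform(rec$RI, rescale = TRUE)
  }

  summarize_one <- function(d, group) {
    do.call(rbind, lapply(.MEASUREMENTS, function(m) {
      v <- d[[m]]
      data.frame(measurement = m, group = group,
                 mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }
  pieces <- list(summarize_one(rec, "total"))
  for (s in c("M", "F")) {
    d <- rec[!is.na(rec$sex) & rec$sex == s, , drop = FALSE]
    if (nrow(d)) pieces[[length(pieces) + 1]] <- summarize_one(d, paste0("sex:", s))
  }
  bins <- age_bin(rec$age)
  for (b in levels(bins)) {
    d <- rec[!is.na(bins) & bins == b, , drop = FALSE]
    if (nrow(d)) pieces[[length(pieces) + 1]] <- summarize_one(d, paste0("age:", b))
  }
  summary_tab <- do.call(rbind, pieces)

  has_sex <- length(unique(stats::na.omit(rec$sex))) >= 2 &&
    min(table(stats::na.omit(rec$sex))) >= 2
  sex_tests <- if (has_sex) group_compare(rec, by = "sex") else NULL
  has_age <- nlevels(droplevels(bins[!is.na(bins)])) >= 2
  age_tests <- if (has_age) group_compare(rec, by = "age_bin") else NULL

  anova_incl <- if (nrow(rec) >= 2) {
    anova_lsd(list(anatomical = rec$AI, operative = rec$OI,
                   radiographic = rec$RI), adjust = lsd_adjust)
  } else NULL
  anova_ante <- if (nrow(rec) >= 2) {
    anova_lsd(list(anatomical = rec$AA, operative = rec$OA,
                   radiographic = rec$RA), adjust = lsd_adjust)
  } else NULL

  perpendicularity <- NULL
  audit_cols <- c(coronal_sagittal = "angle_coronal_sagittal",
                  coronal_transverse = "angle_coronal_transverse")
  if (all(audit_cols %in% names(rec)) && nrow(rec) >= 2) {
    # one audit per case, not per hip
    one_per_case <- rec[!duplicated(rec$case_id), , drop = FALSE]
    perpendicularity <- lapply(audit_cols, function(col) {
      x <- one_per_case[[col]]
      if (length(x[is.finite(x)]) >= 2 && stats::sd(x, na.rm = TRUE) > 0) {
        t_test_vs_90(x)
      } else list(statistic = NA_real_, p_value = NA_real_,
                  mean = mean(x, na.rm = TRUE), n = sum(is.finite(x)))
    })
  }

  structure(list(summary = summary_tab, normality = normality,
                 sex_tests = sex_tests, age_tests = age_tests,
                 anova_inclination = anova_incl,
                 anova_anteversion = anova_ante,
                 perpendicularity = perpendicularity,
                 n_hips = nrow(rec), n_excluded = n_excluded,
                 ri_transformed = ri_transformed),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d hips (%d excluded)%s\n", x$n_hips,
              x$n_excluded,
              if (x$ri_transformed) "; RI Blom-transformed" else ""))
  tot <- x$summary[x$summary$group == "total", ]
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %s: %.2f +/- %.2f (n = %d)\n", tot$measurement[i],
                tot$mean[i], tot$sd[i], tot$n[i]))
  }
  if (!is.null(x$anova_inclination)) {
    cat(sprintf("  inclination ANOVA: F = %.2f, p = %.3g\n",
                x$anova_inclination$F, x$anova_inclination$p_value))
  }
  if (!is.null(x$anova_anteversion)) {
    cat(sprintf("  anteversion ANOVA: F = %.2f, p = %.3g\n",
                x$anova_anteversion$F, x$anova_anteversion$p_value))
  }
  invisible(x)
}
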