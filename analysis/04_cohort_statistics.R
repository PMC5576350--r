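#!/usr/bin/env Rscript
# Cohort statistics over the measured hips: normality of each measurement
# (with the Blom fallback for RI), subgroup summaries and tests by sex and
# age bin, and one-way ANOVA with Fisher LSD contrasts comparing the
# anatomical, operative and radiographic readings of inclination and of
# anteversion.

suppressMessages(library(acetorient))

records <- read.csv("results/measurements.csv")
sm <- summarize_cohort(records)

write.csv(sm$summary, "results/cohort_summary.csv", row.names = FALSE)
write.csv(sm$normality, "results/normality_tests.csv", row.names = FALSE)
if (!is.null(sm$sex_tests)) {
  write.csv(rbind(sm$sex_tests, sm$age_tests), "results/subgroup_tests.csv",
            row.names = FALSE)
}
pw <- rbind(cbind(family = "inclination", sm$anova_inclination$pairwise),
            cbind(family = "anteversion", sm$anova_anteversion$pairwise))
write.csv(pw, "results/lsd_contrasts.csv", row.names = FALSE)

print(sm)
cat("\nLSD pairwise contrasts:\n")
print(pw, digits = 4)
cat(sprintf("\nsystem divergences: OA - RA = %.2f deg, RI - AI = %.2f deg, AA - RA = %.2f deg\n",
            mean(records$OA - records$RA), mean(records$RI - records$AI),
            mean(records$AA - records$RA)))
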