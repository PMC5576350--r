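#!/usr/bin/env Rscript
# Audits reference-plane perpendicularity across the cohort: the three
# pairwise plane angles per case, and one-sample t-tests of the
# coronal-sagittal and coronal-transverse angles against 90 degrees. The
# sagittal-transverse angle is 90 by construction and is reported, not
# tested.

suppressMessages(library(acetorient))

records <- read.csv("results/measurements.csv")
audit <- records[!duplicated(records$case_id),
                 c("case_id", "angle_coronal_sagittal",
                   "angle_coronal_transverse", "angle_sagittal_transverse")]
write.csv(audit, "results/plane_audit.csv", row.names = FALSE)

cat(sprintf("coronal-sagittal:   %.2f +/- %.2f deg\n",
            mean(audit$angle_coronal_sagittal), sd(audit$angle_coronal_sagittal)))
cat(sprintf("coronal-transverse: %.2f +/- %.2f deg\n",
            mean(audit$angle_coronal_transverse), sd(audit$angle_coronal_transverse)))
cat(sprintf("sagittal-transverse: %.12f deg (construction)\n",
            mean(audit$angle_sagittal_transverse)))

for (col in c("angle_coronal_sagittal")) {
  if (sd(audit[[col]]) > 0) {
    ht <- t_test_vs_90(audit[[col]])
    cat(sprintf("%s vs 90: t = %.3f, p = %.3f -> %s\n", col, ht$statistic,
                ht$p_value,
                if (ht$p_value > 0.05) "statistically perpendicular"
                else "deviates from perpendicular"))
  }
}
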