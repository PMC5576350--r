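#!/usr/bin/env Rscript
# Conversion-formula residuals across the cohort: evaluates, per hip,
#   r1 = OA - atan(sin RI * cos RA)
#   r2 = AA - atan(cos OI * cos OA)
#   r3 = RA - asin(tan OI * cos OA)   (undefined outside the asin domain)
# as printed in the source literature, alongside the geometrically
# consistent identities (c1-c3) implied by the axis parametrization. The
# printed residuals are systematically non-zero even though every hip's six
# angles come from one exact geometry, while the consistent identities
# vanish up to measurement noise: the printed conversions do not transform
# one measurement system into another.

suppressMessages(library(acetorient))

records <- read.csv("results/measurements.csv")
res <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
  r <- murray_residuals(records[i, ], consistent = TRUE)
  data.frame(case_id = records$case_id[i], side = records$side[i],
             r1 = r$r1, r2 = r$r2, r3 = r$r3, r3_defined = r$r3_defined,
             c1 = r$c1, c2 = r$c2, c3 = r$c3)
}))
write.csv(res, "results/murray_residuals.csv", row.names = FALSE)

cat("printed conversion residuals (deg):\n")
for (m in c("r1", "r2", "r3")) {
  v <- res[[m]][is.finite(res[[m]])]
  cat(sprintf("  %s: %.2f +/- %.2f (n = %d defined)\n", m, mean(v), sd(v),
              length(v)))
}
cat("geometrically consistent residuals (deg):\n")
for (m in c("c1", "c2", "c3")) {
  cat(sprintf("  %s: %.4f +/- %.4f\n", m, mean(res[[m]]), sd(res[[m]])))
}
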