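#!/usr/bin/env Rscript
# Stage 3: interrater agreement. One-way random, absolute-agreement,
# average-measures intraclass correlation ICC(1,4) for guarding (binary
# codes) and movement self-efficacy (ordinal codes), overall and per
# exercise type.

suppressPackageStartupMessages(library(guardnet))

cohort <- read_cohort("results/cohort")
icc <- icc_table(cohort$instances, cohort$ratings)
write.csv(icc, "results/icc.csv", row.names = FALSE)

cat("ICC(1,k), one-way random, average measures:\n")
print(transform(icc, icc = round(icc, 2)), row.names = FALSE)
good <- icc$icc[icc$measure == "guarding" & icc$exercise != "all"]
cat(sprintf("guarding per-exercise ICCs span %.2f-%.2f\n",
            min(good, na.rm = TRUE), max(good, na.rm = TRUE)))
cat("wrote results/icc.csv\n")
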