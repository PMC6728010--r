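#!/usr/bin/env Rscript
# Stage 2: aggregate rater labels into analysis records -- guarding as the
# sum of present-codes over the 4 raters (0-4), movement self-efficacy as
# the median ordinal code -- keeping instances with at least one of pain,
# anxiety or distress reported.

suppressPackageStartupMessages(library(guardnet))

cohort <- read_cohort("results/cohort")
records <- assemble_records(cohort$instances, cohort$ratings)
write.csv(records, "results/records.csv", row.names = FALSE)

cat(nrow(records), "of", nrow(cohort$instances),
    "instances pass the inclusion rule\n")
cat(sprintf("guarding score: mean %.1f, SD %.1f\n",
            mean(records$guarding), sd(records$guarding)))
cat(sprintf("self-efficacy:  mean %.1f, SD %.1f\n",
            mean(records$self_efficacy), sd(records$self_efficacy)))
cat("wrote results/records.csv\n")
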