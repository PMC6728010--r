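#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic chronic-pain cohort at study scale --
# 17 patients, 1-9 exercise instances each (mean 6), three exercise types in
# a 73/19/8 mix, two challenge levels, and 4 physiotherapist raters per
# instance -- and write it under results/cohort/.

suppressPackageStartupMessages(library(guardnet))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

cohort <- simulate_cohort(generator_config(seed = seed))
paths <- write_cohort(cohort, "results/cohort")

inst <- cohort$instances
cat("simulated", nrow(inst), "exercise instances from",
    length(unique(inst$patient_id)), "patients (seed", seed, ")\n")
cat("exercise mix:\n")
print(round(prop.table(table(inst$exercise)), 2))
cat("self-report profile:\n")
print(round(rbind(mean = colMeans(inst[c("pain", "anxiety", "distress")]),
                  sd = apply(inst[c("pain", "anxiety", "distress")], 2, sd)),
            2))
cat("wrote:", paste(basename(paths), collapse = ", "),
    "-> results/cohort/\n")
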