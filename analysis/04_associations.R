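#!/usr/bin/env Rscript
# Stage 4: pairwise Spearman correlations among the five analysis variables,
# the lower/higher dichotomizations (pain and anxiety at 5/10, distress at
# >19/39, self-efficacy at better-than-medium), and the guarding-score
# frequency distributions by stratum.

suppressPackageStartupMessages(library(guardnet))

records <- read.csv("results/records.csv", stringsAsFactors = FALSE)
cm <- correlation_matrix(records)
write.csv(cm$table, "results/correlations.csv", row.names = FALSE)
print(cm)

tab <- cm$table
top <- tab[order(-abs(tab$rho)), ][1, ]
cat(sprintf("strongest association: %s ~ %s, rho = %.2f (n = %d)\n",
            top$var1, top$var2, top$rho, top$n))

labelled <- dichotomize(records)
freq <- guarding_frequency_table(labelled)
write.csv(freq, "results/fig1_counts.csv", row.names = FALSE)
g0 <- freq[freq$guarding == 0, ]
cat("instances with guarding score 0, by stratum:\n")
print(stats::xtabs(count ~ variable + level, g0))
cat("wrote results/correlations.csv, results/fig1_counts.csv\n")
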