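#!/usr/bin/env Rscript
# Render the paired-comparison tables as a markdown report, one section per
# sex stratum, shaped like a standard kinematics comparison table:
# median (IQR) per condition, z, P, effect size r and magnitude category.
suppressPackageStartupMessages(library(feedkin))

comparison <- read.csv("results/pipeline/comparison.csv")
lines <- report_comparison(comparison)
writeLines(lines, "results/report.md")
cat("Wrote results/report.md (", length(lines), "lines )\n")
cat("Largest effects:\n")
top <- comparison[order(abs(comparison$r), decreasing = TRUE), ][1:5, ]
print(top[, c("stratum", "metric", "phase", "z", "p", "r", "category")],
      row.names = FALSE, digits = 3)
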