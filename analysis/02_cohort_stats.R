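#!/usr/bin/env Rscript
# Cohort statistics over the label-quality table from 01_simulate_cohort.R:
# one-sample t-tests of coupling and drift against zero, and paired
# mirror-vs-mimic t-tests for the accuracy/precision metrics.
#
# Input:  results/metrics.tsv
# Output: results/stats_labels.tsv

suppressPackageStartupMessages(library(myolabel))

metrics <- read.delim("results/metrics.tsv")
stats <- cohort_stats(label_metrics = metrics)
write.table(stats, "results/stats_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Cohort statistics (n = ", length(unique(metrics$participant)),
    " participants):\n\n", sep = "")
show <- function(df) {
  df$p <- signif(df$p, 3)
  df$estimate <- signif(df$estimate, 4)
  print(df[, c("test", "term", "estimate", "statistic", "df", "p")],
        row.names = FALSE)
}
show(stats[stats$test == "one_sample_t_vs_0", ])
cat("\nBoth coupling and drift should differ from zero: the ground-truth\n",
    "hand neither isolates movements nor holds a fixed rest posture.\n\n",
    sep = "")
show(stats[stats$test == "paired_t_mirror_vs_mimic", ])
cat("\nNegative estimates favour mirror labels (smaller error);\n",
    "timing dispersion is the one metric where mimic labels are more\n",
    "consistent (the reaction lag is steadier than bimanual asynchrony).\n",
    sep = "")
cat("\nWrote results/stats_labels.tsv\n")
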