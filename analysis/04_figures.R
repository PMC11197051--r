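#!/usr/bin/env Rscript
# Summary figures for the cohort metrics and the learning curve.
#
# Inputs:  results/metrics.tsv, results/learning_curve.tsv (if present)
# Outputs: results/figures/label_quality.pdf, results/figures/learning_curve.pdf

suppressPackageStartupMessages({
  library(myolabel)
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

metrics <- read.delim("results/metrics.tsv")
rows <- list()
for (v in c("mag_err_mean_pct", "mag_err_disp_pct",
            "timing_err_abs_mean_ms", "timing_err_disp_ms", "rmse")) {
  rows[[v]] <- data.frame(metric = v, paradigm = metrics$paradigm,
                          value = metrics[[v]])
}
long <- do.call(rbind, rows)
p1 <- ggplot(long, aes(paradigm, value, fill = paradigm)) +
  geom_violin(alpha = 0.5, show.legend = FALSE) +
  geom_jitter(width = 0.08, size = 1, show.legend = FALSE) +
  facet_wrap(~metric, scales = "free_y") +
  labs(title = "Training-label quality by paradigm",
       subtitle = "7 simulated participants; lower is better except none",
       x = NULL, y = NULL) +
  theme_minimal()
ggsave("results/figures/label_quality.pdf", p1, width = 8, height = 5)
cat("wrote results/figures/label_quality.pdf\n")

lc_file <- "results/learning_curve.tsv"
if (file.exists(lc_file)) {
  lc <- read.delim(lc_file)
  summ <- unique(lc[, c("paradigm", "algorithm", "n_train_trials",
                        "summary_rmse")])
  p2 <- ggplot(summ, aes(n_train_trials, summary_rmse,
                         colour = paradigm, linetype = algorithm)) +
    geom_line() + geom_point() +
    labs(title = "Decoder error vs training-set size",
         x = "training trials per movement",
         y = "RMSE vs ground truth (median over folds)") +
    theme_minimal()
  ggsave("results/figures/learning_curve.pdf", p2, width = 6, height = 4)
  cat("wrote results/figures/learning_curve.pdf\n")
} else {
  cat("no learning_curve.tsv yet; run analysis/03_decoding_curves.R first\n")
}
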