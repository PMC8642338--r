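#!/usr/bin/env Rscript
# Measure every participant x rate with the weighted up-down staircase:
# each true threshold becomes a Weibull observer (width = threshold, 2%
# lapses) and one adaptive run per condition estimates its threshold as the
# mean of the last six of 18 reversals.

suppressPackageStartupMessages(library(ratesync))

truth <- read.csv("results/cohort_truth.csv")
meas <- measure_cohort_staircase(truth, seed = 42)
write.csv(meas, "results/thresholds_wud.csv", row.names = FALSE)

rel_err <- with(meas, measured_threshold / threshold - 1)
message(sprintf("Measured %d staircases; median |relative error| vs truth: %.1f%%",
                nrow(meas), 100 * median(abs(rel_err))))
message(sprintf("Spearman correlation measured vs true thresholds: %.3f",
                cor(meas$threshold, meas$measured_threshold,
                    method = "spearman")))
message("Wrote results/thresholds_wud.csv")
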