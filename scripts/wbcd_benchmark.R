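#!/usr/bin/env Rscript
# OPTIONAL benchmark on the real Wisconsin Breast Cancer (Original) file.
#
# This script is NOT part of the test suite: it needs a user-supplied copy
# of the UCI file (breast-cancer-wisconsin.data), and the published
# accuracies depend on seeds and hyperparameters the original study does
# not state.  It reruns the stratified 50/50 holdout with 100 repetitions
# and reports where the APC's mean accuracy lands; agreement with the
# published figure within about one percentage point is typical but is not
# asserted.
#
# Usage:
#   Rscript scripts/wbcd_benchmark.R path/to/breast-cancer-wisconsin.data [seed]

suppressPackageStartupMessages(library(apclass))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/wbcd_benchmark.R <wbcd file> [seed]")
}
path <- args[1]
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

d <- read_wbcd(path, missing_policy("impute_global_mean"))
print(load_summary(d))

plan <- stratified_holdout(d$class, fraction = 0.5, repetitions = 100,
                           base_seed = seed)
res <- evaluate_classifier(d, apc_classifier(), plan,
                           policy = missing_policy("impute_global_mean"))
g <- glance(res)
cat(sprintf(
  "APC, stratified 50/50 holdout x %d (seed %d): mean accuracy %.2f%% (sd %.2f%%), rejection %.2f%%\n",
  g$units, seed, 100 * g$mean_accuracy, 100 * g$sd_accuracy,
  100 * g$mean_rejection_rate))

mdc <- glance(evaluate_classifier(d, mdc_classifier(), plan))
cat(sprintf("MDC, same protocol: mean accuracy %.2f%%\n",
            100 * mdc$mean_accuracy))
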