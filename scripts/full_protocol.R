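#!/usr/bin/env Rscript

# Full-scale reproduction of the reference experiment: 100,000 simulated
# segments (75,000 train / 25,000 validation), the default 1,225,606-weight
# network trained for 33 epochs, evaluated point-wise and object-wise on
# 10,000 independently simulated segments. This runs for many hours on one
# CPU; use scripts/acceptance.R or runPipeline(scale = ...) for desk-scale
# runs of the same protocol.
#
# usage: Rscript scripts/full_protocol.R [--seed S] [--out-dir DIR]

library(nmrmultiplet)

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(getArg("--seed", "1"))
outDir <- getArg("--out-dir", "full_protocol_results")

res <- runPipeline(outDir, scale = 1, seed = seed, verbose = TRUE)

m <- res$results$metrics
cat(sprintf("average accuracy  %.1f%%\n", 100 * mean(m$accuracy)))
cat(sprintf("average precision %.1f%%\n",
            100 * mean(m$precision, na.rm = TRUE)))
cat(sprintf("average recall    %.1f%%\n", 100 * mean(m$recall, na.rm = TRUE)))
cat(sprintf("average F1        %.1f%%\n", 100 * mean(m$f1, na.rm = TRUE)))
for (ow in res$results$objectwise)
  cat(sprintf("mAP at IOU %.2f    %.1f%%\n", ow$iou, 100 * ow$mAP))
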