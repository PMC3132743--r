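#!/usr/bin/env Rscript
# Partition each gene's variance into within-strain (W) and between-strain
# (B) components and summarize the W/T ratio by expression bin, the
# intra- vs inter-strain variability analysis.

suppressPackageStartupMessages(library(strainvar))

X <- read_expression_matrix("results/expression.tsv",
                            "results/samples.tsv")
vp <- partition_variance(X)
write_variance_table(vp, "results/variance_partition.tsv",
                     header = c(stage = "variance"))

cat("W/T ratio: median", round(median(vp$ratio), 3),
    "| point mass at 1 (truncation):", round(mean(vp$ratio == 1), 3),
    "\n")
print(table(vp$bin))
hist_counts <- table(cut(vp$ratio, seq(0, 1, 0.1), include.lowest = TRUE))
write.table(as.data.frame(hist_counts),
            "results/wt_histogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
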