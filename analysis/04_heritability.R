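#!/usr/bin/env Rscript
# Heritability of expression: where do the cross lines sit relative to
# their parents? Computes parental-interval distances for LnA and LnC
# over genes with significant LE vs HW differential expression, their
# kernel densities, and the interacting-locus calls.

suppressPackageStartupMessages(library(strainvar))

X <- read_expression_matrix("results/expression.tsv",
                            "results/samples.tsv")
fit <- fit_simple_pairwise(X)

prof <- distance_profile(X, fit)
d <- c(prof$records$d_LnA, prof$records$d_LnC)
cat("gated probesets:", nrow(prof$records), "\n")
cat("distance values inside [0,1]:",
    round(mean(d >= 0 & d <= 1, na.rm = TRUE), 3),
    "| inside [-0.1,1.1]:",
    round(mean(d >= -0.1 & d <= 1.1, na.rm = TRUE), 3), "\n")
write.table(prof$records, "results/heritability_distances.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

inter <- find_interacting_loci(fit)
cat("interacting gene x line calls:", nrow(inter),
    "| found in both lines:",
    length(unique(inter$gene_id[inter$both_lines])), "\n")
write.table(inter, "results/interacting_loci.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
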