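#!/usr/bin/env Rscript
# Platform and cross-species concordance: qPCR-style ddCt validation of
# array fold changes, and rank correlation of per-gene inter-strain
# variability statistics across a simulated homolog map (emulating a
# rat-vs-mouse comparison).

suppressPackageStartupMessages(library(strainvar))

X <- read_expression_matrix("results/expression.tsv",
                            "results/samples.tsv")
fit <- fit_simple_pairwise(X)

## qPCR emulation for 21 genes: Ct values derived from the simulated
## log2 expression plus measurement noise (one PCR cycle ~ one log2 unit)
set.seed(901)
genes <- sample(f_statistic_filter(fit, 0.001), 21)
st <- X$samples$strain
pcr <- do.call(rbind, lapply(genes, function(g) {
  data.frame(gene = g, sample = X$samples$sample_id, strain = st,
             Ct_target = 25 - X$values[g, ] + rnorm(20, sd = 0.3),
             Ct_reference = 20 + rnorm(20, sd = 0.1))
}))
pcr <- pcr_normalize(pcr, calibrator_strain = "LE")
write.table(pcr, "results/pcr_measurements.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## all pairwise log2 fold changes on both platforms
gm <- strain_means(X)
pairs <- combn(colnames(gm), 2)
fc_array <- fc_pcr <- c()
for (g in genes) {
  ne <- tapply(log2(pcr$NE[pcr$gene == g]), pcr$strain[pcr$gene == g],
               mean)
  for (j in seq_len(ncol(pairs))) {
    fc_array <- c(fc_array, gm[g, pairs[1, j]] - gm[g, pairs[2, j]])
    fc_pcr <- c(fc_pcr, ne[[pairs[1, j]]] - ne[[pairs[2, j]]])
  }
}
conc <- platform_concordance(fc_array, fc_pcr)
cat("array vs PCR fold-change concordance over", conc$n,
    "comparisons: Pearson R =", round(conc$r, 3), "\n")

## cross-species comparison: independent "mouse" statistics
rat_F <- setNames(fit$F, fit$gene_ids)
hm <- simulate_homolog_map(fit$gene_ids, paste0("Mm", 1:4000),
                           fraction_multi_match = 0.3, seed = 902L)
set.seed(903)
mouse_q <- setNames(runif(length(unique(hm$mouse_gene))),
                    unique(hm$mouse_gene))
for (mode in c("none", "mean", "min", "max")) {
  agg <- suppressMessages(homolog_aggregate(rat_F, hm, mode))
  cc <- cross_species_correlation(agg$stat, mouse_q[agg$mouse_gene])
  cat(sprintf("mode %-4s: %d pairs, Spearman rho = %+.3f (p = %.2g)\n",
              mode, cc$n, cc$rho, cc$p))
}

## cross-tissue style comparison on gene groups
groups <- list(Strain = sample(names(rat_F), 200),
               Diet = sample(names(rat_F), 150))
ct <- cross_tissue_compare(rat_F, groups)
print(ct)
write.table(ct, "results/cross_tissue.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
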