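#!/usr/bin/env Rscript
# Functional enrichment: Fisher-exact term enrichment across the ten W/T
# deciles and across the eleven contrasts (ten strain pairs + AHR), the
# cumulative log10-p term selection, and DIANA clustering of the
# resulting term x contrast matrix. Annotations are simulated with a
# term coupled to the AHR gene set so the expected structure is known.

suppressPackageStartupMessages(library(strainvar))

X <- read_expression_matrix("results/expression.tsv",
                            "results/samples.tsv")
truth <- read.delim("results/truth.tsv")
vp <- partition_variance(X)
fit_s <- fit_simple_pairwise(X)
fit_a <- fit_ancestry_ahr(X)

ahr_set <- truth$gene_id[truth$ahr_effect != 0]
ann <- simulate_annotations(truth$gene_id, n_terms = 40,
                            genes_per_term = 80,
                            coupled_set = ahr_set, coupled_term = 1,
                            enrichment_factor = 60, seed = 206L)

em_dec <- decile_enrichment(vp, ann)
cat("terms enriched at p < 1e-5 in >= 1 W/T decile:", nrow(em_dec), "\n")
write.table(data.frame(term_id = rownames(em_dec), em_dec),
            "results/enrichment_deciles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

em <- contrast_enrichment(fit_s, fit_a, ann)
sel <- cumulative_term_selection(em, cutoff = -10)
cat("terms below the -10 cumulative log10 p cutoff:", nrow(sel), "\n")
if (nrow(sel) > 0) {
  cat("best AHR-column term:",
      rownames(em)[which.min(em[, "AHR"])], "at log10 p =",
      round(min(em[, "AHR"]), 2), "\n")
}
write.table(data.frame(term_id = rownames(em), em, check.names = FALSE),
            "results/enrichment_contrasts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(sel) >= 2) {
  tree <- diana(correlation_distance(sel))
  writeLines(diana_newick(tree), "results/enrichment_terms.newick")
}

# permutation FDR on the coupled term's gene set
hits <- permutation_fdr(ahr_set, truth$gene_id, ann, n_perm = 1000,
                        fdr_threshold = 0.10, seed = 207L)
cat("terms surviving the 10% permutation FDR:", nrow(hits), "\n")
write.table(hits, "results/enrichment_permutation_fdr.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
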