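#!/usr/bin/env Rscript
# Transcription-factor binding-site enrichment: scores a JASPAR-style
# motif over simulated target promoters (motif planted) against two
# background pools (all promoters; promoters of expressed genes), using
# the five-null permutation scheme (mono- and dinucleotide shuffles,
# PWM column permutation, and two background resamplings).

suppressPackageStartupMessages(library(strainvar))

set.seed(701)
cons <- sample(c("A", "C", "G", "T"), 18, replace = TRUE)
counts <- sapply(cons, function(b) {
  v <- rep(1, 4); names(v) <- c("A", "C", "G", "T"); v[b] <- 97; v
})
colnames(counts) <- NULL
pwm <- strainvar:::pwm_object("MX0001", "SYNTH18", counts)
write_jaspar(list(pwm), "results/test_motif.jaspar")

targets <- simulate_promoters(sprintf("t%02d", 1:50), 2001, pwm,
                              planted_fraction = 0.8, instances = 2,
                              seed = 702L)
pool <- simulate_promoters(sprintf("a%03d", 1:300), 2001, pwm,
                           planted_fraction = 0, seed = 703L)
write_fasta(targets$sequences, "results/target_promoters.fa")

res <- five_test_significance(pwm, targets$sequences, pool$sequences,
                              pool$sequences[1:150], n_perm = 1000,
                              seed = 704L)
print(res)
out <- data.frame(motif_id = res$motif_id, raw_score = res$raw_score,
                  t(res$p_enrich), n_significant = res$n_significant,
                  call = res$call)
write.table(out, "results/tfbs_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("motif", res$motif_id, "call:", res$call, "with", res$n_significant,
    "of", res$n_tests, "tests significant; raw score",
    round(res$raw_score, 2), "\n")
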