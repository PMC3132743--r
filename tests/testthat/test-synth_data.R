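test_that("simulation is reproducible from its seed", {
  a <- simulate_expression(sim_config(n_genes = 200, seed = 5))
  b <- simulate_expression(sim_config(n_genes = 200, seed = 5))
  expect_identical(a$X$values, b$X$values)
  expect_identical(a$truth$strain_means, b$truth$strain_means)
  c <- simulate_expression(sim_config(n_genes = 200, seed = 6))
  expect_false(identical(a$X$values, c$X$values))
})

test_that("noise-only genes have chi-square-consistent sample variances", {
  sim <- simulate_expression(sim_config(n_genes = 2000,
                                        fraction_strain_de = 0,
                                        fraction_ahr_de = 0,
                                        fraction_interacting = 0,
                                        sigma_w = 0.5, seed = 8))
  v <- apply(sim$X$values, 1, var)
  n <- ncol(sim$X$values)
  lo <- 0.25 * qchisq(0.025, n - 1) / (n - 1)
  hi <- 0.25 * qchisq(0.975, n - 1) / (n - 1)
  cover <- mean(v >= lo & v <= hi)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("planted AHR effects appear between carrier and wildtype groups", {
  sim <- simulate_expression(sim_config(n_genes = 2000,
                                        fraction_strain_de = 0,
                                        fraction_interacting = 0,
                                        fraction_ahr_de = 0.1,
                                        ahr_effect = 3, seed = 9))
  st <- sim$X$samples$strain
  carrier <- rowMeans(sim$X$values[, st %in% c("HW", "LnA")])
  wild <- rowMeans(sim$X$values[, st %in% c("LE", "SD", "LnC")])
  diff <- (carrier - wild)[sim$truth$ahr_genes]
  signed <- sim$truth$ahr_effect[match(sim$truth$ahr_genes,
                                       sim$truth$gene_ids)]
  expect_equal(mean(abs(diff - signed)), 0, tolerance = 0.2)
  expect_true(all(abs(abs(signed) - 3) < 1e-12))
})

test_that("heritability classes respect the parental interval", {
  sim <- simulate_expression(sim_config(n_genes = 3000,
                                        fraction_interacting = 0.02,
                                        fraction_ahr_de = 0, seed = 10))
  m <- sim$truth$strain_means
  lo <- pmin(m[, "LE"], m[, "HW"])
  hi <- pmax(m[, "LE"], m[, "HW"])
  dir <- sim$truth$class == "directional"
  eps <- 1e-9
  expect_true(all(m[dir, "LnA"] >= lo[dir] - eps &
                    m[dir, "LnA"] <= hi[dir] + eps))
  expect_true(all(m[dir, "LnC"] >= lo[dir] - eps &
                    m[dir, "LnC"] <= hi[dir] + eps))
  tr <- sim$truth$interacting
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    g <- match(tr$gene_id[i], sim$truth$gene_ids)
    val <- m[g, tr$line[i]]
    if (tr$direction[i] == "above") expect_gt(val, hi[g])
    else expect_lt(val, lo[g])
  }
})

test_that("replicate floor is enforced", {
  expect_error(sim_config(replicates_per_strain = 1), "replicates")
})

test_that("promoter simulation plants verifiable motif instances", {
  pwm <- sharp_pwm(L = 8, peak = 997)
  cons <- rownames(pwm$counts)[apply(pwm$counts, 2, which.max)]
  cons <- paste(cons, collapse = "")

  full <- simulate_promoters(paste0("g", 1:30), length = 8, motif = pwm,
                             planted_fraction = 1, seed = 4)
  expect_length(full$planted, 30)
  # every sequence is a (possibly reverse-complemented) near-consensus draw
  match_frac <- vapply(full$sequences, function(s) {
    max(mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]]),
        mean(strsplit(oracle_revcomp(s), "")[[1]] ==
               strsplit(cons, "")[[1]]))
  }, 0)
  expect_true(all(match_frac >= 6 / 8))

  none <- simulate_promoters(paste0("g", 1:50), length = 300, motif = pwm,
                             planted_fraction = 0, seed = 4)
  expect_length(none$planted, 0)
  hits <- sum(vapply(none$sequences, function(s) {
    m <- gregexpr(cons, s, fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, 0L))
  # expected consensus occurrences: 50 * 293 windows * (1/4)^8
  expect_lte(hits, qbinom(0.999, 50 * 293, 0.25^8))

  again <- simulate_promoters(paste0("g", 1:50), length = 300, motif = pwm,
                              planted_fraction = 0, seed = 4)
  expect_identical(none$sequences, again$sequences)
  expect_error(simulate_promoters("g1", length = 4, motif = pwm,
                                  planted_fraction = 1),
               "longer than sequence")
})

test_that("annotation simulation couples the requested term", {
  genes <- paste0("g", 1:200)
  coupled <- genes[1:40]
  ann <- simulate_annotations(genes, n_terms = 10, genes_per_term = 20,
                              coupled_set = coupled, coupled_term = 1,
                              enrichment_factor = 10, seed = 5)
  expect_identical(ann, simulate_annotations(genes, 10, 20, coupled,
                                             1, 10, seed = 5))
  # achieved odds ratio of the coupled term within 2-fold of requested,
  # averaged over replicates
  ors <- vapply(1:30, function(s) {
    a <- simulate_annotations(genes, 10, 20, coupled, 1, 10, seed = s)
    memb <- unique(a$gene_id[a$term_id == "T0001"])
    x11 <- sum(memb %in% coupled)
    x10 <- length(coupled) - x11
    x01 <- length(memb) - x11
    x00 <- length(genes) - length(coupled) - x01
    (x11 + 0.5) * (x00 + 0.5) / ((x10 + 0.5) * (x01 + 0.5))
  }, 0)
  expect_gt(mean(ors), 5)
  expect_lt(mean(ors), 20)

  flat <- simulate_annotations(genes, 10, 20, character(0), 1, 10,
                               seed = 5)
  sizes <- table(flat$term_id)
  expect_true(all(sizes == 20))
  expect_error(simulate_annotations(genes, 3, 500), "exceeds")
})

test_that("homolog map honours multiplicity", {
  rat <- paste0("r", 1:120)
  mouse <- paste0("m", 1:100)
  bij <- simulate_homolog_map(rat, mouse, 0, seed = 6)
  expect_equal(anyDuplicated(bij$rat_gene), 0)
  expect_equal(anyDuplicated(bij$mouse_gene), 0)
  multi <- simulate_homolog_map(rat, mouse, 0.2, seed = 6)
  n_pairs <- length(unique(multi$mouse_gene))
  expect_equal(sum(table(multi$mouse_gene) == 2) / n_pairs, 0.2,
               tolerance = 0.05)
  expect_identical(multi, simulate_homolog_map(rat, mouse, 0.2, seed = 6))
})
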