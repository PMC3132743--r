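test_that("a uniform PWM on a uniform background scores exactly zero", {
  counts <- matrix(1, 4, 6)
  rownames(counts) <- c("A", "C", "G", "T")
  pwm <- strainvar:::pwm_object("U1", "UNIFORM", counts)
  withr::with_seed(71, {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  })
  expect_equal(sequence_score(pwm, s), 0, tolerance = 1e-12)
})

test_that("a consensus hit scores far above background", {
  pwm <- sharp_pwm(L = 12, peak = 997)
  cons <- paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)],
                collapse = "")
  withr::with_seed(72, {
    bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  })
  planted <- paste0(substr(bg, 1, 200), cons, substr(bg, 213, 400))
  expect_gt(sequence_score(pwm, planted), sequence_score(pwm, bg) + 5)
})

test_that("per-sequence scores match manual window enumeration", {
  counts <- matrix(c(8, 1, 1, 1,
                     1, 8, 1, 1,
                     1, 1, 1, 8), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- strainvar:::pwm_object("M3", "ACT", counts)
  seqch <- "ACGTTACG"
  got <- sequence_score(pwm, seqch, pseudocount = 0.375)

  # independent enumeration over all 6 windows on each strand
  f <- sweep(counts + 0.375, 2, colSums(counts + 0.375), "/")
  lr_of <- function(s) {
    v <- strsplit(s, "")[[1]]
    prod(vapply(seq_along(v),
                function(j) f[v[j], j] / 0.25, 0))
  }
  windows <- function(s) vapply(1:6, function(i) substr(s, i, i + 2), "")
  all_lr <- c(vapply(windows(seqch), lr_of, 0),
              vapply(windows(oracle_revcomp(seqch)), lr_of, 0))
  expect_equal(got, log(mean(all_lr)), tolerance = 1e-12)

  expect_error(sequence_score(pwm, "AC"), "shorter")
})

test_that("windows touching non-ACGT characters contribute zero likelihood", {
  counts <- matrix(c(8, 1, 1, 1,
                     1, 8, 1, 1), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- strainvar:::pwm_object("M2", "AC", counts)
  # windows overlapping the N are excluded from the likelihood average
  f <- sweep(counts + 0.375, 2, colSums(counts + 0.375), "/")
  lr <- function(b1, b2) f[b1, 1] / 0.25 * f[b2, 2] / 0.25
  s <- "ACNAC"
  valid <- c(lr("A", "C"), lr("A", "C"),                 # forward AC, AC
             lr("G", "T"), lr("G", "T"))                 # revcomp GT, GT
  expected <- log(sum(valid) / 8)                        # 8 windows total
  expect_equal(sequence_score(pwm, s), expected, tolerance = 1e-12)
})

test_that("set scores are arithmetic means of per-sequence scores", {
  pwm <- sharp_pwm(L = 8)
  withr::with_seed(73, {
    seqs <- vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
            collapse = ""), "")
  })
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  per <- vapply(seqs, function(s) sequence_score(pwm, s, bg), 0)
  expect_equal(set_score(pwm, seqs, bg), mean(per), tolerance = 1e-12)
  expect_equal(set_score(pwm, rep(seqs[1], 5), bg), per[[1]],
               tolerance = 1e-12)
  two <- set_score(pwm, seqs[1:2], bg)
  expect_gte(two, min(per[1:2]))
  expect_lte(two, max(per[1:2]))
  expect_error(set_score(pwm, character(0)), "empty")
})

test_that("set scores are invariant to reverse-complementing every target", {
  pwm <- sharp_pwm(L = 9)
  withr::with_seed(74, {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
            collapse = ""), "")
  })
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  rc <- vapply(seqs, oracle_revcomp, "")
  expect_equal(set_score(pwm, seqs, bg), set_score(pwm, rc, bg),
               tolerance = 1e-10)
})

test_that("shuffles preserve base and dinucleotide composition exactly", {
  withr::with_seed(75, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                        prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
      m <- shuffle_mono(s)
      expect_identical(sort(strsplit(m, "")[[1]]),
                       sort(strsplit(s, "")[[1]]))
      d <- shuffle_dinuc(s)
      expect_identical(as.vector(oracle_dinuc(d)[names(oracle_dinuc(s))]),
                       as.vector(oracle_dinuc(s)))
      expect_identical(substr(d, 1, 1), substr(s, 1, 1))
      expect_identical(substr(d, 150, 150), substr(s, 150, 150))
    }
  })
})

test_that("the expressed background uses the >= 4 mean-intensity rule", {
  vals <- rbind(lowg = rep(3.999, 8), edge = rep(4.0, 8),
                high = rep(9, 8))
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     strain = rep(c("LE", "HW"), each = 4),
                     ahr_variant = 0)
  colnames(vals) <- meta$sample_id
  X <- expression_matrix(vals, meta)
  eb <- expressed_background(X)
  expect_identical(eb, c("edge", "high"))

  sim <- simulate_expression(sim_config(n_genes = 4000,
                                        bin_weights = c(0.5, 0.2, 0.2,
                                                        0.1),
                                        seed = 76))
  frac <- length(expressed_background(sim$X)) / 4000
  expect_equal(frac, 0.5, tolerance = 0.1)
})

test_that("five-test scheme flags a planted motif and calibrates on null", {
  pwm <- sharp_pwm(L = 18)
  genes_t <- sprintf("t%02d", 1:25)
  genes_b <- sprintf("b%03d", 1:120)
  tset <- simulate_promoters(genes_t, 400, pwm, planted_fraction = 0.8,
                             instances = 2, seed = 77)
  pool <- simulate_promoters(genes_b, 400, pwm, planted_fraction = 0,
                             seed = 78)
  res <- five_test_significance(pwm, tset$sequences, pool$sequences,
                                pool$sequences[1:60], n_perm = 150,
                                seed = 79)
  expect_s3_class(res, "TFBSResult")
  expect_identical(res$call, "enriched")
  expect_gte(res$n_significant, 4)
  expect_gte(res$raw_score, 5)
  # add-one estimator: p is never exactly 0; the opposite tail can reach
  # 1 exactly when every null score falls on that side
  expect_true(all(res$p_enrich > 0 & res$p_enrich <= 1, na.rm = TRUE))
  expect_true(all(res$p_deplete > 0 & res$p_deplete <= 1, na.rm = TRUE))
  expect_gte(min(res$p_enrich, na.rm = TRUE), 1 / 151)

  # reproducibility from the seed
  res2 <- five_test_significance(pwm, tset$sequences, pool$sequences,
                                 pool$sequences[1:60], n_perm = 150,
                                 seed = 79)
  expect_identical(res$p_enrich, res2$p_enrich)

  # a random target set from the pool is not called
  calls <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    idx <- sample(120, 25)
    r <- five_test_significance(pwm, pool$sequences[idx],
                                pool$sequences, pool$sequences[1:60],
                                n_perm = 120, seed = 2000 + s)
    r$call
  }, "")
  expect_lte(sum(calls == "enriched"), 1)
})

test_that("column permutation is powerless for single-base repeat motifs", {
  counts <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", ] <- 50   # AAAAAAAA: all columns identical
  pwm <- strainvar:::pwm_object("REP", "POLYA", counts)
  genes <- sprintf("t%02d", 1:15)
  tset <- simulate_promoters(genes, 200, pwm, planted_fraction = 1,
                             instances = 2, seed = 80)
  pool <- simulate_promoters(sprintf("b%02d", 1:60), 200, pwm, 0,
                             seed = 81)
  res <- five_test_significance(pwm, tset$sequences, pool$sequences,
                                pool$sequences[1:30], n_perm = 120,
                                seed = 82)
  # permuting identical columns reproduces the observed score exactly
  expect_gte(res$p_enrich[["matrix"]], 0.99)
  expect_lt(res$p_enrich[["mono"]], 0.05)
  expect_lt(res$p_enrich[["bgA"]], 0.05)
})

test_that("undersized background pools are skipped with a warning", {
  pwm <- sharp_pwm(L = 10)
  tset <- simulate_promoters(sprintf("t%02d", 1:20), 150, pwm, 0.9,
                             instances = 2, seed = 83)
  pool <- simulate_promoters(sprintf("b%02d", 1:30), 150, pwm, 0,
                             seed = 84)
  expect_warning(
    res <- five_test_significance(pwm, tset$sequences, pool$sequences,
                                  pool$sequences[1:5], n_perm = 100,
                                  seed = 85),
    "skipped")
  expect_equal(res$n_tests, 4)
  expect_true(is.na(res$p_enrich[["bgB"]]))
})
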