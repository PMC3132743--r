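five_pop_samples <- function(nrep = 4) {
  strains <- rep(c("LE", "HW", "SD", "LnA", "LnC"), each = nrep)
  data.frame(sample_id = paste0(strains, "_",
                                rep(seq_len(nrep), 5)),
             strain = strains,
             ahr_variant = ifelse(strains %in% c("HW", "LnA"), 1, 0))
}

test_that("design matrices encode strain indicators and ancestry + AHR", {
  samples <- five_pop_samples()
  anc <- strainvar:::default_ancestry(samples$strain)
  rownames(anc) <- samples$sample_id

  D <- build_design(samples, "simple")
  expect_equal(dim(D), c(20L, 5L))
  expect_equal(qr(D)$rank, 5)
  expect_true(all(rowSums(D) == 1))

  Dc <- build_design(samples, "ancestry_ahr", ancestry = anc)
  lna <- Dc[samples$strain == "LnA", , drop = FALSE][1, ]
  expect_equal(lna[["HW"]], 0.5)
  expect_equal(lna[["LE"]], 0.5)
  expect_equal(lna[["SD"]], 0)
  expect_equal(lna[["AHR"]], 1)
  hw <- Dc[samples$strain == "HW", , drop = FALSE][1, ]
  expect_equal(unname(hw[c("HW", "LE", "SD", "AHR")]), c(1, 0, 0, 1))

  # without the cross lines the AHR column is confounded with HW
  sub <- samples[samples$strain %in% c("LE", "HW", "SD"), ]
  anc_sub <- anc[samples$strain %in% c("LE", "HW", "SD"), ]
  expect_error(build_design(sub, "ancestry_ahr", ancestry = anc_sub),
               "rank-deficient")
})

test_that("pairwise contrasts enumerate unordered pairs", {
  expect_equal(ncol(pairwise_contrast_matrix(c("A", "B", "C", "D", "E"))),
               10)
  expect_equal(ncol(pairwise_contrast_matrix(c("A", "B"))), 1)
  C4 <- pairwise_contrast_matrix(c("A", "B", "C", "D"))
  expect_equal(ncol(C4), 6)
  expect_true(all(colSums(C4) == 0))
  expect_true(all(colSums(abs(C4)) == 2))
})

test_that("genewise OLS matches the normal-equations oracle", {
  samples <- five_pop_samples()
  withr::with_seed(31, {
    vals <- matrix(rnorm(30 * 20), nrow = 30,
                   dimnames = list(paste0("g", 1:30), samples$sample_id))
    X <- expression_matrix(vals, samples)
    fit <- fit_genewise(X, "simple")
    D <- build_design(samples, "simple")
    for (g in c(2, 17)) {
      beta <- solve(t(D) %*% D) %*% t(D) %*% vals[g, ]
      expect_equal(unname(fit$coefficients[g, ]), as.vector(beta),
                   tolerance = 1e-10)
      res <- vals[g, ] - D %*% beta
      expect_equal(unname(fit$s2[g]), sum(res^2) / (20 - 5),
                   tolerance = 1e-10)
    }
    # a gene equal to a design column has zero residual variance
    vals2 <- vals
    vals2[1, ] <- D[, "LE"]
    X2 <- expression_matrix(vals2, samples)
    expect_equal(fit_genewise(X2, "simple")$s2[[1]], 0, tolerance = 1e-20)
    # two-group coefficients are the group means
    gmeans <- tapply(vals[5, ], samples$strain, mean)
    expect_equal(unname(fit$coefficients[5, names(gmeans)]),
                 as.vector(gmeans), tolerance = 1e-12)
  })
})

test_that("moderated statistics agree with the reference eBayes", {
  skip_if_not_installed("limma")
  samples <- five_pop_samples()
  withr::with_seed(32, {
    s2 <- 0.25 * 4 / rchisq(300, 4)
    vals <- matrix(rnorm(300 * 20, sd = sqrt(rep(s2, 20))), nrow = 300,
                   dimnames = list(paste0("g", 1:300), samples$sample_id))
  })
  X <- expression_matrix(vals, samples)
  fit <- fit_genewise(X, "simple")
  C <- pairwise_contrast_matrix(colnames(fit$design))
  mod <- moderate(fit, C)

  lf <- limma::lmFit(vals, build_design(samples, "simple"))
  lf <- limma::contrasts.fit(lf, C)
  le <- limma::eBayes(lf)
  expect_equal(mod$d0, le$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, le$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t), unname(le$t), tolerance = 1e-8)
  expect_equal(unname(mod$p), unname(le$p.value), tolerance = 1e-8)
  expect_equal(unname(mod$F), unname(le$F), tolerance = 1e-8)
})

test_that("moderation hyperparameters are recovered from a known prior", {
  sim <- simulate_expression(sim_config(n_genes = 10000,
                                        fraction_strain_de = 0,
                                        fraction_ahr_de = 0,
                                        fraction_interacting = 0,
                                        sigma_w = NULL, var_prior_df = 4,
                                        var_prior_s02 = 0.25, seed = 33))
  fit <- moderate(fit_genewise(sim$X, "simple"))
  expect_gt(fit$d0, 3)
  expect_lt(fit$d0, 5)
  expect_gt(fit$s02, 0.2)
  expect_lt(fit$s02, 0.3)
})

test_that("identical variances trigger the infinite-prior branch", {
  samples <- five_pop_samples()
  # deterministic per-strain patterns give identical residual variance
  base <- rep(c(0.3, -0.1, 0.2, -0.4), 5)
  vals <- matrix(rep(base, each = 60), nrow = 60, byrow = FALSE)
  vals <- vals + matrix(rnorm(60 * 20, sd = 1e-8), nrow = 60)
  rownames(vals) <- paste0("g", 1:60)
  colnames(vals) <- samples$sample_id
  X <- expression_matrix(vals, samples)
  fit <- fit_genewise(X, "simple")
  fit$s2 <- rep(0.5, 60)   # exactly identical variances
  mod <- moderate(fit)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s02, 0.5, tolerance = 1e-9)
  expect_true(all(abs(mod$s2_post - mod$s02) < 1e-12))
})

test_that("shrinkage moves every t toward the prior variance side", {
  sim <- simulate_expression(sim_config(n_genes = 500, sigma_w = NULL,
                                        seed = 34))
  fit <- fit_genewise(sim$X, "simple")
  C <- pairwise_contrast_matrix(colnames(fit$design))
  mod <- moderate(fit, C)
  t_ord <- sweep(mod$M, 2, sqrt(diag(t(C) %*% fit$xtxi %*% C)), "/") /
    sqrt(fit$s2)
  small <- fit$s2 < mod$s02
  expect_true(all(abs(mod$t[small, ]) <= abs(t_ord[small, ]) + 1e-12))
  expect_true(all(abs(mod$t[!small, ]) >= abs(t_ord[!small, ]) - 1e-12))
})

test_that("pairwise M values are antisymmetric under pair reversal", {
  sim <- simulate_expression(sim_config(n_genes = 100, seed = 35))
  fit <- fit_genewise(sim$X, "simple")
  Cf <- matrix(c(1, -1, 0, 0, 0), ncol = 1,
               dimnames = list(colnames(fit$design), "a"))
  Cr <- -Cf
  mf <- moderate(fit, Cf)
  mr <- moderate(fit, Cr)
  expect_equal(unname(mf$M), unname(-mr$M), tolerance = 1e-12)
  expect_equal(unname(mf$p), unname(mr$p), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.037), 0.037)
  q <- adjust_fdr(runif(100))
  expect_true(all(diff(q[order(runif(100))]) > -1))  # q values in [0,1]
  expect_true(all(q >= 0 & q <= 1))
})

test_that("fold-change conversion matches the published examples", {
  fc <- m_to_fold_change(-2.9)
  expect_equal(round(fc$fold, 1), 7.5)
  expect_identical(fc$direction, "repression")
  fc2 <- m_to_fold_change(5.8)
  expect_gt(fc2$fold, 50)
  expect_identical(fc2$direction, "induction")
  expect_equal(m_to_fold_change(0)$fold, 1)
})

test_that("threshold sensitivity plateaus at the planted DE count", {
  sim <- simulate_expression(sim_config(n_genes = 1000,
                                        fraction_strain_de = 0.1,
                                        strain_effect_range = c(4, 5),
                                        fraction_ahr_de = 0,
                                        fraction_interacting = 0,
                                        sigma_w = 0.2, seed = 36))
  fit <- fit_simple_pairwise(sim$X)
  ts <- threshold_sensitivity(fit, thresholds = c(1, 10^-(1:7), 0))
  all_ct <- ts[ts$threshold == 1, ]
  expect_true(all(all_ct$n_q == 1000))
  expect_true(all(ts$n_q[ts$threshold == 0] == 0))
  # LE-HW DE genes: planted with both-parent effects; counts at stringent
  # thresholds stay near the true DE count for that pair
  truthde <- sum(abs(sim$truth$strain_means[, "LE"] -
                       sim$truth$strain_means[, "HW"]) > 0.5)
  ct <- grep("LE-HW|HW-LE", unique(ts$contrast), value = TRUE)
  n7 <- ts$n_q[ts$contrast == ct & ts$threshold == 1e-7]
  expect_equal(n7, truthde, tolerance = 0.15)
})

test_that("AHR effect table recovers planted effects with calibrated FDR", {
  sim <- simulate_expression(sim_config(n_genes = 3000,
                                        fraction_ahr_de = 0.02,
                                        ahr_effect = 3, sigma_w = 0.5,
                                        seed = 37))
  fit <- fit_ancestry_ahr(sim$X)
  tab <- ahr_effect_table(fit, q_threshold = 0.05)
  truth <- sim$truth$ahr_genes
  expect_gte(mean(truth %in% tab$gene_id), 0.9)
  # estimated M of planted genes is near the planted effect size
  planted_M <- abs(tab$M[tab$gene_id %in% truth])
  expect_equal(mean(planted_M), 3, tolerance = 0.15)
  counts <- attr(tab, "fdr_counts")
  expect_true(all(diff(counts) >= 0))

  null <- simulate_expression(sim_config(n_genes = 3000,
                                         fraction_ahr_de = 0,
                                         fraction_strain_de = 0,
                                         fraction_interacting = 0,
                                         seed = 38))
  tab0 <- ahr_effect_table(fit_ancestry_ahr(null$X))
  expect_lte(nrow(tab0), ceiling(0.05 * 3000))

  expect_error(ahr_effect_table(fit_simple_pairwise(sim$X)), "AHR")
})
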