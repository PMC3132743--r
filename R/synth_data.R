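#' Simulation configuration for the five-population design
#'
#' Defaults emulate the study design the pipeline targets: three parental
#' strains (LE, HW, SD) and two crossbred lines (LnA, LnC) each of 0.5 LE +
#' 0.5 HW ancestry, four replicate animals per population, log2 intensities
#' spanning four expression bins, strain effects on a subset of genes, an
#' AHR-genotype effect shared by HW and LnA, and cross-line means that are
#' predominantly intermediate between the parents (directional genetics)
#' with a small planted fraction outside the parental range (interacting
#' loci).
#'
#' @param n_genes number of genes.
#' @param replicates_per_strain animals per population (default 4).
#' @param fraction_strain_de fraction of genes with parental strain effects.
#' @param strain_effect_range absolute log2 effect-size range for strain
#'   effects (drawn uniformly, random sign).
#' @param fraction_ahr_de fraction of genes with an AHR-genotype effect.
#' @param ahr_effect_range absolute log2 effect-size range for AHR effects.
#' @param ahr_effect fixed AHR effect size; overrides the range when not
#'   \code{NULL} (sign still random).
#' @param fraction_interacting fraction of genes planted outside the
#'   parental range in one cross line.
#' @param d_mix_shape shape of the symmetric Beta(a, a) distribution of
#'   the per-gene parental mixing weight d for directional genes. The
#'   default 0.5 is U-shaped: cross-line expression sits near one of the
#'   two parental levels at most genes, as expected when fixed cis-acting
#'   parental alleles drive the difference, while remaining inside the
#'   parental interval; 1 gives a uniform mixing weight.
#' @param interacting_offset_factor offset beyond the nearer parent, as a
#'   multiple of the parental span (floored at 1 log2 unit of span).
#' @param sigma_w within-strain standard deviation: a single number used
#'   for all genes (default 0.3 log2 units, typical replicate noise of
#'   normalized arrays), or \code{NULL} to draw per-gene values from a
#'   scaled inverse chi-square with \code{var_prior_df} and
#'   \code{var_prior_s02}.
#' @param var_prior_df,var_prior_s02 hyperparameters of the per-gene
#'   variance prior (defaults 4 and 0.25, typical of microarray data).
#' @param sigma_b when non-\code{NULL}, switches the generator to a pure
#'   random-effects design: every population's mean is baseline +
#'   N(0, sigma_b^2), independently per gene and population, with no
#'   directional/interacting or AHR structure (used to calibrate the W/T
#'   estimator, e.g. sigma_b = sigma_w gives a true ratio of 0.5).
#' @param bin_weights mixture weights of baseline intensities over the four
#'   expression bins (<4, 4-8, 8-12, >12).
#' @param seed integer seed; all sub-generators derive child seeds from it.
#' @return a list of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_genes = 5000,
                       replicates_per_strain = 4,
                       fraction_strain_de = 0.10,
                       strain_effect_range = c(1.5, 3),
                       fraction_ahr_de = 0.007,
                       ahr_effect_range = c(0.5, 3.5),
                       ahr_effect = NULL,
                       fraction_interacting = 0.0025,
                       interacting_offset_factor = 1.5,
                       d_mix_shape = 0.5,
                       sigma_w = 0.3,
                       var_prior_df = 4,
                       var_prior_s02 = 0.25,
                       sigma_b = NULL,
                       bin_weights = c(0.35, 0.35, 0.25, 0.05),
                       seed = 1L) {
  stopifnot(fraction_strain_de >= 0, fraction_strain_de <= 1,
            fraction_ahr_de >= 0, fraction_ahr_de <= 1,
            fraction_interacting >= 0,
            fraction_interacting + fraction_strain_de <= 1,
            replicates_per_strain >= 2,
            length(bin_weights) == 4, all(bin_weights >= 0))
  if (!is.null(sigma_w)) stopifnot(sigma_w > 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

# Baseline intensity mixture spanning the four expression bins.
# Component centres sit inside <4, 4-8, 8-12 and >12.
draw_baseline <- function(n, weights) {
  weights <- weights / sum(weights)
  comp <- sample.int(4L, n, replace = TRUE, prob = weights)
  mu <- c(2.5, 6, 10, 13)[comp]
  sd <- c(0.8, 1.0, 1.0, 0.5)[comp]
  stats::rnorm(n, mu, sd)
}

#' Simulate an expression matrix with known ground truth
#'
#' Values are strain mean + Gaussian noise(0, sigma_w,g) on the log2 scale.
#' The AHR effect is added to every population carrying the variant
#' receptor (HW and LnA). Cross-line means are a convex combination of the
#' LE and HW means at a per-gene mixing weight d ~ Uniform(0,1) for
#' directional genes, or placed outside the parental range for interacting
#' genes (one line, chosen at random, offset beyond the nearer parent).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{X} (an \code{ExpressionMatrix}) and
#'   \code{truth} (a list holding per-gene strain means, sigma_w, AHR
#'   effects, heritability classes and true W/T ratios).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$replicates_per_strain < 2)
    stop("need at least 2 replicates per strain")
  set.seed(child_seed(config$seed, "expression"))
  G <- config$n_genes
  nrep <- config$replicates_per_strain
  strains <- ALL_STRAINS
  ahr_carrier <- c(LE = 0, HW = 1, SD = 0, LnA = 1, LnC = 0)

  baseline <- draw_baseline(G, config$bin_weights)
  sigma_w <- if (is.null(config$sigma_w)) {
    sqrt(config$var_prior_df * config$var_prior_s02 /
           stats::rchisq(G, df = config$var_prior_df))
  } else rep(config$sigma_w, G)

  means <- matrix(rep(baseline, length(strains)), nrow = G,
                  dimnames = list(NULL, strains))

  if (!is.null(config$sigma_b)) {
    ## pure random-effects design: independent population offsets, no
    ## directional / interacting / AHR structure
    means <- means + matrix(stats::rnorm(G * length(strains), 0,
                                         config$sigma_b),
                            nrow = G, ncol = length(strains))
    gene_ids <- sprintf("g%05d", seq_len(G))
    rownames(means) <- gene_ids
    return(assemble_simulation(config, means, sigma_w, gene_ids,
                               strains, ahr_carrier, nrep,
                               class = rep("random_effects", G),
                               delta = rep(0, G), ahr_genes = integer(0),
                               d_mix = rep(NA_real_, G),
                               interacting = empty_interacting()))
  }

  ## gene classes: strain-DE (directional over the cross), interacting,
  ## or non-DE. AHR effects are assigned independently.
  n_de <- round(config$fraction_strain_de * G)
  n_int <- round(config$fraction_interacting * G)
  idx <- sample.int(G)
  de_genes <- idx[seq_len(n_de)]
  int_genes <- idx[n_de + seq_len(n_int)]
  class <- rep("non_de", G)
  class[de_genes] <- "directional"

  draw_effect <- function(n, range) {
    stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
  }

  # parental strain effects: each parental strain of a DE gene gets an
  # independent effect, present with probability 2/3
  for (s in PARENTAL_STRAINS) {
    hit <- de_genes[stats::runif(length(de_genes)) < 2 / 3]
    means[hit, s] <- means[hit, s] + draw_effect(length(hit),
                                                 config$strain_effect_range)
  }
  # directional cross-line means: shared per-gene mixing weight d
  d_mix <- stats::rbeta(G, config$d_mix_shape, config$d_mix_shape)
  means[, "LnA"] <- d_mix * means[, "LE"] + (1 - d_mix) * means[, "HW"]
  means[, "LnC"] <- means[, "LnA"]

  # interacting genes: one line pushed outside the parental range
  int_line <- character(0)
  int_dir <- character(0)
  if (n_int > 0) {
    int_line <- sample(c("LnA", "LnC"), n_int, replace = TRUE)
    above <- stats::runif(n_int) < 0.5
    for (j in seq_len(n_int)) {
      g <- int_genes[j]
      span <- abs(means[g, "LE"] - means[g, "HW"])
      off <- config$interacting_offset_factor * max(span, 1)
      hi <- max(means[g, "LE"], means[g, "HW"])
      lo <- min(means[g, "LE"], means[g, "HW"])
      means[g, int_line[j]] <- if (above[j]) hi + off else lo - off
    }
    class[int_genes] <- ifelse(above, "interacting_above",
                               "interacting_below")
    int_dir <- ifelse(above, "above", "below")
  }

  # AHR-genotype effect, shared by every variant-carrier population
  n_ahr <- round(config$fraction_ahr_de * G)
  ahr_genes <- sample.int(G, n_ahr)
  delta <- rep(0, G)
  if (n_ahr > 0) {
    delta[ahr_genes] <- if (!is.null(config$ahr_effect)) {
      config$ahr_effect * sample(c(-1, 1), n_ahr, replace = TRUE)
    } else draw_effect(n_ahr, config$ahr_effect_range)
  }
  for (s in strains[ahr_carrier[strains] == 1])
    means[, s] <- means[, s] + delta

  gene_ids <- sprintf("g%05d", seq_len(G))
  rownames(means) <- gene_ids
  interacting <- if (n_int > 0)
    data.frame(gene_id = gene_ids[int_genes], line = int_line,
               direction = int_dir, stringsAsFactors = FALSE)
  else empty_interacting()
  assemble_simulation(config, means, sigma_w, gene_ids, strains,
                      ahr_carrier, nrep, class = class, delta = delta,
                      ahr_genes = ahr_genes, d_mix = d_mix,
                      interacting = interacting)
}

empty_interacting <- function() {
  data.frame(gene_id = character(0), line = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

# Draw replicate values around the population means and package matrix,
# metadata and ground truth.
assemble_simulation <- function(config, means, sigma_w, gene_ids, strains,
                                ahr_carrier, nrep, class, delta, ahr_genes,
                                d_mix, interacting) {
  G <- nrow(means)
  sample_strain <- rep(strains, each = nrep)
  sample_ids <- paste0(sample_strain, "_", rep(seq_len(nrep),
                                               times = length(strains)))
  values <- means[, sample_strain] +
    matrix(stats::rnorm(G * length(sample_ids), 0, sigma_w),
           nrow = G, ncol = length(sample_ids))
  colnames(values) <- sample_ids
  rownames(values) <- gene_ids
  samples <- data.frame(sample_id = sample_ids, strain = sample_strain,
                        ahr_variant = ahr_carrier[sample_strain],
                        stringsAsFactors = FALSE, row.names = NULL)
  X <- expression_matrix(values, samples)
  # true W/T: within variance over within + between-strain-mean variance
  b_true <- apply(means, 1L, stats::var)
  truth <- list(
    gene_ids = gene_ids,
    strain_means = means,
    sigma_w = sigma_w,
    ahr_effect = delta,
    ahr_genes = gene_ids[sort(ahr_genes)],
    class = class,
    d_mix = d_mix,
    interacting = interacting,
    wt_ratio = sigma_w^2 / (sigma_w^2 + b_true)
  )
  list(X = X, truth = truth)
}

#' Simulate promoter sequences with a planted motif
#'
#' Background bases are i.i.d. from \code{background}; a fraction of genes
#' receives one motif instance sampled from the PWM column frequencies,
#' placed at a uniform position on a uniform strand.
#'
#' @param gene_ids character vector of genes.
#' @param length promoter length in bp.
#' @param motif a PWM object (see \code{\link{read_jaspar}}).
#' @param planted_fraction fraction of genes receiving motif instances.
#' @param instances number of instances planted per planted gene
#'   (default 1; real factor-bound promoters often carry several sites).
#' @param background base composition, named numeric over A,C,G,T.
#' @param seed integer seed.
#' @return list with \code{sequences} (named character) and \code{planted}
#'   (character vector of gene ids carrying an instance).
#' @export
simulate_promoters <- function(gene_ids, length, motif,
                               planted_fraction = 0,
                               instances = 1L,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1, instances >= 1)
  L <- ncol(motif$counts)
  if (planted_fraction > 0 && L > length)
    stop("motif longer than sequence")
  set.seed(child_seed(seed, "promoters"))
  bases <- c("A", "C", "G", "T")
  bg <- background[bases] / sum(background[bases])
  probs <- sweep(motif$counts, 2L, colSums(motif$counts), "/")
  n <- base::length(gene_ids)
  n_plant <- round(planted_fraction * n)
  planted <- sort(sample.int(n, n_plant))
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(bases, length, replace = TRUE, prob = bg)
    if (i %in% planted) {
      for (k in seq_len(instances)) {
        inst <- vapply(seq_len(L),
                       function(j) sample(bases, 1L, prob = probs[, j]), "")
        if (stats::runif(1) < 0.5)
          inst <- rev(chartr("ACGT", "TGCA", inst))
        pos <- sample.int(length - L + 1L, 1L)
        s[pos:(pos + L - 1L)] <- inst
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- gene_ids
  list(sequences = seqs, planted = gene_ids[planted])
}

#' Simulate a gene-to-term annotation table
#'
#' One term's membership is enriched in \code{coupled_set} by the requested
#' odds factor; all other terms draw members uniformly.
#'
#' @param gene_ids universe of genes.
#' @param n_terms number of terms.
#' @param genes_per_term members per term.
#' @param coupled_set subset of \code{gene_ids} to enrich in
#'   \code{coupled_term} (may be empty).
#' @param coupled_term index (1..n_terms) of the enriched term.
#' @param enrichment_factor sampling-odds multiplier for coupled genes.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id}, \code{term_id}.
#' @export
simulate_annotations <- function(gene_ids, n_terms, genes_per_term,
                                 coupled_set = character(0),
                                 coupled_term = 1L,
                                 enrichment_factor = 1,
                                 seed = 1L) {
  if (genes_per_term > length(gene_ids))
    stop("genes_per_term exceeds number of genes")
  stopifnot(all(coupled_set %in% gene_ids))
  set.seed(child_seed(seed, "annotations"))
  terms <- sprintf("T%04d", seq_len(n_terms))
  out <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    w <- rep(1, length(gene_ids))
    if (t == coupled_term && length(coupled_set) > 0)
      w[gene_ids %in% coupled_set] <- enrichment_factor
    members <- sample(gene_ids, genes_per_term, prob = w)
    out[[t]] <- data.frame(gene_id = members, term_id = terms[t],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a rat-to-mouse homolog map
#'
#' A fraction of mouse genes is matched by two rat genes (multi-match),
#' the remainder one-to-one; supports testing of homolog aggregation.
#'
#' @param rat_genes,mouse_genes identifier vectors.
#' @param fraction_multi_match fraction of mapped mouse genes with two rat
#'   matches.
#' @param seed integer seed.
#' @return data.frame with columns \code{rat_gene}, \code{mouse_gene}.
#' @export
simulate_homolog_map <- function(rat_genes, mouse_genes,
                                 fraction_multi_match = 0, seed = 1L) {
  stopifnot(fraction_multi_match >= 0, fraction_multi_match <= 1)
  set.seed(child_seed(seed, "homologs"))
  n_pairs <- min(length(mouse_genes),
                 floor(length(rat_genes) / (1 + fraction_multi_match)))
  mouse <- sample(mouse_genes, n_pairs)
  n_multi <- round(fraction_multi_match * n_pairs)
  n_rat <- n_pairs + n_multi
  rat <- sample(rat_genes, n_rat)
  multi <- if (n_multi > 0) sample.int(n_pairs, n_multi) else integer(0)
  data.frame(rat_gene = rat,
             mouse_gene = c(mouse, mouse[multi]),
             stringsAsFactors = FALSE)
}
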