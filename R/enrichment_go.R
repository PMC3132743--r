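# Build a terms x genes logical membership matrix from a long annotation
# table, restricted to a gene universe.
membership_matrix <- function(annotation, universe) {
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term_id))
  M <- matrix(FALSE, nrow = length(terms), ncol = length(universe),
              dimnames = list(terms, universe))
  M[cbind(match(ann$term_id, terms), match(ann$gene_id, universe))] <- TRUE
  M
}

#' Fisher-exact (hypergeometric) term enrichment
#'
#' For each term, the one-sided upper-tail p of the 2x2 table (genes in
#' set and term, in set not term, in term not set, in neither), i.e. the
#' probability of observing at least as many term genes in the set under
#' hypergeometric sampling.
#'
#' @param set character vector of genes, a subset of \code{universe}.
#' @param universe character vector of all genes.
#' @param annotation data.frame with columns \code{gene_id},
#'   \code{term_id}; only terms annotated to at least one universe gene
#'   are reported.
#' @param depletion if \code{TRUE}, the lower-tail p is returned instead.
#' @return named numeric vector of p-values, one per term.
#' @export
fisher_enrichment <- function(set, universe, annotation,
                              depletion = FALSE) {
  if (length(set) == 0) stop("empty gene set")
  if (length(universe) == 0) stop("empty universe")
  if (!all(set %in% universe)) stop("set must be a subset of the universe")
  M <- membership_matrix(annotation, universe)
  if (nrow(M) == 0) stop("no annotated terms in the universe")
  in_set <- universe %in% set
  k_overlap <- as.vector(M %*% in_set)
  m_term <- rowSums(M)
  n_set <- sum(in_set)
  N <- length(universe)
  p <- if (depletion) {
    stats::phyper(k_overlap, m_term, N - m_term, n_set)
  } else {
    stats::phyper(k_overlap - 1, m_term, N - m_term, n_set,
                  lower.tail = FALSE)
  }
  names(p) <- rownames(M)
  p
}

#' Permutation FDR for term enrichment
#'
#' Null p-value distributions are generated from random gene sets of the
#' same size drawn from the universe; at each candidate p cut the FDR is
#' the mean number of null discoveries divided by the observed discovery
#' count. Terms surviving at \code{fdr_threshold} (default 10\%) are
#' returned. Seeded and reproducible.
#'
#' @param set,universe,annotation as in \code{\link{fisher_enrichment}}.
#' @param n_perm number of randomizations (default 1000, minimum 100).
#' @param fdr_threshold FDR cut (default 0.10).
#' @param seed integer seed.
#' @return data.frame of surviving terms with columns \code{term_id},
#'   \code{p}, \code{fdr}.
#' @export
permutation_fdr <- function(set, universe, annotation, n_perm = 1000,
                            fdr_threshold = 0.10, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (length(set) > length(universe)) stop("set larger than universe")
  set.seed(child_seed(seed, "permutation_fdr"))
  obs <- fisher_enrichment(set, universe, annotation)
  M <- membership_matrix(annotation, universe)
  m_term <- rowSums(M)
  N <- length(universe)
  n_set <- sum(universe %in% set)
  null_p_mat <- matrix(NA_real_, nrow = n_perm, ncol = nrow(M))
  for (b in seq_len(n_perm)) {
    rnd <- logical(N)
    rnd[sample.int(N, n_set)] <- TRUE
    k <- as.vector(M %*% rnd)
    null_p_mat[b, ] <- stats::phyper(k - 1, m_term, N - m_term, n_set,
                                     lower.tail = FALSE)
  }
  cuts <- sort(unique(obs))
  n_null <- vapply(cuts, function(ct) mean(rowSums(null_p_mat <= ct)), 0)
  n_obs <- vapply(cuts, function(ct) sum(obs <= ct), 0)
  fdr_at <- pmin(1, ifelse(n_obs > 0, n_null / n_obs, 0))
  ok <- cuts[fdr_at <= fdr_threshold]
  if (length(ok) == 0)
    return(data.frame(term_id = character(0), p = numeric(0),
                      fdr = numeric(0)))
  cut <- max(ok)
  keep <- obs <= cut
  data.frame(term_id = names(obs)[keep], p = obs[keep],
             fdr = fdr_at[match(obs[keep], cuts)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select terms by cumulative log10 enrichment
#'
#' Keeps terms whose row sum of log10 p across contrasts is at or below
#' the cutoff (default -10, i.e. an unadjusted cumulative enrichment
#' probability of 1e-10; -5, -7.5, -20 and -30 are common alternates).
#'
#' @param matrix terms x contrasts matrix of log10 p (cells <= 0).
#' @param cutoff cumulative log10 score cut.
#' @return the reduced matrix.
#' @export
cumulative_term_selection <- function(matrix, cutoff = -10) {
  stopifnot(is.matrix(matrix))
  matrix[rowSums(matrix) <= cutoff, , drop = FALSE]
}

#' Enrichment matrix over the ten W/T decile groups
#'
#' Runs Fisher enrichment of every term in each W/T decile and keeps terms
#' strongly enriched (p below \code{min_p}, default 1e-5) in at least one
#' group. Cells are log10 p. Empty deciles give a column of p = 1 with a
#' warning. Per-column set sizes are attached as attribute
#' \code{set_sizes} (deciles differ slightly in size, hence in power).
#'
#' @param partition data.frame from \code{\link{partition_variance}}.
#' @param annotation gene-to-term table.
#' @param min_p selection threshold (default 1e-5).
#' @return terms x 10 matrix of log10 p.
#' @export
decile_enrichment <- function(partition, annotation, min_p = 1e-5) {
  universe <- partition$gene_id
  M <- membership_matrix(annotation, universe)
  res <- matrix(0, nrow = nrow(M), ncol = 10,
                dimnames = list(rownames(M), paste0("decile", 1:10)))
  sizes <- integer(10)
  for (g in 1:10) {
    set <- partition$gene_id[partition$decile == g]
    sizes[g] <- length(set)
    if (length(set) == 0) {
      warning("empty W/T decile ", g, "; column reported as p = 1")
      res[, g] <- 0
    } else {
      res[, g] <- log10(fisher_enrichment(set, universe, annotation))
    }
  }
  keep <- apply(res, 1L, min) < log10(min_p)
  out <- res[keep, , drop = FALSE]
  attr(out, "set_sizes") <- sizes
  out
}

#' Enrichment matrix over pairwise contrasts plus the AHR term
#'
#' For each pairwise contrast, the DE gene set (adjusted p below
#' \code{q_threshold}) is tested for term enrichment; an eleventh column
#' holds the AHR-dependent gene set from the ancestry + AHR model. Cells
#' are log10 p. Feed the result to
#' \code{\link{cumulative_term_selection}} and \code{\link{diana}}.
#'
#' @param fit_simple a \code{ModeratedFit} with pairwise contrasts.
#' @param fit_ahr a \code{ModeratedFit} with an AHR contrast.
#' @param annotation gene-to-term table.
#' @param q_threshold DE threshold (default 0.05).
#' @return terms x (pairs + 1) matrix of log10 p with attribute
#'   \code{set_sizes}.
#' @export
contrast_enrichment <- function(fit_simple, fit_ahr, annotation,
                                q_threshold = 0.05) {
  stopifnot(inherits(fit_simple, "ModeratedFit"))
  if (!inherits(fit_ahr, "ModeratedFit") ||
      !"AHR" %in% colnames(fit_ahr$M))
    stop("fit_ahr must carry an AHR contrast")
  universe <- fit_simple$gene_ids
  M <- membership_matrix(annotation, universe)
  cols <- c(colnames(fit_simple$q), "AHR")
  res <- matrix(0, nrow = nrow(M), ncol = length(cols),
                dimnames = list(rownames(M), cols))
  sizes <- integer(length(cols))
  names(sizes) <- cols
  for (ct in colnames(fit_simple$q)) {
    set <- universe[fit_simple$q[, ct] < q_threshold]
    sizes[ct] <- length(set)
    if (length(set) == 0) {
      warning("contrast ", ct, " has no DE genes; column reported as p = 1")
    } else {
      res[, ct] <- log10(fisher_enrichment(set, universe, annotation))
    }
  }
  ahr_set <- fit_ahr$gene_ids[fit_ahr$q[, "AHR"] < q_threshold]
  ahr_set <- intersect(ahr_set, universe)
  sizes["AHR"] <- length(ahr_set)
  if (length(ahr_set) == 0) {
    warning("AHR contrast has no DE genes; column reported as p = 1")
  } else {
    res[, "AHR"] <- log10(fisher_enrichment(ahr_set, universe, annotation))
  }
  attr(res, "set_sizes") <- sizes
  res
}
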