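#' Place a gene set on the genome
#'
#' Orders the queried genes by chromosome then start coordinate, carrying
#' strand and an optional direction-of-change tag (e.g. up/down). Genes
#' absent from the locus table are skipped and counted.
#'
#' @param genes character vector of gene ids.
#' @param loci locus table from \code{\link{read_loci}}.
#' @param direction optional named vector (by gene id) of change tags.
#' @return data.frame ordered by (chromosome, start) with attribute
#'   \code{n_skipped}.
#' @export
map_gene_set <- function(genes, loci, direction = NULL) {
  found <- loci[loci$gene_id %in% genes, , drop = FALSE]
  n_skipped <- length(setdiff(genes, loci$gene_id))
  if (n_skipped > 0)
    message(n_skipped, " gene(s) without locus information skipped")
  found <- found[order(found$chromosome, found$start), , drop = FALSE]
  found$direction <- if (!is.null(direction))
    unname(direction[found$gene_id]) else
      rep(NA_character_, nrow(found))
  rownames(found) <- NULL
  attr(found, "n_skipped") <- n_skipped
  found
}

#' Sliding-window hotspot scan for genomic clustering of a gene set
#'
#' Slides windows along every chromosome (half-window step), counts set
#' genes per window, and compares against \code{n_perm} random same-size
#' gene sets drawn from the universe. Empirical p per window uses the
#' add-one estimator; q is BH across windows. Quantifies whether a gene
#' set is concentrated into genomic "islands".
#'
#' @param genes the gene set.
#' @param universe background genes (all must have loci to count).
#' @param loci locus table.
#' @param window_size window width in bp (default 5e6).
#' @param n_perm number of random sets (default 1000).
#' @param seed integer seed.
#' @return data.frame of windows (chromosome, start, end, n_set,
#'   n_universe, p, q), BED-like ordering.
#' @export
hotspot_scan <- function(genes, universe, loci, window_size = 5e6,
                         n_perm = 1000, seed = 1L) {
  if (window_size <= 0) stop("window_size must be positive")
  set.seed(child_seed(seed, "hotspot"))
  loci <- loci[loci$gene_id %in% universe, , drop = FALSE]
  pos <- (loci$start + loci$end) / 2
  windows <- do.call(rbind, lapply(split(seq_len(nrow(loci)),
                                         loci$chromosome), function(ii) {
    lo <- min(pos[ii])
    hi <- max(pos[ii])
    starts <- seq(lo, max(lo, hi - window_size / 2), by = window_size / 2)
    data.frame(chromosome = loci$chromosome[ii[1L]], start = starts,
               end = starts + window_size, stringsAsFactors = FALSE)
  }))
  rownames(windows) <- NULL
  in_window <- function(members) {
    sel <- loci$gene_id %in% members
    vapply(seq_len(nrow(windows)), function(w)
      sum(sel & loci$chromosome == windows$chromosome[w] &
            pos >= windows$start[w] & pos < windows$end[w]), 0L)
  }
  # precompute per-window gene index lists for fast permutation counting
  win_members <- lapply(seq_len(nrow(windows)), function(w)
    which(loci$chromosome == windows$chromosome[w] &
            pos >= windows$start[w] & pos < windows$end[w]))
  n_set <- length(intersect(genes, loci$gene_id))
  sel_obs <- loci$gene_id %in% genes
  obs <- vapply(win_members, function(ii) sum(sel_obs[ii]), 0L)
  exceed <- integer(nrow(windows))
  for (b in seq_len(n_perm)) {
    rnd <- logical(nrow(loci))
    rnd[sample.int(nrow(loci), n_set)] <- TRUE
    cnt <- vapply(win_members, function(ii) sum(rnd[ii]), 0L)
    exceed <- exceed + (cnt >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(windows,
             n_set = obs,
             n_universe = lengths(win_members),
             p = p, q = adjust_fdr(p),
             stringsAsFactors = FALSE)
}
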