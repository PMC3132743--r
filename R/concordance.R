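#' Normalized expression from qPCR threshold cycles
#'
#' NE = 2^-(ddCt) with ddCt = (Ct_target - Ct_reference) - calibrator_dCt:
#' expression of the target gene relative to a reference gene, relative to
#' a calibrator condition. Monotone decreasing in Ct_target and increasing
#' in Ct_reference.
#'
#' @param Ct_target,Ct_reference threshold cycles (finite).
#' @param calibrator_dCt calibrator delta-Ct (default 0).
#' @return normalized expression (dimensionless, > 0).
#' @export
ddct <- function(Ct_target, Ct_reference, calibrator_dCt = 0) {
  stopifnot(all(is.finite(Ct_target)), all(is.finite(Ct_reference)),
            all(is.finite(calibrator_dCt)))
  2^-((Ct_target - Ct_reference) - calibrator_dCt)
}

#' Summarize a qPCR table into per-strain normalized expression
#'
#' Computes delta-Ct per measurement and normalized expression against a
#' calibrator, defaulting to the mean delta-Ct of a designated reference
#' strain for each gene.
#'
#' @param pcr data.frame with columns \code{gene}, \code{sample},
#'   \code{strain}, \code{Ct_target}, \code{Ct_reference}.
#' @param calibrator_strain strain whose mean delta-Ct calibrates each
#'   gene (default: first strain in the table).
#' @return the input with added \code{dCt} and \code{NE} columns.
#' @export
pcr_normalize <- function(pcr, calibrator_strain = NULL) {
  need <- c("gene", "sample", "strain", "Ct_target", "Ct_reference")
  stopifnot(all(need %in% names(pcr)))
  if (any(pcr$Ct_target <= 0) || any(pcr$Ct_reference <= 0))
    stop("threshold cycles must be positive")
  if (is.null(calibrator_strain)) calibrator_strain <- pcr$strain[1L]
  pcr$dCt <- pcr$Ct_target - pcr$Ct_reference
  cal <- tapply(pcr$dCt[pcr$strain == calibrator_strain],
                pcr$gene[pcr$strain == calibrator_strain], mean)
  pcr$NE <- ddct(pcr$Ct_target, pcr$Ct_reference,
                 calibrator_dCt = unname(cal[pcr$gene]))
  pcr
}

#' Pairwise Welch t-tests between strains
#'
#' Two-tailed t-tests with Welch's adjustment for heteroscedasticity for
#' every unordered pair of strains.
#'
#' @param values_by_strain named list of numeric vectors (>= 2 values
#'   each).
#' @return data.frame with columns \code{strain_a}, \code{strain_b},
#'   \code{t}, \code{df}, \code{p}, \code{log2_fc} (difference of group
#'   means of log2 values, a - b).
#' @export
welch_pairwise <- function(values_by_strain) {
  stopifnot(is.list(values_by_strain), length(values_by_strain) >= 2,
            all(lengths(values_by_strain) >= 2))
  strains <- names(values_by_strain)
  pairs <- utils::combn(length(strains), 2)
  out <- data.frame(strain_a = strains[pairs[1, ]],
                    strain_b = strains[pairs[2, ]],
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    log2_fc = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- values_by_strain[[pairs[1, j]]]
    b <- values_by_strain[[pairs[2, j]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: identical-variance-free groups; report t from the
      # mean difference (0 -> t = 0, p = 1)
      d <- mean(a) - mean(b)
      out$t[j] <- if (d == 0) 0 else sign(d) * Inf
      out$df[j] <- length(a) + length(b) - 2
      out$p[j] <- if (d == 0) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      out$t[j] <- unname(tt$statistic)
      out$df[j] <- unname(tt$parameter)
      out$p[j] <- tt$p.value
    }
    out$log2_fc[j] <- mean(a) - mean(b)
  }
  out
}

#' Array vs qPCR fold-change concordance
#'
#' Pearson correlation (with two-sided p) of paired log2 fold changes
#' measured on the two platforms.
#'
#' @param fc_array,fc_pcr numeric log2 fold changes paired by
#'   (gene, strain pair); length >= 3.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
platform_concordance <- function(fc_array, fc_pcr) {
  stopifnot(length(fc_array) == length(fc_pcr), length(fc_array) >= 3)
  if (stats::sd(fc_array) == 0 || stats::sd(fc_pcr) == 0)
    stop("constant fold-change vector")
  ct <- stats::cor.test(fc_array, fc_pcr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(fc_array))
}

#' Collapse a per-gene statistic through a homolog map
#'
#' Pairs each mouse gene with the statistic of its rat homolog(s),
#' collapsing multi-matches by the requested mode. Unmatched genes are
#' dropped and counted.
#'
#' @param stat_by_gene named numeric vector (by rat gene).
#' @param homolog_map data.frame with columns \code{rat_gene},
#'   \code{mouse_gene}.
#' @param mode \code{"none"} (keep every match as its own row),
#'   \code{"mean"}, \code{"min"} or \code{"max"}.
#' @return data.frame with columns \code{mouse_gene}, \code{stat};
#'   attribute \code{n_dropped} counts map rows whose rat gene lacks a
#'   statistic.
#' @export
homolog_aggregate <- function(stat_by_gene, homolog_map,
                              mode = c("none", "mean", "min", "max")) {
  mode <- match.arg(mode)
  hm <- homolog_map[homolog_map$rat_gene %in% names(stat_by_gene), ,
                    drop = FALSE]
  n_dropped <- nrow(homolog_map) - nrow(hm)
  if (n_dropped > 0)
    message(n_dropped, " homolog pair(s) without statistics dropped")
  stat <- stat_by_gene[hm$rat_gene]
  out <- if (mode == "none") {
    data.frame(mouse_gene = hm$mouse_gene, stat = unname(stat),
               stringsAsFactors = FALSE)
  } else {
    f <- switch(mode, mean = mean, min = min, max = max)
    agg <- tapply(stat, hm$mouse_gene, f)
    data.frame(mouse_gene = names(agg), stat = unname(agg),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Cross-species rank correlation of strain-variability statistics
#'
#' Spearman's rho with tie-corrected p between paired per-gene statistics
#' from the two species.
#'
#' @param x,y paired numeric vectors (length >= 5), e.g. rat p-values and
#'   mouse q-values for inter-strain variability.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
cross_species_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare per-group log2 F statistics against all genes
#'
#' For externally defined gene groups (e.g. diet-, gender- and
#' strain-dependent sets from another tissue), summarizes log2-transformed
#' F statistics per group and Welch-tests each group against the full
#' universe. Genes with multiple statistics should be pre-averaged via
#' \code{\link{homolog_aggregate}}.
#'
#' @param f_stats named numeric vector of F statistics (by gene).
#' @param group_assignments named list of gene-id vectors; a group
#'   \code{"All"} covering every gene is added automatically.
#' @return data.frame with per-group quartiles of log2 F, group size, and
#'   Welch p vs all genes.
#' @export
cross_tissue_compare <- function(f_stats, group_assignments) {
  stopifnot(length(f_stats) > 0, !is.null(names(f_stats)))
  if (any(lengths(group_assignments) == 0)) stop("empty group")
  groups <- c(list(All = names(f_stats)), group_assignments)
  lf_all <- log2(f_stats)
  out <- lapply(names(groups), function(g) {
    genes <- intersect(groups[[g]], names(f_stats))
    if (length(genes) == 0) stop("group '", g, "' shares no genes with ",
                                 "the statistic vector")
    lf <- lf_all[genes]
    qs <- stats::quantile(lf, c(0.25, 0.5, 0.75))
    p <- if (g == "All") 1 else
      stats::t.test(lf, lf_all, var.equal = FALSE)$p.value
    data.frame(group = g, n = length(lf), q25 = qs[[1]], median = qs[[2]],
               q75 = qs[[3]], p_vs_all = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
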