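#' Parental-interval distance for a cross line
#'
#' d = (Y_test - Y_low) / (Y_high - Y_low), where Y_high and Y_low are the
#' higher- and lower-expressing parental strains. d = 0 means the line
#' matches the lower parent, d = 1 the higher parent; d outside [0, 1]
#' means the line lies outside the parental interval. Affine-invariant:
#' shifting or positively rescaling all three inputs leaves d unchanged.
#'
#' @param Y_test,Y_high,Y_low numeric signal intensities (vectorized).
#' @return numeric distances; \code{NA} where \code{Y_high == Y_low}
#'   (undefined, flagged not tested).
#' @export
heritability_distance <- function(Y_test, Y_high, Y_low) {
  span <- Y_high - Y_low
  ifelse(span == 0, NA_real_, (Y_test - Y_low) / span)
}

#' Per-gene strain means
#' @param X an \code{ExpressionMatrix}.
#' @return genes x strains matrix of means.
#' @export
strain_means <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  strain <- factor(X$samples$strain)
  n_i <- as.vector(table(strain))
  Z <- stats::model.matrix(~ strain - 1)
  gm <- X$values %*% Z %*% diag(1 / n_i, nlevels(strain))
  colnames(gm) <- levels(strain)
  gm
}

#' Distance profile of the cross lines over the parental interval
#'
#' For genes with significant parental differential expression (the gate:
#' adjusted p below \code{q_threshold} on the parent_a vs parent_b
#' contrast), computes each line's parental-interval distance from strain
#' mean intensities, splits genes by parental direction, and fits Gaussian
#' kernel densities (Silverman's rule-of-thumb bandwidth) per line and
#' direction.
#'
#' @param X an \code{ExpressionMatrix}.
#' @param fit a \code{ModeratedFit} with pairwise contrasts fitted on
#'   \code{X} (the gate).
#' @param parent_a,parent_b parental strain names (default LE, HW).
#' @param lines cross-line names (default LnA, LnC).
#' @param q_threshold gate threshold on the adjusted p (default 0.05).
#' @param bandwidth optional KDE bandwidth override (log2 units).
#' @return list with \code{records} (data.frame: gene_id, direction,
#'   d_<line> columns) and \code{densities} (list of
#'   \code{stats::density} objects keyed by "<line>.<direction>").
#' @export
distance_profile <- function(X, fit, parent_a = "LE", parent_b = "HW",
                             lines = c("LnA", "LnC"), q_threshold = 0.05,
                             bandwidth = NULL) {
  stopifnot(inherits(fit, "ModeratedFit"))
  ct <- paste(parent_a, parent_b, sep = "-")
  if (!ct %in% colnames(fit$q))
    ct <- paste(parent_b, parent_a, sep = "-")
  if (!ct %in% colnames(fit$q))
    stop("fit lacks the ", parent_a, " vs ", parent_b, " contrast")
  gate <- fit$q[, ct] < q_threshold
  if (!any(gate)) stop("no genes pass the parental differential-",
                       "expression gate at q < ", q_threshold)
  gm <- strain_means(X)[gate, , drop = FALSE]
  a <- gm[, parent_a]
  b <- gm[, parent_b]
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  direction <- ifelse(a > b, paste0(parent_a, ">", parent_b),
                      paste0(parent_b, ">", parent_a))
  rec <- data.frame(gene_id = rownames(gm), direction = direction,
                    stringsAsFactors = FALSE)
  for (ln in lines)
    rec[[paste0("d_", ln)]] <- heritability_distance(gm[, ln], hi, lo)
  densities <- list()
  for (ln in lines) {
    for (dir in unique(direction)) {
      d <- rec[rec$direction == dir, paste0("d_", ln)]
      d <- d[is.finite(d)]
      if (length(d) >= 2) {
        bw <- if (is.null(bandwidth)) stats::bw.nrd0(d) else bandwidth
        densities[[paste0(ln, ".", dir)]] <-
          stats::density(d, bw = bw, kernel = "gaussian")
      }
    }
  }
  list(records = rec, densities = densities, contrast = ct,
       q_threshold = q_threshold)
}

#' Identify interacting loci
#'
#' A gene x line pair is called interacting when the line differs
#' significantly (adjusted p below \code{q_threshold}) from both parental
#' strains with the same coefficient sign, i.e. the line's expression lies
#' outside both parents. Genes called in both lines are flagged.
#'
#' @param fit a \code{ModeratedFit} with pairwise contrasts including each
#'   line vs each parent.
#' @param parent_a,parent_b parental strain names.
#' @param lines cross-line names.
#' @param q_threshold significance threshold (default 0.05).
#' @return data.frame with columns \code{gene_id}, \code{line},
#'   \code{direction} (above/below), \code{q_vs_a}, \code{q_vs_b},
#'   \code{both_lines}.
#' @export
find_interacting_loci <- function(fit, parent_a = "LE", parent_b = "HW",
                                  lines = c("LnA", "LnC"),
                                  q_threshold = 0.05) {
  stopifnot(inherits(fit, "ModeratedFit"), !is.null(fit$q))
  get_ct <- function(x, y) {
    ct <- paste(x, y, sep = "-")
    if (ct %in% colnames(fit$q)) return(list(name = ct, sign = 1))
    ct <- paste(y, x, sep = "-")
    if (ct %in% colnames(fit$q)) return(list(name = ct, sign = -1))
    stop("fit lacks the ", x, " vs ", y, " contrast")
  }
  out <- list()
  for (ln in lines) {
    ca <- get_ct(ln, parent_a)
    cb <- get_ct(ln, parent_b)
    # M for line - parent, with sign corrected for contrast orientation
    Ma <- ca$sign * fit$M[, ca$name]
    Mb <- cb$sign * fit$M[, cb$name]
    qa <- fit$q[, ca$name]
    qb <- fit$q[, cb$name]
    hit <- qa < q_threshold & qb < q_threshold & sign(Ma) == sign(Mb) &
      Ma != 0
    if (any(hit))
      out[[ln]] <- data.frame(gene_id = fit$gene_ids[hit], line = ln,
                              direction = ifelse(Ma[hit] > 0, "above",
                                                 "below"),
                              q_vs_a = qa[hit], q_vs_b = qb[hit],
                              stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(gene_id = character(0), line = character(0),
               direction = character(0), q_vs_a = numeric(0),
               q_vs_b = numeric(0))
  rownames(res) <- NULL
  res$both_lines <- res$gene_id %in%
    res$gene_id[duplicated(res$gene_id)]
  res
}
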