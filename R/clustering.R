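#' Filter genes by across-sample variance
#'
#' Keeps genes whose variance across all samples is strictly above the
#' threshold (default 0.25).
#'
#' @param X an \code{ExpressionMatrix}.
#' @param threshold non-negative variance threshold.
#' @return character vector of gene ids.
#' @export
variance_filter <- function(X, threshold = 0.25) {
  stopifnot(inherits(X, "ExpressionMatrix"), threshold >= 0)
  v <- apply(X$values, 1L, stats::var)
  rownames(X$values)[v > threshold]
}

#' Filter genes by the overall moderated F statistic
#'
#' Keeps genes with overall-F p-value below the threshold (default 0.001),
#' the linear-model analogue of the variance filter.
#'
#' @param fit a \code{ModeratedFit} with contrasts.
#' @param p_threshold raw p-value threshold.
#' @return character vector of gene ids.
#' @export
f_statistic_filter <- function(fit, p_threshold = 0.001) {
  stopifnot(inherits(fit, "ModeratedFit"), !is.null(fit$F_p))
  fit$gene_ids[fit$F_p < p_threshold]
}

#' Mean-center and root-mean-square scale rows
#'
#' Per gene: subtract the mean, then divide by the root mean square of the
#' centered values, so each row has mean 0 and RMS 1.
#'
#' @param M numeric matrix (genes x samples); constant rows are an error.
#' @return standardized matrix.
#' @export
center_scale <- function(M) {
  M <- as.matrix(M)
  ctr <- M - rowMeans(M)
  rms <- sqrt(rowMeans(ctr^2))
  if (any(rms == 0)) {
    bad <- rownames(M)[rms == 0]
    stop("constant row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  ctr / rms
}

#' Pearson correlation distance
#'
#' distance = 1 - r, ranging over [0, 2].
#'
#' @param A numeric matrix whose \emph{rows} are the items to compare, or
#'   a vector (with \code{B}).
#' @param B optional second vector.
#' @return distance matrix (as \code{dist}) or a single distance.
#' @export
correlation_distance <- function(A, B = NULL) {
  if (!is.null(B)) {
    stopifnot(length(A) == length(B), length(A) >= 3)
    if (stats::sd(A) == 0 || stats::sd(B) == 0)
      stop("constant vector")
    return(1 - stats::cor(A, B))
  }
  A <- as.matrix(A)
  if (ncol(A) < 3) stop("need vectors of length >= 3")
  if (any(apply(A, 1L, stats::sd) == 0)) stop("constant vector")
  stats::as.dist(1 - stats::cor(t(A)))
}

#' Divisive hierarchical clustering (DIANA)
#'
#' Classical divisive analysis: start with all items in one cluster;
#' repeatedly split the cluster of largest diameter by seeding a splinter
#' group with the item of maximal average dissimilarity and migrating
#' items whose average dissimilarity to the splinter is smaller than to
#' the remainder. Deterministic given the matrix; ties are broken by the
#' lowest item index.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @return object of class \code{diana_tree}: a recursive binary tree;
#'   each internal node has \code{left}, \code{right}, \code{diameter};
#'   leaves hold item indices. Also carries \code{labels} and the split
#'   order.
#' @export
diana <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("distance matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  diam <- function(idx) if (length(idx) < 2) 0 else
    max(D[idx, idx, drop = FALSE])

  split_cluster <- function(idx) {
    # seed the splinter with the item of maximal average dissimilarity
    avg_all <- rowMeans(D[idx, idx, drop = FALSE]) * length(idx) /
      (length(idx) - 1)
    seed <- idx[which.max(avg_all)]           # which.max: lowest index wins
    splinter <- seed
    rest <- setdiff(idx, seed)
    repeat {
      if (length(rest) <= 1) break
      avg_rest <- vapply(rest, function(i) {
        others <- setdiff(rest, i)
        mean(D[i, others])
      }, 0)
      avg_spl <- vapply(rest, function(i) mean(D[i, splinter]), 0)
      gain <- avg_rest - avg_spl
      best <- which.max(gain)
      if (gain[best] <= 0) break
      splinter <- c(splinter, rest[best])
      rest <- setdiff(rest, rest[best])
    }
    list(splinter = sort(splinter), rest = sort(rest))
  }

  build <- function(idx) {
    if (length(idx) == 1) return(list(leaf = idx))
    sp <- split_cluster(idx)
    list(diameter = diam(idx),
         left = build(sp$splinter),
         right = build(sp$rest))
  }
  tree <- build(seq_len(n))
  structure(list(tree = tree, labels = labels, n = n, dist = D),
            class = "diana_tree")
}

#' @export
print.diana_tree <- function(x, ...) {
  cat("DIANA divisive clustering over", x$n, "items\n")
  invisible(x)
}

tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Cut a DIANA tree into k clusters
#'
#' Performs splits divisively in decreasing order of diameter until k
#' clusters remain, matching the top-down semantics of the algorithm.
#'
#' @param tree a \code{diana_tree}.
#' @param k number of clusters.
#' @return integer cluster assignments named by item label.
#' @export
cut_diana <- function(tree, k) {
  stopifnot(inherits(tree, "diana_tree"), k >= 1, k <= tree$n)
  active <- list(tree$tree)
  while (length(active) < k) {
    diams <- vapply(active, function(nd)
      if (!is.null(nd$leaf)) -Inf else nd$diameter, 0)
    j <- which.max(diams)
    nd <- active[[j]]
    active <- c(active[-j], list(nd$left), list(nd$right))
  }
  out <- integer(tree$n)
  for (i in seq_along(active)) out[tree_leaves(active[[i]])] <- i
  names(out) <- tree$labels
  out
}

#' Export a DIANA tree as a Newick string
#'
#' Branch support values are split diameters.
#'
#' @param tree a \code{diana_tree}.
#' @return single Newick string terminated by ';'.
#' @export
diana_newick <- function(tree) {
  stopifnot(inherits(tree, "diana_tree"))
  rec <- function(node) {
    if (!is.null(node$leaf)) return(tree$labels[node$leaf])
    paste0("(", rec(node$left), ",", rec(node$right), ")")
  }
  paste0(rec(tree$tree), ";")
}

#' Agreement between a tree cut and known labels
#'
#' Cuts the tree into k clusters and scores the adjusted Rand index
#' against the given labels.
#'
#' @param tree a \code{diana_tree}.
#' @param k number of clusters.
#' @param labels reference labels, one per item.
#' @return adjusted Rand index (0 for k = 1).
#' @export
cluster_agreement <- function(tree, k, labels) {
  stopifnot(length(labels) == tree$n)
  if (k == 1) return(0)
  cl <- cut_diana(tree, k)
  mclust::adjustedRandIndex(cl, labels)
}

#' Cluster samples on filtered, standardized genes
#'
#' The Fig-1-style workflow: filter genes (variance or F-statistic),
#' mean-center and RMS-scale each gene, then cluster \emph{samples} by
#' DIANA on Pearson correlation distance over the gene profiles. Set
#' \code{items = "genes"} to cluster genes instead.
#'
#' @param X an \code{ExpressionMatrix}.
#' @param genes gene ids to use (e.g. from \code{\link{variance_filter}}).
#' @param items cluster \code{"samples"} (default) or \code{"genes"}.
#' @return a \code{diana_tree}.
#' @export
cluster_samples <- function(X, genes, items = c("samples", "genes")) {
  items <- match.arg(items)
  M <- center_scale(X$values[genes, , drop = FALSE])
  if (items == "samples") M <- t(M)
  diana(correlation_distance(M))
}
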