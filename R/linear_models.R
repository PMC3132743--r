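#' Build a design matrix from sample metadata
#'
#' Two codings are supported. \code{simple}: one indicator column per
#' strain/line (cell-means, no intercept), so contrasts are direct mean
#' differences. \code{ancestry_ahr}: one column per parental strain holding
#' the sample's ancestry proportions plus an AHR column holding the
#' variant-receptor indicator; crossbred samples carry 0.5/0.5 parental
#' coefficients.
#'
#' @param samples data.frame of sample metadata (from an
#'   \code{ExpressionMatrix}).
#' @param model_kind \code{"simple"} or \code{"ancestry_ahr"}.
#' @param ancestry samples x parental-strain proportion matrix; required
#'   for \code{ancestry_ahr} (taken from the \code{ExpressionMatrix} by
#'   \code{\link{fit_genewise}}).
#' @return numeric design matrix with named coefficient columns and
#'   attribute \code{model_kind}.
#' @export
build_design <- function(samples, model_kind = c("simple", "ancestry_ahr"),
                         ancestry = NULL) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "simple") {
    strain <- factor(samples$strain)
    D <- stats::model.matrix(~ strain - 1)
    colnames(D) <- levels(strain)
  } else {
    if (is.null(ancestry)) stop("ancestry matrix required for ancestry_ahr")
    keep <- colnames(ancestry)[colSums(ancestry) > 0]
    D <- cbind(ancestry[, keep, drop = FALSE],
               AHR = as.numeric(samples$ahr_variant))
  }
  rownames(D) <- samples$sample_id
  if (qr(D)$rank < ncol(D))
    stop("design matrix is rank-deficient for model '", model_kind,
         "' with the populations present")
  attr(D, "model_kind") <- model_kind
  D
}

#' All pairwise contrasts between strains
#'
#' One column per unordered pair (+1/-1), k(k-1)/2 columns for k strains;
#' column names are \code{"A-B"}.
#'
#' @param strains character vector of strain names (design columns).
#' @return contrast matrix, strains x pairs.
#' @export
pairwise_contrast_matrix <- function(strains) {
  k <- length(strains)
  if (k < 2) stop("need at least 2 strains")
  pairs <- utils::combn(k, 2)
  C <- matrix(0, nrow = k, ncol = ncol(pairs),
              dimnames = list(strains, paste(strains[pairs[1, ]],
                                             strains[pairs[2, ]],
                                             sep = "-")))
  for (j in seq_len(ncol(pairs))) {
    C[pairs[1, j], j] <- 1
    C[pairs[2, j], j] <- -1
  }
  C
}

#' Genewise ordinary least squares
#'
#' Fits every gene against the same design by the normal equations,
#' vectorized across genes.
#'
#' @param X an \code{ExpressionMatrix}.
#' @param design design matrix from \code{\link{build_design}}, or a
#'   \code{model_kind} string to build one from \code{X}'s metadata.
#' @return list of class \code{GenewiseFit} with per-gene coefficients,
#'   residual variance \code{s2}, residual df, average intensity \code{A},
#'   and the design's \code{xtxi} = (X'X)^-1.
#' @export
fit_genewise <- function(X, design = "simple") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.character(design))
    design <- build_design(X$samples, design, ancestry = X$ancestry)
  Y <- X$values
  if (nrow(design) != ncol(Y)) stop("design rows do not match samples")
  if (anyNA(Y) || any(!is.finite(Y))) stop("non-finite expression values")
  n <- ncol(Y)
  p <- ncol(design)
  df_resid <- n - p
  if (df_resid < 1) stop("no residual degrees of freedom")
  xtx <- crossprod(design)
  xtxi <- solve(xtx)
  coef <- Y %*% design %*% xtxi        # genes x p
  fitted <- coef %*% t(design)
  s2 <- rowSums((Y - fitted)^2) / df_resid
  structure(list(coefficients = coef, s2 = s2, df_resid = df_resid,
                 A = rowMeans(Y), design = design, xtxi = xtxi,
                 gene_ids = rownames(Y),
                 model_kind = attr(design, "model_kind")),
            class = "GenewiseFit")
}

# Invert trigamma: find x > 0 with trigamma(x) = y, by Newton iteration on
# the reciprocal scale (trigamma is convex decreasing; 1/trigamma is nearly
# linear). Tolerance 1e-8.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderation of genewise variances
#'
#' Shrinks each gene's residual variance toward an ensemble prior. The
#' prior (d0, s0^2) is estimated by matching the first two moments of
#' log s2 to the scaled-F prior predictive: with z = log s2,
#' E z = log s0^2 + digamma(d0/2) - log(d0/2) - (digamma(d/2) - log(d/2))
#' and Var z = trigamma(d/2) + trigamma(d0/2), solved by trigamma
#' inversion. The posterior variance is
#' s~2 = (d0 s0^2 + d s2) / (d0 + d), used with d0 + d degrees of freedom.
#'
#' @param fit a \code{GenewiseFit} over at least 50 genes.
#' @param contrasts optional contrast matrix (coefficients x contrasts);
#'   when supplied, per-contrast M (log2 difference), moderated t, p, q,
#'   and an overall moderated F with p and q are computed.
#' @return list of class \code{ModeratedFit} extending the fit with
#'   \code{d0}, \code{s02}, \code{s2_post}, and, per contrast, matrices
#'   \code{M}, \code{t}, \code{p}, \code{q}, plus \code{F}, \code{F_p},
#'   \code{F_q} when contrasts span >= 1 dimension.
#' @export
moderate <- function(fit, contrasts = NULL) {
  stopifnot(inherits(fit, "GenewiseFit"))
  G <- length(fit$s2)
  if (G < 50) stop("hyperparameter estimation needs >= 50 genes")
  d <- fit$df_resid
  s2 <- pmax(fit$s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  v <- stats::var(e) - trigamma(d / 2)
  if (v > 0) {
    d0 <- 2 * trigamma_inverse(v)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else if (stats::var(z) < 1e-12) {
    # degenerate input: literally identical variances; shrink fully to
    # the common value
    d0 <- Inf
    s02 <- exp(mean(z))
  } else {
    # dispersion at or below the chi-square sampling baseline: infinite
    # prior df; exp(ebar) corrects the log-chi-square bias of log s2
    d0 <- Inf
    s02 <- exp(ebar)
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else
    rep(s02, G)
  out <- c(unclass(fit),
           list(d0 = d0, s02 = s02, s2_post = s2_post,
                df_total = d0 + d))
  if (!is.null(contrasts)) {
    C <- as.matrix(contrasts)
    if (nrow(C) != ncol(fit$coefficients))
      stop("contrast rows do not match coefficients")
    M <- fit$coefficients %*% C
    cvar <- t(C) %*% fit$xtxi %*% C         # unscaled contrast covariance
    se_unscaled <- sqrt(pmax(diag(cvar), 0))
    tt <- sweep(M, 2L, se_unscaled, "/") / sqrt(s2_post)
    df_t <- d0 + d    # Inf prior df gives the normal / chi-square limit
    p <- 2 * stats::pt(abs(tt), df = df_t, lower.tail = FALSE)
    q <- apply(p, 2L, adjust_fdr)
    out$M <- M
    out$t <- tt
    out$p <- p
    out$q <- matrix(q, nrow = G, dimnames = dimnames(p))
    # overall moderated F over the contrast space (rank r)
    ev <- eigen(cvar, symmetric = TRUE)
    r <- sum(ev$values > max(ev$values) * 1e-10)
    Q <- ev$vectors[, seq_len(r), drop = FALSE] %*%
      diag(1 / sqrt(ev$values[seq_len(r)]), r)
    U <- M %*% Q
    Fstat <- rowSums(U^2) / (r * s2_post)
    F_p <- stats::pf(Fstat, df1 = r, df2 = df_t, lower.tail = FALSE)
    out$F <- Fstat
    out$F_p <- F_p
    out$F_q <- adjust_fdr(F_p)
    out$contrast_rank <- r
  }
  structure(out, class = c("ModeratedFit", "GenewiseFit"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with monotonicity enforcement, as implemented in
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Fit the simple model with all pairwise contrasts and moderation
#'
#' Convenience wrapper: cell-means fit, all k(k-1)/2 pairwise contrasts,
#' empirical-Bayes moderation, BH adjustment per contrast, and the overall
#' moderated F (a proxy for inter-strain variability).
#'
#' @param X an \code{ExpressionMatrix}.
#' @return a \code{ModeratedFit}.
#' @export
fit_simple_pairwise <- function(X) {
  fit <- fit_genewise(X, "simple")
  C <- pairwise_contrast_matrix(colnames(fit$design))
  moderate(fit, C)
}

#' Fit the ancestry + AHR model with moderation
#'
#' Parental-ancestry proportions set the strain coefficients and a 0/1
#' indicator carries the variant-AHR effect; the AHR coefficient is the
#' contrast of interest.
#'
#' @param X an \code{ExpressionMatrix}.
#' @return a \code{ModeratedFit} with a single \code{AHR} contrast.
#' @export
fit_ancestry_ahr <- function(X) {
  fit <- fit_genewise(X, "ancestry_ahr")
  p <- ncol(fit$coefficients)
  C <- matrix(0, nrow = p, ncol = 1,
              dimnames = list(colnames(fit$coefficients), "AHR"))
  C["AHR", 1] <- 1
  moderate(fit, C)
}

#' Sensitivity of pairwise DE counts to the significance threshold
#'
#' Counts, for every pairwise contrast, the genes significant below each
#' threshold on a log-spaced grid (default 1e-1 .. 1e-7), on both the
#' adjusted (q) and raw (p) scale.
#'
#' @param fit a \code{ModeratedFit} with pairwise contrasts.
#' @param thresholds numeric vector of thresholds.
#' @return data.frame with columns \code{contrast}, \code{threshold},
#'   \code{n_q} (count at q < threshold), \code{n_p} (count at p <
#'   threshold).
#' @export
threshold_sensitivity <- function(fit, thresholds = 10^-(1:7)) {
  stopifnot(inherits(fit, "ModeratedFit"), !is.null(fit$q))
  out <- expand.grid(contrast = colnames(fit$q), threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$n_q <- mapply(function(ct, th) sum(fit$q[, ct] < th),
                    out$contrast, out$threshold)
  out$n_p <- mapply(function(ct, th) sum(fit$p[, ct] < th),
                    out$contrast, out$threshold)
  out
}

#' Table of genes with AHR-dependent expression
#'
#' @param fit a \code{ModeratedFit} from \code{\link{fit_ancestry_ahr}}.
#' @param q_threshold keep genes with AHR q below this value (default
#'   0.05); counts at 0.001, 0.01 and 0.05 are attached as attribute
#'   \code{fdr_counts}.
#' @return data.frame sorted by q with columns \code{gene_id}, \code{M},
#'   \code{t}, \code{p}, \code{q}, \code{fold_change}, \code{direction}.
#' @export
ahr_effect_table <- function(fit, q_threshold = 0.05) {
  stopifnot(inherits(fit, "ModeratedFit"))
  if (is.null(fit$M) || !"AHR" %in% colnames(fit$M))
    stop("fit lacks an AHR contrast")
  M <- fit$M[, "AHR"]
  tab <- data.frame(gene_id = fit$gene_ids, M = M, t = fit$t[, "AHR"],
                    p = fit$p[, "AHR"], q = fit$q[, "AHR"],
                    stringsAsFactors = FALSE)
  fc <- m_to_fold_change(M)
  tab$fold_change <- fc$fold
  tab$direction <- fc$direction
  tab <- tab[order(tab$q, tab$p), , drop = FALSE]
  counts <- vapply(c(0.001, 0.01, 0.05), function(th) sum(tab$q < th), 0L)
  names(counts) <- c("0.001", "0.01", "0.05")
  res <- tab[tab$q < q_threshold, , drop = FALSE]
  attr(res, "fdr_counts") <- counts
  res
}

#' Convert a log2 M-value to a fold change with direction
#'
#' An M-value of -2.9 is a 7.5-fold repression; positive M is induction.
#'
#' @param M numeric log2 differences.
#' @return list with \code{fold} = 2^|M| and \code{direction} in
#'   \{repression, induction, none\}.
#' @export
m_to_fold_change <- function(M) {
  stopifnot(all(is.finite(M)))
  list(fold = 2^abs(M),
       direction = ifelse(M < 0, "repression",
                          ifelse(M > 0, "induction", "none")))
}
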