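#' Partition per-gene variance into within- and between-strain components
#'
#' One-way random-effects ANOVA estimators, method of moments with zero
#' truncation: W is the pooled within-strain mean square; B = max(0,
#' (MSB - W) / n0), with n0 the replicate count for a balanced design or
#' its unbalanced analogue (N - sum(n_i^2)/N) / (k - 1). The W/T ratio
#' (T = W + B) measures how much of a gene's variability is
#' within-strain (1 = all within, 0 = all between). Constant genes and
#' genes where truncation fires report ratio 1.
#'
#' @param X an \code{ExpressionMatrix} with >= 2 strains and >= 2
#'   replicates per strain.
#' @return data.frame with columns \code{gene_id}, \code{W}, \code{B},
#'   \code{T}, \code{ratio}, \code{mean_intensity}, \code{bin},
#'   \code{decile} and a logical \code{constant} flag.
#' @export
partition_variance <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  strain <- factor(X$samples$strain)
  k <- nlevels(strain)
  if (k < 2) stop("need at least 2 strains")
  n_i <- as.vector(table(strain))
  if (any(n_i < 2))
    stop("strain(s) with fewer than 2 replicates: ",
         paste(levels(strain)[n_i < 2], collapse = ", "))
  Y <- X$values
  N <- ncol(Y)
  # group means via indicator algebra (vectorized across genes)
  Z <- stats::model.matrix(~ strain - 1)
  gm <- Y %*% Z %*% diag(1 / n_i, k)          # genes x strains means
  grand <- rowMeans(Y)
  ssw <- rowSums((Y - gm[, as.integer(strain), drop = FALSE])^2)
  ssb <- rowSums(sweep((gm - grand)^2, 2L, n_i, "*"))
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  B <- pmax(0, (msb - msw) / n0)
  W <- msw
  Tt <- W + B
  constant <- Tt < .Machine$double.eps
  ratio <- ifelse(constant, 1, W / Tt)
  ratio <- pmin(1, pmax(0, ratio))
  data.frame(gene_id = rownames(Y), W = W, B = B, T = Tt, ratio = ratio,
             mean_intensity = grand,
             bin = bin_by_intensity(grand),
             decile = decile_groups(ratio),
             constant = constant,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign expression bins by mean log2 intensity
#'
#' Boundaries: unexpressed below 4, low in [4, 8), medium in [8, 12),
#' high at 12 and above.
#'
#' @param mean_intensity numeric vector of finite means.
#' @return factor with levels unexpressed, low, medium, high.
#' @export
bin_by_intensity <- function(mean_intensity) {
  stopifnot(all(is.finite(mean_intensity)))
  cut(mean_intensity, breaks = c(-Inf, 4, 8, 12, Inf),
      labels = c("unexpressed", "low", "medium", "high"),
      right = FALSE)
}

#' Assign W/T ratios to ten equally spaced groups
#'
#' Group k covers [(k-1)/10, k/10), with the last group closed at 1.
#'
#' @param ratios numeric in [0, 1].
#' @return integer group labels 1..10.
#' @export
decile_groups <- function(ratios) {
  if (any(ratios < 0 | ratios > 1, na.rm = TRUE))
    stop("ratios must lie in [0, 1]")
  g <- pmin(floor(ratios * 10) + 1L, 10L)
  as.integer(g)
}

#' Write a variance-partition table to TSV
#' @param vp data.frame from \code{\link{partition_variance}}.
#' @param path output path.
#' @param header optional named character vector written as '# key: value'
#'   comment lines.
#' @export
write_variance_table <- function(vp, path, header = NULL) {
  write_tsv_with_header(vp, path, header)
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    for (k in names(header))
      cat("# ", k, ": ", header[[k]], "\n", sep = "", file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
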