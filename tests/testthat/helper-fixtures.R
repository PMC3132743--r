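# Shared fixtures and independent helpers for the suite.

# A sharply peaked PWM of length L with a reproducible consensus:
# dominant base gets `peak` counts, the rest 1 each.
sharp_pwm <- function(L = 18, peak = 97, seed = 2) {
  withr::with_seed(seed, {
    cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    counts <- sapply(cons, function(b) {
      v <- rep(1, 4)
      names(v) <- c("A", "C", "G", "T")
      v[b] <- peak
      v
    })
    colnames(counts) <- NULL
    strainvar:::pwm_object("MX0001", paste0("SHARP", L), counts)
  })
}

# Reverse complement without touching package internals.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Does the DIANA tree place the two cross lines as sisters, i.e. the
# smallest node containing every LnA sample holds exactly the LnA + LnC
# samples (or a subset of cross samples)?
cross_lines_are_sisters <- function(tree, strains) {
  cross <- which(strains %in% c("LnA", "LnC"))
  find_min <- function(node) {
    if (!all(cross %in% strainvar:::tree_leaves(node))) return(NULL)
    l <- if (is.null(node$leaf)) find_min(node$left) else NULL
    r <- if (is.null(node$leaf)) find_min(node$right) else NULL
    if (!is.null(l)) l else if (!is.null(r)) r else
      strainvar:::tree_leaves(node)
  }
  setequal(find_min(tree$tree), cross)
}

# Independent one-way ANOVA variance components by explicit summation.
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  n_i <- tabulate(groups)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssw <- 0
  for (g in levels(groups))
    ssw <- ssw + sum((values[groups == g] - gm[g])^2)
  ssb <- sum(n_i * (gm - grand)^2)
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  W <- msw
  B <- max(0, (msb - msw) / n0)
  list(W = W, B = B, ratio = W / (W + B))
}

# Hypergeometric upper-tail p by explicit enumeration of the tail.
oracle_hyper_tail <- function(k_overlap, m_term, n_other, n_set) {
  kk <- k_overlap:min(m_term, n_set)
  sum(choose(m_term, kk) * choose(n_other, n_set - kk)) /
    choose(m_term + n_other, n_set)
}

# Count overlapping dinucleotides of a string.
oracle_dinuc <- function(s) {
  v <- strsplit(s, "")[[1]]
  table(paste0(v[-length(v)], v[-1]))
}
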