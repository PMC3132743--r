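BASES <- c("A", "C", "G", "T")

# Encode a sequence as integer codes 1..4 (A,C,G,T); anything else is NA.
encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(v, BASES)
}

# Pseudocount-smoothed column frequencies of a PWM.
pwm_freqs <- function(pwm, pseudocount = 0.375) {
  counts <- pwm$counts + pseudocount
  sweep(counts, 2L, colSums(counts), "/")
}

# Log likelihood-ratio weights (natural log) of motif vs background, with
# a 5th row of -Inf so NA codes (non-ACGT) zero out any window they touch.
pwm_logratio <- function(pwm, background, pseudocount = 0.375) {
  f <- pwm_freqs(pwm, pseudocount)
  bg <- background[BASES] / sum(background[BASES])
  lw <- log(f / bg)
  rbind(lw, rep(-Inf, ncol(lw)))
}

# Sum the log-ratio weights over all windows of the encoded sequence; the
# log-sum-exp of window log-LRs gives log of the summed LR.
window_loglr <- function(codes, lw) {
  L <- ncol(lw)
  n <- length(codes)
  nw <- n - L + 1L
  codes[is.na(codes)] <- 5L
  acc <- numeric(nw)
  for (j in seq_len(L))
    acc <- acc + lw[cbind(codes[j:(j + nw - 1L)], j)]
  acc
}

#' Average likelihood-ratio score of a PWM on one sequence
#'
#' A simplified motif-over-background statistic: the likelihood ratio of
#' each motif-length window (pseudocount-smoothed column frequencies over
#' the background composition) is averaged over every position on both
#' strands, and the natural log of that mean is returned. Windows
#' containing non-ACGT characters contribute a likelihood ratio of 0. A
#' uniform PWM on a uniform background scores exactly 0 everywhere.
#'
#' @param pwm a PWM object.
#' @param sequence a single DNA string, length >= motif length.
#' @param background named base composition (A, C, G, T).
#' @param pseudocount smoothing constant added to every PWM cell
#'   (default 0.375).
#' @return the per-sequence score (log mean likelihood ratio).
#' @export
sequence_score <- function(pwm, sequence,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           pseudocount = 0.375) {
  lw <- pwm_logratio(pwm, background, pseudocount)
  score_encoded(encode_seq(sequence), lw)
}

# Core scorer on an encoded sequence given precomputed log weights.
score_encoded <- function(codes, lw) {
  L <- ncol(lw) - 0L
  if (length(codes) < ncol(lw)) stop("sequence shorter than motif")
  fwd <- window_loglr(codes, lw)
  # reverse strand: score the reverse complement (5 - code, NA-safe via
  # code 5 -> 0 -> remap to 5)
  rc <- 5L - rev(ifelse(is.na(codes), 0L, codes))
  rc[rc == 5L | rc == 0L] <- 5L
  rc[rc < 1L] <- 5L
  rev_scores <- window_loglr(rc, lw)
  all_lr <- c(fwd, rev_scores)
  m <- max(all_lr)
  if (!is.finite(m)) return(-Inf)
  log(mean(exp(all_lr - m))) + m
}

#' Mean per-sequence score of a PWM over a sequence set
#'
#' @param pwm a PWM object.
#' @param sequences character vector of DNA strings (>= 1).
#' @param background named base composition; if \code{NULL}, estimated
#'   from the sequences themselves.
#' @param pseudocount PWM smoothing constant.
#' @return the raw set score (arithmetic mean of per-sequence scores).
#' @export
set_score <- function(pwm, sequences, background = NULL,
                      pseudocount = 0.375) {
  if (length(sequences) == 0) stop("empty sequence set")
  if (is.null(background)) background <- base_composition(sequences)
  lw <- pwm_logratio(pwm, background, pseudocount)
  mean(vapply(sequences,
              function(s) score_encoded(encode_seq(s), lw), 0,
              USE.NAMES = FALSE))
}

#' Base composition of a sequence set
#' @param sequences character vector of DNA strings.
#' @return named frequency vector over A, C, G, T (non-ACGT ignored).
#' @export
base_composition <- function(sequences) {
  tab <- table(factor(unlist(strsplit(toupper(sequences), "",
                                      fixed = TRUE)), levels = BASES))
  f <- as.vector(tab) / sum(tab)
  names(f) <- BASES
  f
}

#' Mononucleotide shuffle of a sequence
#'
#' Random permutation of the characters; base composition is preserved
#' exactly.
#'
#' @param sequence DNA string.
#' @return shuffled string.
#' @export
shuffle_mono <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  paste(v[sample.int(length(v))], collapse = "")
}

#' Dinucleotide-preserving shuffle (Euler-path shuffle)
#'
#' Altschul-Erickson shuffle: treats the sequence as an Eulerian walk on
#' the graph of base-to-base transitions, samples a random spanning
#' arborescence toward the final base to fix each vertex's exit edge, and
#' permutes the remaining edges. The dinucleotide (and hence
#' mononucleotide) count vector is preserved exactly.
#'
#' @param sequence DNA string (characters beyond ACGT are handled as
#'   additional vertices).
#' @return shuffled string with identical dinucleotide counts.
#' @export
shuffle_dinuc <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(v)
  if (n <= 2) return(sequence)
  verts <- unique(v)
  edges <- split(v[-1L], factor(v[-n], levels = verts))
  last <- v[n]
  # sample a last-edge tree: from each non-terminal vertex, walk randomly
  # until the terminal vertex is reached; the first exit edge found on the
  # walk for each vertex forms a spanning arborescence into `last`
  repeat {
    last_edge <- setNames(rep(NA_character_, length(verts)), verts)
    ok <- TRUE
    for (s in setdiff(verts, last)) {
      cur <- s
      steps <- 0L
      while (cur != last) {
        nxt <- sample(edges[[cur]], 1L)
        last_edge[cur] <- nxt
        cur <- nxt
        steps <- steps + 1L
        if (steps > 4L * n) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the non-tree edges of each vertex, appending the tree edge last
  out_edges <- list()
  for (s in verts) {
    e <- edges[[s]]
    if (!is.na(last_edge[s])) {
      drop <- match(last_edge[s], e)
      e <- e[-drop]
    }
    e <- if (length(e) > 0) e[sample.int(length(e))] else character(0)
    if (!is.na(last_edge[s])) e <- c(e, last_edge[s])
    out_edges[[s]] <- e
  }
  res <- character(n)
  res[1L] <- v[1L]
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- v[1L]
  for (i in 2:n) {
    nxt <- out_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Count dinucleotides of a sequence
#' @param sequence DNA string.
#' @return named table of overlapping 2-mers.
#' @export
dinuc_counts <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (length(v) < 2) return(table(character(0)))
  table(paste0(v[-length(v)], v[-1L]))
}

# Permute PWM columns (identity excluded when possible).
permute_pwm_columns <- function(pwm) {
  L <- ncol(pwm$counts)
  perm <- sample.int(L)
  pwm_object(pwm$motif_id, pwm$name, pwm$counts[, perm, drop = FALSE])
}

#' Genes expressed above a mean-intensity threshold
#'
#' The expressed background for motif analysis: genes whose grand-mean
#' log2 intensity is at or above the threshold (default 4).
#'
#' @param X an \code{ExpressionMatrix}.
#' @param threshold intensity threshold (default 4).
#' @return character vector of gene ids.
#' @export
expressed_background <- function(X, threshold = 4) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  rownames(X$values)[rowMeans(X$values) >= threshold]
}

#' Five-way permutation significance for motif enrichment
#'
#' The observed statistic is the raw set score of the PWM on the target
#' promoters. Five independent nulls are evaluated: (1) per-sequence
#' mononucleotide shuffles of the targets; (2) per-sequence
#' dinucleotide-preserving shuffles; (3) column-order permutations of the
#' PWM on the intact targets; (4) random target-size sets drawn from a
#' background pool of all promoters; (5) the same from a pool of expressed
#' promoters. Each null yields \code{n_perm} set scores; the enrichment p
#' is (1 + #\{null >= observed\}) / (n_perm + 1) (never exactly 0 or 1),
#' and the depletion p the analogue with <=. A motif is called enriched
#' when at least four of the five tests give p < \code{p_threshold} and
#' the raw score reaches \code{score_threshold}; depleted when at least
#' four depletion p fall below \code{p_threshold}. A pool smaller than the
#' target set skips that pool's test with a warning and the 4-of-n rule is
#' applied to the tests actually run.
#'
#' @param pwm a PWM object.
#' @param target_sequences named character vector of target promoters.
#' @param background_pool_all,background_pool_expressed promoter pools.
#' @param n_perm permutations per test (default 1000, minimum 100).
#' @param seed integer seed.
#' @param p_threshold per-test significance level (default 0.05).
#' @param score_threshold minimum raw score for an enrichment call
#'   (default 5).
#' @param background base composition; estimated from the pooled
#'   background when \code{NULL}.
#' @param pseudocount PWM smoothing constant.
#' @return list of class \code{TFBSResult}: \code{motif_id},
#'   \code{raw_score}, \code{p_enrich} and \code{p_deplete} (named length-5
#'   vectors, NA for skipped tests), \code{n_significant}, \code{n_tests},
#'   \code{call} in \{enriched, depleted, NS\}.
#' @export
five_test_significance <- function(pwm, target_sequences,
                                   background_pool_all,
                                   background_pool_expressed,
                                   n_perm = 1000, seed = 1L,
                                   p_threshold = 0.05,
                                   score_threshold = 5,
                                   background = NULL,
                                   pseudocount = 0.375) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  set.seed(child_seed(seed, paste0("tfbs_", pwm$motif_id)))
  if (is.null(background))
    background <- base_composition(c(background_pool_all,
                                     background_pool_expressed))
  lw <- pwm_logratio(pwm, background, pseudocount)
  codes <- lapply(target_sequences, encode_seq)
  n_t <- length(codes)
  per_seq <- vapply(codes, function(cd) score_encoded(cd, lw), 0)
  observed <- mean(per_seq)

  add_one_p <- function(null_scores, obs) {
    c(enrich = (1 + sum(null_scores >= obs)) / (length(null_scores) + 1),
      deplete = (1 + sum(null_scores <= obs)) / (length(null_scores) + 1))
  }

  null_mono <- numeric(n_perm)
  null_di <- numeric(n_perm)
  null_mat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    # mononucleotide shuffle operates directly on the encoded sequence
    null_mono[b] <- mean(vapply(codes, function(cd)
      score_encoded(cd[sample.int(length(cd))], lw), 0))
    null_di[b] <- mean(vapply(target_sequences, function(s)
      score_encoded(encode_seq(shuffle_dinuc(s)), lw), 0))
    lwp <- pwm_logratio(permute_pwm_columns(pwm), background, pseudocount)
    null_mat[b] <- mean(vapply(codes, function(cd)
      score_encoded(cd, lwp), 0))
  }

  pool_null <- function(pool) {
    if (length(pool) < n_t) return(NULL)
    lw_pool <- lw
    scores <- vapply(pool, function(s)
      score_encoded(encode_seq(s), lw_pool), 0, USE.NAMES = FALSE)
    vapply(seq_len(n_perm), function(b)
      mean(scores[sample.int(length(scores), n_t)]), 0)
  }
  null_a <- pool_null(background_pool_all)
  null_b <- pool_null(background_pool_expressed)
  if (is.null(null_a))
    warning("background pool (all) smaller than target set; test skipped")
  if (is.null(null_b))
    warning("background pool (expressed) smaller than target set; ",
            "test skipped")

  nulls <- list(mono = null_mono, di = null_di, matrix = null_mat,
                bgA = null_a, bgB = null_b)
  p_enrich <- p_deplete <- setNames(rep(NA_real_, 5), names(nulls))
  for (nm in names(nulls)) {
    if (!is.null(nulls[[nm]])) {
      pp <- add_one_p(nulls[[nm]], observed)
      p_enrich[nm] <- pp["enrich"]
      p_deplete[nm] <- pp["deplete"]
    }
  }
  n_run <- sum(!is.na(p_enrich))
  n_sig_enrich <- sum(p_enrich < p_threshold, na.rm = TRUE)
  n_sig_deplete <- sum(p_deplete < p_threshold, na.rm = TRUE)
  need <- min(4L, n_run)
  call <- "NS"
  if (n_sig_enrich >= need && observed >= score_threshold) {
    call <- "enriched"
  } else if (n_sig_deplete >= need) {
    call <- "depleted"
  }
  structure(list(motif_id = pwm$motif_id, name = pwm$name,
                 raw_score = observed, p_enrich = p_enrich,
                 p_deplete = p_deplete,
                 n_significant = max(n_sig_enrich, n_sig_deplete),
                 n_tests = n_run, call = call,
                 n_perm = n_perm, per_sequence_scores = per_seq),
            class = "TFBSResult")
}

#' @export
print.TFBSResult <- function(x, ...) {
  cat("TFBS", x$motif_id, x$name, "- raw score",
      format(x$raw_score, digits = 4), "- call:", x$call, "(",
      x$n_significant, "of", x$n_tests, "tests )\n")
  invisible(x)
}
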