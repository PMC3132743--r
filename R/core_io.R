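#' @import stats
#' @import utils
NULL

# Canonical population labels for the five-population design.
PARENTAL_STRAINS <- c("LE", "HW", "SD")
ALL_STRAINS <- c("LE", "HW", "SD", "LnA", "LnC")

#' Construct an ExpressionMatrix
#'
#' The central container of the pipeline: a genes x samples matrix of
#' log2-normalized intensities together with per-sample metadata (strain
#' label, parental-ancestry proportions, AHR genotype).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#'   Rownames are gene identifiers, colnames sample identifiers.
#' @param samples data.frame with columns \code{sample_id}, \code{strain}
#'   and \code{ahr_variant} (0/1), one row per column of \code{values}.
#' @param ancestry numeric matrix, samples x parental strains, each row
#'   summing to 1. Rownames must match \code{samples$sample_id}. If
#'   \code{NULL}, a default is derived from the strain labels of the
#'   five-population design (parentals pure; LnA/LnC = 0.5 LE + 0.5 HW).
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, samples, ancestry = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values contain missing or non-finite entries")
  if (is.null(rownames(values))) stop("values must carry gene ids as rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0L)
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "strain", "ahr_variant")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L)
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("metadata rows (", nrow(samples), ") do not match sample columns (",
         ncol(values), ")")
  if (!all(samples$ahr_variant %in% c(0, 1)))
    stop("ahr_variant must be 0 or 1")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    idx <- match(colnames(values), samples$sample_id)
    if (anyNA(idx)) {
      bad <- colnames(values)[is.na(idx)]
      stop("sample(s) in matrix missing from metadata: ",
           paste(bad, collapse = ", "))
    }
    samples <- samples[idx, , drop = FALSE]
  }
  if (is.null(ancestry)) ancestry <- default_ancestry(samples$strain)
  ancestry <- as.matrix(ancestry)
  rownames(ancestry) <- samples$sample_id
  bad <- abs(rowSums(ancestry) - 1) > 1e-9
  if (any(bad))
    stop("ancestry proportions do not sum to 1 for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "))
  structure(list(values = values, samples = samples, ancestry = ancestry),
            class = "ExpressionMatrix")
}

# Default ancestry rows for the five-population design; unknown labels are
# treated as their own (pure) parental population.
default_ancestry <- function(strains) {
  parents <- union(PARENTAL_STRAINS, setdiff(unique(strains),
                                             c("LnA", "LnC")))
  anc <- matrix(0, nrow = length(strains), ncol = length(parents),
                dimnames = list(NULL, parents))
  for (i in seq_along(strains)) {
    s <- strains[i]
    if (s %in% c("LnA", "LnC")) {
      anc[i, "LE"] <- 0.5
      anc[i, "HW"] <- 0.5
    } else {
      anc[i, s] <- 1
    }
  }
  anc
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("strains:", paste(sprintf("%s(%d)", names(table(x$samples$strain)),
                                table(x$samples$strain)), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file has gene ids in the first column and one column per
#' sample; the metadata file is keyed by \code{sample_id} and must cover
#' every sample column. An \code{ancestry_*} column group, if present,
#' supplies parental-ancestry proportions.
#'
#' @param path expression TSV.
#' @param meta_path metadata TSV with columns \code{sample_id},
#'   \code{strain}, \code{ahr_variant} and optional \code{ancestry_<parent>}
#'   columns.
#' @return an \code{ExpressionMatrix}; column order of \code{path} is kept.
#' @export
read_expression_matrix <- function(path, meta_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric value at gene '", gene_ids[bad], "', sample '",
           names(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  values <- as.matrix(vals)
  rownames(values) <- gene_ids
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing) > 0L)
    stop("sample(s) in matrix missing from metadata: ",
         paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  anc_cols <- grep("^ancestry_", names(meta), value = TRUE)
  ancestry <- NULL
  if (length(anc_cols) > 0L) {
    ancestry <- as.matrix(meta[, anc_cols, drop = FALSE])
    colnames(ancestry) <- sub("^ancestry_", "", anc_cols)
  }
  expression_matrix(values, meta[, c("sample_id", "strain", "ahr_variant")],
                    ancestry)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path,meta_path output file paths.
#' @return \code{x}, invisibly.
#' @export
write_expression_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  anc <- as.data.frame(x$ancestry)
  names(anc) <- paste0("ancestry_", names(anc))
  meta <- cbind(x$samples, anc)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a gene-locus table (TSV)
#'
#' Columns \code{gene_id, chromosome, start, end, strand, tss}; coordinates
#' are 1-based inclusive.
#'
#' @param path TSV path.
#' @return data.frame of loci.
#' @export
read_loci <- function(path) {
  loci <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand", "tss")
  miss <- setdiff(need, names(loci))
  if (length(miss) > 0L)
    stop("locus table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(loci$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(loci$start > loci$end)) stop("locus with start > end")
  loci
}

#' Read JASPAR-format position-count matrices
#'
#' Accepts both common count-matrix dialects: a \code{">ID NAME"} header
#' followed by four plain rows of counts (A, C, G, T order), or rows
#' labelled \code{"A [ 1 2 3 ]"}.
#'
#' @param path JASPAR file.
#' @return named list of PWM objects, each a list with \code{motif_id},
#'   \code{name} and a 4 x L \code{counts} matrix (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' headers found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- trimws(sub("^>", "", lines[heads[i]]))
    parts <- strsplit(hdr, "[ \t]+")[[1L]]
    motif_id <- parts[1L]
    name <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else ""
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) < 4L)
      stop("motif ", motif_id, ": expected 4 count rows, got ", length(body))
    body <- body[1:4]
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[", "", ln)
      ln <- gsub("\\]", "", ln)
      as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
    })
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1L)
      stop("motif ", motif_id, ": count rows have differing lengths")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("motif ", motif_id, ": negative count")
    if (any(colSums(counts) <= 0))
      stop("motif ", motif_id, ": zero column sum")
    out[[motif_id]] <- pwm_object(motif_id, name, counts)
  }
  out
}

pwm_object <- function(motif_id, name, counts) {
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, all(counts >= 0),
            all(colSums(counts) > 0))
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, name = name, counts = counts),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$motif_id, x$name, "- length", ncol(x$counts), "\n")
  invisible(x)
}

#' Write PWMs in JASPAR bracketed format
#'
#' @param pwms list of PWM objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    cat(">", p$motif_id, " ", p$name, "\n", sep = "", file = con)
    for (b in c("A", "C", "G", "T"))
      cat(b, " [ ", paste(p$counts[b, ], collapse = " "), " ]\n",
          sep = "", file = con)
  }
  invisible(path)
}

#' Extract promoter windows around transcription start sites
#'
#' Windows span \code{tss - upstream .. tss + downstream} (1-based,
#' inclusive) so the default -1000..+1000 window is 2,001 bp. Minus-strand
#' genes are reverse-complemented. Windows running off a chromosome end are
#' truncated with a warning.
#'
#' @param genome named character vector of chromosome sequences, or a
#'   \code{Biostrings::DNAStringSet}, or a FASTA path.
#' @param loci data.frame as returned by \code{\link{read_loci}}.
#' @param upstream,downstream non-negative window half-widths in bp.
#' @return named character vector, one promoter per gene.
#' @export
extract_promoters <- function(genome, loci, upstream = 1000,
                              downstream = 1000) {
  if (upstream < 0 || downstream < 0)
    stop("upstream/downstream must be non-negative")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("[ \t].*$", "", names(genome))
    genome <- as.character(genome)
    names(genome) <- nm
  }
  out <- character(nrow(loci))
  names(out) <- loci$gene_id
  for (i in seq_len(nrow(loci))) {
    chr <- loci$chromosome[i]
    if (!chr %in% names(genome))
      stop("unknown chromosome '", chr, "' for gene ", loci$gene_id[i])
    seq <- genome[[chr]]
    clen <- nchar(seq)
    # the window is defined on the plus strand relative to the TSS; for
    # minus-strand genes "upstream" means larger coordinates
    if (loci$strand[i] == "+") {
      lo <- loci$tss[i] - upstream
      hi <- loci$tss[i] + downstream
    } else {
      lo <- loci$tss[i] - downstream
      hi <- loci$tss[i] + upstream
    }
    tlo <- max(1L, lo)
    thi <- min(clen, hi)
    if (tlo > lo || thi < hi)
      warning("promoter window truncated at chromosome end for gene ",
              loci$gene_id[i])
    s <- substr(seq, tlo, thi)
    if (loci$strand[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("[ \t].*$", "", names(ss))
  out
}

#' Read a two-column gene-to-term annotation table
#' @param path TSV with columns \code{gene_id}, \code{term_id}.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(ann)))
    stop("annotation table needs columns gene_id, term_id")
  ann
}

# Derive a 32-bit child seed from a root seed and a stage name, so each
# pipeline stage has an independent but reproducible stream and adding a
# stage never perturbs earlier stages.
child_seed <- function(seed, stage) {
  h <- as.integer(utf8ToInt(stage))
  acc <- as.double(seed %% 2147483647L)
  for (v in h) acc <- (acc * 31 + v) %% 2147483647
  as.integer(acc)
}
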