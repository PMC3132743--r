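#' Run the full analysis pipeline from a YAML configuration
#'
#' Orchestrates simulate -> variance -> fit-simple -> fit-ahr ->
#' heritability -> cluster -> enrich -> tfbs -> map -> concordance as
#' configured, writing one TSV per stage into the output directory. Every
#' output carries a '#'-prefixed header block recording package version,
#' root seed and stage parameters. Each stage derives its own child seed
#' from the root seed by stable hashing of the stage name, so adding a
#' stage never perturbs earlier stages and re-running a config reproduces
#' every output.
#'
#' The config needs either an \code{input} block (paths to an expression
#' TSV and metadata TSV) or a \code{simulate} block (arguments for
#' \code{\link{sim_config}}), plus an optional \code{stages} list
#' (default: variance, fit_simple, fit_ahr, heritability, cluster) and an
#' optional \code{seed} (default 1).
#'
#' @param config_path path to a YAML config file.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config_path, out_dir = "results") {
  cfg <- yaml::read_yaml(config_path)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  stages <- if (!is.null(cfg$stages)) unlist(cfg$stages) else
    c("variance", "fit_simple", "fit_ahr", "heritability", "cluster")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[strainvar] ", ...)
  hdr <- function(stage, ...) {
    c(package = paste0("strainvar ",
                       as.character(utils::packageVersion("strainvar"))),
      seed = seed, stage = stage, ...)
  }
  results <- list()

  if (!is.null(cfg$simulate)) {
    log_msg("stage simulate")
    args <- cfg$simulate
    args$seed <- child_seed(seed, "simulate")
    sc <- do.call(sim_config, args)
    sim <- simulate_expression(sc)
    X <- sim$X
    results$truth <- sim$truth
    write_expression_matrix(X, file.path(out_dir, "expression.tsv"),
                            file.path(out_dir, "samples.tsv"))
  } else if (!is.null(cfg$input)) {
    log_msg("stage load")
    X <- read_expression_matrix(cfg$input$expression, cfg$input$metadata)
  } else {
    stop("config must contain either a 'simulate' or an 'input' block")
  }
  results$X <- X

  fit_s <- NULL
  fit_a <- NULL
  need_fit <- function() {
    if (is.null(fit_s)) fit_s <<- fit_simple_pairwise(X)
    fit_s
  }

  for (stage in stages) {
    log_msg("stage ", stage)
    if (stage == "variance") {
      vp <- partition_variance(X)
      results$variance <- vp
      write_tsv_with_header(vp, file.path(out_dir, "variance.tsv"),
                            hdr("variance"))
    } else if (stage == "fit_simple") {
      fit_s <- need_fit()
      tab <- data.frame(gene_id = fit_s$gene_ids, A = fit_s$A,
                        fit_s$q, F = fit_s$F, F_p = fit_s$F_p,
                        check.names = FALSE)
      results$fit_simple <- fit_s
      write_tsv_with_header(tab, file.path(out_dir, "fit_simple.tsv"),
                            hdr("fit_simple"))
    } else if (stage == "fit_ahr") {
      fit_a <- fit_ancestry_ahr(X)
      tab <- data.frame(gene_id = fit_a$gene_ids, A = fit_a$A,
                        fit_a$coefficients,
                        M = fit_a$M[, "AHR"], t = fit_a$t[, "AHR"],
                        p = fit_a$p[, "AHR"], q = fit_a$q[, "AHR"],
                        check.names = FALSE)
      results$fit_ahr <- fit_a
      write_tsv_with_header(tab, file.path(out_dir, "fit_ahr.tsv"),
                            hdr("fit_ahr"))
    } else if (stage == "heritability") {
      fit_s <- need_fit()
      prof <- distance_profile(X, fit_s)
      inter <- find_interacting_loci(fit_s)
      results$heritability <- prof
      results$interacting <- inter
      write_tsv_with_header(prof$records,
                            file.path(out_dir, "heritability.tsv"),
                            hdr("heritability"))
      write_tsv_with_header(inter, file.path(out_dir, "interacting.tsv"),
                            hdr("heritability"))
    } else if (stage == "cluster") {
      thr <- if (!is.null(cfg$cluster$threshold))
        cfg$cluster$threshold else 0.25
      genes <- variance_filter(X, thr)
      if (length(genes) < 2) stop("stage cluster: fewer than 2 genes ",
                                  "pass the variance filter")
      tree <- cluster_samples(X, genes)
      k <- if (!is.null(cfg$cluster$k)) cfg$cluster$k else
        length(unique(X$samples$strain))
      assign <- cut_diana(tree, k)
      results$cluster <- list(tree = tree, assignments = assign)
      writeLines(diana_newick(tree),
                 file.path(out_dir, "dendrogram.newick"))
      write_tsv_with_header(data.frame(sample_id = names(assign),
                                       cluster = assign),
                            file.path(out_dir, "clusters.tsv"),
                            hdr("cluster", k = k, threshold = thr))
    } else if (stage == "enrich") {
      if (is.null(cfg$enrich$annotation))
        stop("stage enrich: missing annotation path in config")
      ann <- read_annotation(cfg$enrich$annotation)
      fit_s <- need_fit()
      if (is.null(fit_a)) fit_a <- fit_ancestry_ahr(X)
      em <- contrast_enrichment(fit_s, fit_a, ann)
      results$enrichment <- em
      write_tsv_with_header(data.frame(term_id = rownames(em), em,
                                       check.names = FALSE),
                            file.path(out_dir, "enrichment.tsv"),
                            hdr("enrich"))
    } else {
      stop("unknown stage '", stage, "' in config")
    }
  }
  invisible(results)
}
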