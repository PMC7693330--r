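#' Run the discovery pipeline end to end
#'
#' Orchestrates the stages: obtain genomes (simulate a cohort, or load
#' FASTA + GFF3 inputs), scan for candidates, tabulate the
#' genomic-context census, compute the mat-vs-rep MILC table, and
#' optionally build a bootstrapped Rep NJ tree.  Every run writes a JSON
#' manifest (package version, config echo, input checksums, seed,
#' per-stage row counts, timestamp) so outputs are reproducible functions
#' of the manifest.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{input}{either `list(simulate = TRUE, n = <int>)` or
#'       `list(fasta = <path>, gff = <path>)`}
#'     \item{mode}{`"strict"` or `"relaxed"` (default strict)}
#'     \item{criteria}{optional [criteria_config()]}
#'     \item{generator}{optional [generator_config()] (simulation only)}
#'     \item{stages}{character subset of `c("scan", "census", "milc",
#'       "phylo")` (default all but phylo)}
#'     \item{bootstrap_n}{replicates for the phylo stage (default 1000)}
#'   }
#' @param out_dir Output directory (created).
#' @param seed Integer seed for all randomness.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  criteria <- config$criteria %||% criteria_config()
  mode <- config$mode %||% "strict"
  stages <- config$stages %||% c("scan", "census", "milc")
  manifest <- list(tool = "sglscan",
                   version = as.character(utils::packageVersion("sglscan")),
                   seed = as.integer(seed),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   mode = mode, stages = stages, counts = list())
  truth <- NULL
  if (isTRUE(config$input$simulate)) {
    gen <- config$generator %||% generator_config()
    n <- config$input$n %||% 20L
    coh_cfg <- config$cohort %||% {
      # small simulations fall back to independent genomes only
      default <- cohort_config()
      if (n >= default$clade_size +
            2L * (default$n_s_pairs + default$n_d_pairs) + 1L) default
      else cohort_config(clade_size = 0L, n_s_pairs = 0L, n_d_pairs = 0L)
    }
    coh <- generate_cohort(gen, n = n, seed = seed, cohort = coh_cfg)
    genomes <- coh$genomes
    truth <- coh$truth
    write_fasta(genomes, file.path(out_dir, "genomes.fasta"))
    write_annotations(genomes, file.path(out_dir, "genomes.gff3"))
    jsonlite::write_json(
      lapply(truth$per_genome, function(t)
        list(sgls = t$sgls, decoys = t$decoys)),
      file.path(out_dir, "truth.json"), dataframe = "rows", na = "null")
    manifest$input <- list(simulate = TRUE, n = n)
  } else {
    if (is.null(config$input$fasta))
      stop("config$input needs either simulate=TRUE or a 'fasta' path")
    genomes <- read_fasta(config$input$fasta)
    manifest$input <- list(
      fasta = config$input$fasta,
      fasta_md5 = unname(tools::md5sum(config$input$fasta)))
    if (!is.null(config$input$gff)) {
      genomes <- read_annotations(config$input$gff, genomes)
      manifest$input$gff <- config$input$gff
      manifest$input$gff_md5 <- unname(tools::md5sum(config$input$gff))
    }
  }
  manifest$counts$genomes <- length(genomes)
  results <- list(genomes = genomes, truth = truth)

  if ("scan" %in% stages) {
    tabs <- lapply(genomes, scan_genome, config = criteria, mode = mode)
    candidates <- do.call(rbind, c(tabs, list(empty_candidate_table())))
    candidates <- as_candidate_table(candidates)
    write_candidates(candidates, file.path(out_dir, "candidates.tsv"), "tsv")
    write_candidates(candidates, file.path(out_dir, "candidates.gff3"), "gff3")
    manifest$counts$candidates <- nrow(candidates)
    results$candidates <- candidates
    message("scan: ", length(genomes), " genome(s), ",
            nrow(candidates), " candidate(s) [", mode, "]")
  }
  if ("census" %in% stages && !is.null(results$candidates)) {
    cen <- census(results$candidates, config$functional_ids %||% character())
    utils::write.table(cen$regions, file.path(out_dir, "census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cen$multiplicity,
                       file.path(out_dir, "multiplicity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$census_total <- sum(cen$regions$n_all)
    results$census <- cen
  }
  if ("milc" %in% stages) {
    milc_tab <- mat_vs_rep_table(genomes,
                                 results$candidates %||%
                                   empty_candidate_table())
    utils::write.table(milc_tab, file.path(out_dir, "milc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$milc_rows <- nrow(milc_tab)
    results$milc <- milc_tab
  }
  if ("phylo" %in% stages) {
    reps <- rep_proteins(genomes)
    aln <- progressive_msa(reps, align_params("aa"))
    write_msa(aln, file.path(out_dir, "rep_alignment.afa"))
    tree <- bootstrap_support(aln, n = config$bootstrap_n %||% 1000L,
                              seed = seed)
    ape::write.tree(tree, file.path(out_dir, "rep_tree.nwk"))
    manifest$counts$tree_tips <- length(tree$tip.label)
    results$tree <- tree
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
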