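#' Count sense codons of a coding sequence
#'
#' The terminal stop codon is excluded; codons containing `N` are skipped
#' and counted in the `skipped` attribute.  An internal stop codon is an
#' error (the input is expected to be a clean CDS).
#'
#' @param cds_nt Nucleotide string, length divisible by 3.
#' @return Named integer vector over the 61 sense codons, with attributes
#'   `L` (gene length in counted sense codons) and `skipped`.
#' @export
codon_counts <- function(cds_nt) {
  cds_nt <- toupper(gsub("U", "T", as.character(cds_nt), fixed = TRUE))
  n <- nchar(cds_nt)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(cds_nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  if (any(codons %in% STOP_CODONS))
    stop("internal stop codon in CDS")
  has_n <- grepl("N", codons, fixed = TRUE)
  skipped <- sum(has_n)
  codons <- codons[!has_n]
  counts <- integer(61L)
  names(counts) <- sense_codons()
  tt <- table(codons)
  counts[names(tt)] <- as.integer(tt)
  structure(counts, L = sum(counts), skipped = skipped)
}

#' MILC codon-usage distance of a gene from a reference usage
#'
#' Measure Independent of Length and Composition.  For each amino acid
#' `a` present in the gene, `M_a = 2 * sum_c o_c * log(f_c / g_c)` over its
#' codons `c`, where `o_c` are gene codon counts, `f_c` the gene's
#' within-amino-acid codon frequencies and `g_c` the reference's
#' (zero reference cells receive a pseudocount before normalising;
#' `0 * log(0/g) = 0`).  The statistic is
#' `MILC = sum_a M_a / L - C` with the length/degeneracy correction
#' `C = sum_{a present} (r_a - 1) / L - 0.5`, `r_a` the codon degeneracy
#' of `a` and `L` the gene length in sense codons.  Single-codon amino
#' acids (Met, Trp) contribute 0 to both sums.
#'
#' @param gene_counts Codon counts from [codon_counts()] (or any named
#'   vector over the 61 sense codons).
#' @param reference_counts Reference codon counts (same form) defining
#'   `g_c`.
#' @param pseudocount Added to zero reference cells of amino acids present
#'   in the gene.
#' @return List of class `milc_value`: `milc`, `sum_Ma`, `correction_C`,
#'   `L`.
#' @export
milc <- function(gene_counts, reference_counts, pseudocount = 0.5) {
  sc <- sense_codons()
  o <- numeric(61L); names(o) <- sc
  o[names(gene_counts)[names(gene_counts) %in% sc]] <-
    gene_counts[names(gene_counts) %in% sc]
  ref <- numeric(61L); names(ref) <- sc
  ref[names(reference_counts)[names(reference_counts) %in% sc]] <-
    reference_counts[names(reference_counts) %in% sc]
  L <- sum(o)
  if (L == 0) stop("gene has no sense codons (L == 0)")
  fam <- codons_by_aa()
  sum_Ma <- 0
  degen_sum <- 0L
  for (aa in names(fam)) {
    cods <- fam[[aa]]
    oc <- o[cods]
    if (sum(oc) == 0) next          # amino acid absent from the gene
    degen_sum <- degen_sum + length(cods) - 1L
    if (length(cods) == 1L) next    # Met/Trp contribute 0
    gc <- ref[cods]
    gc[gc == 0] <- pseudocount
    f <- oc / sum(oc)
    g <- gc / sum(gc)
    term <- ifelse(oc > 0, oc * log(f / g), 0)
    sum_Ma <- sum_Ma + 2 * sum(term)
  }
  C <- degen_sum / L - 0.5
  structure(list(milc = sum_Ma / L - C, sum_Ma = sum_Ma,
                 correction_C = C, L = as.integer(L)),
            class = "milc_value")
}

#' @export
print.milc_value <- function(x, ...) {
  cat(sprintf("MILC = %.6f  (sum M_a = %.6f, C = %.6f, L = %d)\n",
              x$milc, x$sum_Ma, x$correction_C, x$L))
  invisible(x)
}

#' MILC of mat and rep genes per genome
#'
#' For every genome with complete `mat` and `rep` annotations, computes
#' the MILC of each gene against a reference codon usage and flags whether
#' the genome carries a rep-embedded candidate (region 16).  By default the
#' reference usage is the concatenation of all annotated CDS of the same
#' genome (self-reference); supply `reference_counts` to use an external
#' usage table instead.
#'
#' @param genomes List of `genome_record`s with genes annotated.
#' @param candidates Candidate table with `region` populated (may be
#'   empty).
#' @param reference_counts Optional external reference codon counts.
#' @return data.frame with columns `genome_id`, `milc_mat`, `milc_rep`,
#'   `has_rep_embedded_sgl`.  Genomes lacking a complete mat or rep are
#'   skipped with a message.
#' @export
mat_vs_rep_table <- function(genomes, candidates = empty_candidate_table(),
                             reference_counts = NULL) {
  candidates <- as_candidate_table(candidates)
  rows <- list()
  for (g in genomes) {
    gm <- get_gene(g, "mat"); gr <- get_gene(g, "rep")
    if (is.null(gm) || is.null(gr) ||
        any(gm$start_truncated, gm$end_truncated,
            gr$start_truncated, gr$end_truncated)) {
      message("mat_vs_rep_table: skipping ", g$genome_id,
              " (missing or partial mat/rep)")
      next
    }
    ref <- reference_counts
    if (is.null(ref)) {
      cds <- vapply(g$genes$gene_name[g$genes$gene_name %in%
                                        c("mat", "coat", "rep")],
                    function(nm) gene_seq(g, nm), "")
      ref <- Reduce(`+`, lapply(cds, codon_counts))
    }
    has_sgl <- any(candidates$genome_id == g$genome_id &
                     !is.na(candidates$region) & candidates$region == 16L)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g$genome_id,
      milc_mat = milc(codon_counts(gene_seq(g, "mat")), ref)$milc,
      milc_rep = milc(codon_counts(gene_seq(g, "rep")), ref)$milc,
      has_rep_embedded_sgl = has_sgl,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(genome_id = character(), milc_mat = double(),
                      milc_rep = double(), has_rep_embedded_sgl = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
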