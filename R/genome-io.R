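#' Construct a genome record
#'
#' A genome record holds one levivirus-like genome: an identifier, the
#' plus-strand nucleotide sequence (uppercase DNA alphabet, `U` already
#' transliterated to `T`), and optional core-gene annotations.  Internal
#' coordinates are 0-based half-open throughout the package; GFF3 files on
#' disk are 1-based inclusive.
#'
#' @param genome_id Identifier (non-empty string).
#' @param sequence Nucleotide sequence; lowercase and RNA (`U`) input is
#'   normalised.
#' @param description Free-text description.
#' @param genes `NULL` or a data.frame with columns `gene_name`
#'   (`mat`/`coat`/`rep`/`other`), `start`, `end` (0-based half-open),
#'   `start_truncated`, `end_truncated`.
#' @param is_partial Whether the genome is a partial contig.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequence, description = "",
                          genes = NULL, is_partial = FALSE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nzchar(genome_id))
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (!nzchar(sequence)) stop("empty sequence for record '", genome_id, "'")
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) && nzchar(bad))
    stop("record '", genome_id, "': non-IUPAC character '", bad, "'")
  if (is.null(genes)) genes <- empty_gene_table()
  genes <- validate_genes(genes, nchar(sequence), genome_id)
  structure(list(genome_id = genome_id, sequence = sequence,
                 description = description, genes = genes,
                 is_partial = isTRUE(is_partial)),
            class = "genome_record")
}

empty_gene_table <- function() {
  data.frame(gene_name = character(), start = integer(), end = integer(),
             start_truncated = logical(), end_truncated = logical(),
             stringsAsFactors = FALSE)
}

validate_genes <- function(genes, seq_len, genome_id) {
  req <- c("gene_name", "start", "end")
  if (!all(req %in% names(genes)))
    stop("gene table needs columns ", paste(req, collapse = ", "))
  if (is.null(genes$start_truncated)) genes$start_truncated <- FALSE
  if (is.null(genes$end_truncated)) genes$end_truncated <- FALSE
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (any(genes$start >= genes$end))
      stop("genome '", genome_id, "': gene interval with start >= end")
    if (any(genes$start < 0L) || any(genes$end > seq_len))
      stop("genome '", genome_id, "': gene interval outside [0, ", seq_len, ")")
    core <- genes[genes$gene_name %in% c("mat", "coat", "rep"), ]
    if (nrow(core)) {
      ord <- match(c("mat", "coat", "rep"), core$gene_name)
      ord <- ord[!is.na(ord)]
      if (is.unsorted(core$start[ord]))
        warning("genome '", genome_id,
                "': core genes mat/coat/rep out of 5'->3' order")
    }
  }
  rownames(genes) <- NULL
  genes[, c("gene_name", "start", "end", "start_truncated", "end_truncated")]
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", nchar(x$sequence), " nt",
      if (x$is_partial) " (partial)", "\n", sep = "")
  if (nrow(x$genes)) {
    for (i in seq_len(nrow(x$genes)))
      cat(sprintf("  %-5s [%d, %d)\n", x$genes$gene_name[i],
                  x$genes$start[i], x$genes$end[i]))
  }
  invisible(x)
}

#' Fetch an annotated gene interval from a genome record
#'
#' @param genome A `genome_record`.
#' @param gene_name Gene to look up (`mat`, `coat`, `rep`).
#' @return One-row data.frame, or `NULL` when absent.
#' @export
get_gene <- function(genome, gene_name) {
  g <- genome$genes[genome$genes$gene_name == gene_name, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  g[1, , drop = FALSE]
}

#' Extract a gene's nucleotide sequence
#' @param genome A `genome_record`.
#' @param gene_name Annotated gene name.
#' @return Nucleotide string.
#' @export
gene_seq <- function(genome, gene_name) {
  g <- get_gene(genome, gene_name)
  if (is.null(g)) stop("gene '", gene_name, "' not annotated on ",
                       genome$genome_id)
  substr(genome$sequence, g$start + 1L, g$end)
}

#' Read genomes from a (multi-)FASTA file
#'
#' Sequences are uppercased and RNA `U` is transliterated to `T`.  Gene
#' tables are left empty; see [read_annotations()].
#'
#' @param path FASTA file.
#' @return List of `genome_record`, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  out <- lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), description = desc[i]))
  names(out) <- ids
  out
}

#' Write genome records to FASTA
#' @param genomes List of `genome_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "genome_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Populate gene annotations from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention.  The gene name is taken from a
#' configurable attribute key (default `Name`).  mat/coat/rep lines out of
#' 5'->3' order trigger a warning but are kept.
#'
#' @param path GFF3 file.
#' @param genomes List of `genome_record` (as from [read_fasta()]).
#' @param name_attr Attribute key holding the gene name.
#' @return The genome list with `genes` tables filled in.
#' @export
read_annotations <- function(path, genomes, name_attr = "Name") {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  names(genomes) <- ids
  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqid), ids)
  if (length(unknown))
    stop("GFF3 seqid(s) not among loaded genomes: ",
         paste(unknown, collapse = ", "))
  nm <- S4Vectors::mcols(gr)[[name_attr]]
  if (is.null(nm)) stop("GFF3 attribute '", name_attr, "' not present")
  nm <- as.character(nm)
  for (k in seq_along(gr)) {
    gid <- seqid[k]
    start0 <- GenomicRanges::start(gr)[k] - 1L   # 1-based incl -> 0-based
    end0 <- GenomicRanges::end(gr)[k]            # inclusive end -> half-open
    glen <- nchar(genomes[[gid]]$sequence)
    if (start0 < 0L || end0 > glen)
      stop("GFF3 feature on ", gid, " out of bounds: ",
           start0 + 1L, "..", end0, " vs length ", glen)
    gene <- if (nm[k] %in% c("mat", "coat", "rep")) nm[k] else "other"
    genomes[[gid]]$genes <- rbind(
      genomes[[gid]]$genes,
      data.frame(gene_name = gene, start = start0, end = end0,
                 start_truncated = FALSE, end_truncated = FALSE,
                 stringsAsFactors = FALSE))
  }
  for (gid in ids)
    genomes[[gid]]$genes <- validate_genes(genomes[[gid]]$genes,
                                           nchar(genomes[[gid]]$sequence), gid)
  genomes
}

#' Write gene annotations to GFF3
#' @param genomes List of `genome_record`.
#' @param path Output GFF3 file (1-based inclusive coordinates).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genomes, path) {
  rows <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    data.frame(seqid = g$genome_id, start = g$genes$start + 1L,
               end = g$genes$end, name = g$genes$gene_name,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqid,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "sglscan"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$Name <- rows$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Translate a coding nucleotide sequence
#'
#' Uses the standard genetic code.  A trailing stop codon is stripped and
#' reported through the `stop_present` attribute; internal stops render as
#' `*` and set `internal_stop`.  With `as_initiator = TRUE` a leading
#' `GTG`/`TTG` is read as `M` (bacterial initiator).
#'
#' @param nt_seq Nucleotide string, length divisible by 3.
#' @param as_initiator Render a leading GTG/TTG as methionine.
#' @return Amino-acid string with attributes `stop_present` and
#'   `internal_stop`.
#' @export
translate_cds <- function(nt_seq, as_initiator = FALSE) {
  nt_seq <- toupper(gsub("U", "T", as.character(nt_seq), fixed = TRUE))
  n <- nchar(nt_seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  if (n == 0L)
    return(structure("", stop_present = FALSE, internal_stop = FALSE))
  codons <- substring(nt_seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  gc <- genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (as_initiator && codons[1] %in% c("GTG", "TTG")) aa[1] <- "M"
  stop_present <- aa[length(aa)] == "*"
  if (stop_present) aa <- aa[-length(aa)]
  structure(paste(aa, collapse = ""),
            stop_present = stop_present,
            internal_stop = any(aa == "*"))
}

# ---- candidate tables -------------------------------------------------

CANDIDATE_COLUMNS <- c(
  "genome_id", "start", "end", "frame", "start_codon", "protein",
  "has_stop", "sd_best", "sd_spacer", "sd_window", "sd_pass",
  "kd_max", "kd_start", "kd_end", "kd_window", "kd_short", "tmd_pass",
  "len_pass", "strict_pass", "relaxed_fail", "region", "host_gene",
  "frame_offset")

#' An empty candidate table
#'
#' Candidate tables are plain data.frames keyed by
#' `(genome_id, start, end, frame)` with one row per ORF candidate and a
#' fixed, documented column order.
#' @return Zero-row candidate table.
#' @export
empty_candidate_table <- function() {
  data.frame(
    genome_id = character(), start = integer(), end = integer(),
    frame = integer(), start_codon = character(), protein = character(),
    has_stop = logical(), sd_best = integer(), sd_spacer = integer(),
    sd_window = character(), sd_pass = logical(), kd_max = double(),
    kd_start = integer(), kd_end = integer(), kd_window = integer(),
    kd_short = logical(), tmd_pass = logical(), len_pass = logical(),
    strict_pass = logical(), relaxed_fail = character(),
    region = integer(), host_gene = character(), frame_offset = integer(),
    stringsAsFactors = FALSE)
}

#' Coerce a data.frame to a valid candidate table
#'
#' Enforces the fixed column order and types, normalises unset character
#' fields to empty strings, and checks key uniqueness on
#' `(genome_id, start, end, frame)`.
#' @param df data.frame with at least the populated candidate columns.
#' @return Candidate table.
#' @export
as_candidate_table <- function(df) {
  tmpl <- empty_candidate_table()
  for (cn in CANDIDATE_COLUMNS)
    if (is.null(df[[cn]])) df[[cn]] <- rep(NA, nrow(df))
  for (cn in CANDIDATE_COLUMNS) {
    target <- class(tmpl[[cn]])[1]
    df[[cn]] <- switch(target,
      integer = as.integer(df[[cn]]),
      numeric = as.numeric(df[[cn]]),
      logical = as.logical(df[[cn]]),
      character = {
        v <- as.character(df[[cn]])
        v[is.na(v)] <- ""   # unset character fields are empty strings
        v
      })
  }
  df <- df[, CANDIDATE_COLUMNS]
  key <- paste(df$genome_id, df$start, df$end, df$frame)
  if (anyDuplicated(key))
    stop("duplicate candidate key(s): ", key[duplicated(key)][1])
  rownames(df) <- NULL
  df
}

#' Write a candidate table to disk
#'
#' TSV and JSON outputs round-trip losslessly through
#' [read_candidates()]; GFF3 output uses 1-based inclusive coordinates.
#'
#' @param table Candidate table.
#' @param path Output file.
#' @param format One of `"tsv"`, `"gff3"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(table, path, format = c("tsv", "gff3", "json")) {
  format <- match.arg(format)
  table <- as_candidate_table(table)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else if (format == "json") {
    jsonlite::write_json(table, path, dataframe = "columns", na = "null",
                         auto_unbox = FALSE, digits = NA)
  } else {
    if (!nrow(table)) {
      writeLines("##gff-version 3", path)
      return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = table$genome_id,
      ranges = IRanges::IRanges(start = table$start + 1L, end = table$end),
      strand = "+")
    S4Vectors::mcols(gr)$source <- "sglscan"
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$phase <- 0L
    S4Vectors::mcols(gr)$ID <- paste0(table$genome_id, ":", table$start + 1L,
                                      "-", table$end, ":f", table$frame)
    S4Vectors::mcols(gr)$Name <- S4Vectors::mcols(gr)$ID
    S4Vectors::mcols(gr)$region <- table$region
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return Candidate table.
#' @export
read_candidates <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = "NA",
                            stringsAsFactors = FALSE, quote = "")
    # empty-string character fields come back NA from read.table; restore
    for (cn in c("sd_window", "relaxed_fail", "host_gene", "protein"))
      if (cn %in% names(df)) df[[cn]][is.na(df[[cn]])] <- ""
  } else {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                        stringsAsFactors = FALSE)
    if (!nrow(df)) df <- empty_candidate_table()
  }
  as_candidate_table(df)
}
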