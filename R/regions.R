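#' Assign a candidate interval to one of 18 genomic-context regions
#'
#' The taxonomy is anchored on the three core genes in mat-coat-rep order:
#' region 1 is fully 5' of `mat` and region 18 fully 3' of `rep`; for gene
#' i (1 = mat, 2 = coat, 3 = rep), region `6i-4` overlaps only the gene's
#' 5' end, `6i-3` spans the gene entirely, `6i-2` is fully embedded in it
#' (so mat -> 4, coat -> 10, rep -> 16), `6i-1` overlaps only its 3' end,
#' `6i` bridges its 3' end and the next gene's 5' end, and `6i+1` is fully
#' intergenic downstream of it.  The function is total and deterministic:
#' an interval spanning several genes classifies as "spans" for the
#' 5'-most gene fully covered; an interval embedded in overlapping genes
#' is assigned to the 3'-most containing gene.
#'
#' @param candidate_interval 0-based half-open `c(start, end)`.
#' @param genes Gene table of a `genome_record` (needs mat, coat, rep).
#' @return List with `region` (1..18), `host_gene`
#'   (`mat`/`coat`/`rep`/`none`) and `frame_offset` (0/1/2, `NA` unless the
#'   interval lies fully inside a single gene).
#' @export
classify_region <- function(candidate_interval, genes) {
  a <- as.integer(candidate_interval[1]); b <- as.integer(candidate_interval[2])
  stopifnot(a < b)
  core <- c("mat", "coat", "rep")
  gi <- lapply(core, function(g) {
    row <- genes[genes$gene_name == g, , drop = FALSE]
    if (!nrow(row)) stop("gene '", g, "' missing from annotation")
    c(row$start[1], row$end[1])
  })
  s <- vapply(gi, `[`, 0L, 1); e <- vapply(gi, `[`, 0L, 2)
  if (is.unsorted(s, strictly = TRUE) || is.unsorted(e))
    stop("core genes out of 5'->3' order")

  result <- function(region) {
    host <- if (region %in% c(1L, 7L, 13L, 18L)) "none"
            else core[ceiling((region - 1L) / 6L)]
    off <- NA_integer_
    if (host != "none") {
      hs <- s[match(host, core)]; he <- e[match(host, core)]
      if (a >= hs && b <= he) off <- (a - hs) %% 3L
    }
    list(region = region, host_gene = host, frame_offset = off)
  }

  if (b <= s[1]) return(result(1L))
  if (a >= e[3]) return(result(18L))
  embedded <- which(a >= s & b <= e)
  spans <- which(a <= s & b >= e)
  spans <- setdiff(spans, embedded)
  if (length(spans)) return(result(6L * min(spans) - 3L))
  if (length(embedded)) return(result(6L * max(embedded) - 2L))
  overlaps <- which(a < e & b > s)
  if (length(overlaps) >= 2L) return(result(6L * min(overlaps)))
  if (length(overlaps) == 1L) {
    i <- overlaps
    if (a < s[i]) return(result(6L * i - 4L))
    return(result(6L * i - 1L))
  }
  # fully intergenic
  for (i in 1:2) if (a >= e[i] && b <= s[i + 1]) return(result(6L * i + 1L))
  stop("unclassifiable interval [", a, ", ", b, ")")  # unreachable on valid input
}

#' Reading-frame offset of a candidate relative to its host gene
#'
#' @param candidate Candidate row or list with 0-based `start`, `end`.
#' @param host_gene One-row gene table entry (0-based `start`, `end`).
#' @return `(start - gene_start) mod 3` when the candidate lies fully
#'   inside the gene, else `NA`.  An offset of 0 (same frame as the host)
#'   carries attribute `same_frame = TRUE` -- embedded sgls are expected in
#'   shifted frames.
#' @export
frame_offset <- function(candidate, host_gene) {
  a <- as.integer(candidate$start); b <- as.integer(candidate$end)
  gs <- as.integer(host_gene$start); ge <- as.integer(host_gene$end)
  if (a < gs || b > ge) return(NA_integer_)
  off <- (a - gs) %% 3L
  if (off == 0L) attr(off, "same_frame") <- TRUE
  off
}

#' Tabulate the genomic-context census
#'
#' Per-region counts over all candidates and over a functional subset,
#' plus a per-genome candidate-multiplicity tally.
#'
#' @param candidates Candidate table with `region` populated (rows from
#'   several genomes may be concatenated).
#' @param functional_ids Character vector of candidate keys
#'   (`"genome_id:start-end"`) deemed functional; must be a subset of the
#'   candidates.
#' @return List with `regions` (data.frame region 1..18, `n_all`,
#'   `n_functional`) and `multiplicity` (data.frame `genome_id`,
#'   `n_candidates`).
#' @export
census <- function(candidates, functional_ids = character()) {
  df <- as_candidate_table(candidates)
  if (anyNA(df$region) && nrow(df))
    stop("all candidates must be classified before census()")
  key <- candidate_key(df)
  missing <- setdiff(functional_ids, key)
  if (length(missing))
    stop("functional id(s) not among candidates: ",
         paste(missing, collapse = ", "))
  n_all <- tabulate(df$region, nbins = 18L)
  n_fun <- tabulate(df$region[key %in% functional_ids], nbins = 18L)
  regions <- data.frame(region = 1:18, n_all = n_all, n_functional = n_fun)
  multiplicity <- if (nrow(df)) {
    tt <- table(df$genome_id)
    data.frame(genome_id = names(tt), n_candidates = as.integer(tt),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(genome_id = character(), n_candidates = integer(),
               stringsAsFactors = FALSE)
  }
  list(regions = regions, multiplicity = multiplicity)
}

#' Candidate keys of the form genome_id:start-end
#' @param candidates Candidate table.
#' @return Character vector.
#' @export
candidate_key <- function(candidates) {
  paste0(candidates$genome_id, ":", candidates$start, "-", candidates$end)
}

#' Classify a closely related genome pair by sgl context
#'
#' Two sgls are S-class (similar) when they occupy the same genomic-context
#' region in their respective genomes, and D-class (different) otherwise.
#'
#' @param sgl_a,sgl_b Candidate rows (0-based `start`, `end`).
#' @param genome_a,genome_b The corresponding `genome_record`s (core genes
#'   annotated).
#' @return List with `class` (`"S"` or `"D"`) and the two region
#'   assignments for audit.
#' @export
classify_pair_context <- function(sgl_a, genome_a, sgl_b, genome_b) {
  ra <- classify_region(c(sgl_a$start, sgl_a$end), genome_a$genes)
  rb <- classify_region(c(sgl_b$start, sgl_b$end), genome_b$genes)
  list(class = if (ra$region == rb$region) "S" else "D",
       region_a = ra, region_b = rb)
}
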