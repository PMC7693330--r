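#' Construct a multiple-sequence-alignment object
#'
#' @param ids Row identifiers.
#' @param rows Aligned strings (equal length, `-` for gaps).
#' @param alphabet `"nt"` or `"aa"`.
#' @return Object of class `msa`.
#' @export
msa <- function(ids, rows, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned rows differ in length")
  if (anyDuplicated(ids)) stop("duplicate row identifiers")
  structure(list(ids = as.character(ids), rows = toupper(as.character(rows)),
                 n_columns = nchar(rows[1]), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " rows x ", x$n_columns, " columns (",
      x$alphabet, ")\n", sep = "")
  invisible(x)
}

msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
}

#' Read an aligned FASTA file as an msa
#' @param path Aligned FASTA.
#' @param alphabet `"nt"` or `"aa"`.
#' @return An `msa`.
#' @export
read_msa <- function(path, alphabet = c("nt", "aa")) {
  set <- Biostrings::readBStringSet(path)
  msa(sub("\\s.*$", "", names(set)),
      vapply(seq_along(set), function(i) as.character(set[[i]]), ""),
      alphabet)
}

#' Write an msa to aligned FASTA
#' @param m An `msa`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(m, path) {
  set <- Biostrings::BStringSet(m$rows)
  names(set) <- m$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- progressive alignment -------------------------------------------

profile_score_matrix <- function(A, B, sub) {
  syms <- rownames(sub)
  countm <- function(P) {
    C <- matrix(0, length(syms), ncol(P))
    for (k in seq_along(syms)) C[k, ] <- colSums(P == syms[k])
    C
  }
  CA <- countm(A); CB <- countm(B)
  t(CA) %*% sub %*% CB / (nrow(A) * nrow(B))
}

merge_profiles <- function(A, B, params) {
  S <- profile_score_matrix(A, B, params$submatrix)
  res <- gotoh_matrix_cpp(S, params$gap_open, params$gap_extend)
  path <- res$path
  out <- matrix("-", nrow(A) + nrow(B), length(path))
  ia <- 0L; ib <- 0L
  for (k in seq_along(path)) {
    if (path[k] != 2L) { ia <- ia + 1L; out[seq_len(nrow(A)), k] <- A[, ia] }
    if (path[k] != 1L) { ib <- ib + 1L
      out[nrow(A) + seq_len(nrow(B)), k] <- B[, ib] }
  }
  out
}

#' Progressive multiple alignment
#'
#' A deliberately simple, fully deterministic progressive aligner: a
#' neighbor-joining guide tree on p-distances from all pairwise global
#' alignments, then profile-profile alignment with sum-of-pairs scoring
#' under the same affine gap costs (gap open 10, extension 1 by default).
#' Adequate for synthetic and moderately diverged data; externally
#' computed alignments can be supplied via [read_msa()] instead.
#'
#' @param seqs Named character vector (or list) of >= 2 ungapped
#'   sequences.
#' @param params An [align_params()] (use `align_params("aa")` for
#'   proteins).
#' @return An `msa` in input row order.
#' @export
progressive_msa <- function(seqs, params = align_params("aa")) {
  seqs <- vapply(seqs, as.character, "")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("s", seq_along(seqs))
  if (any(!nzchar(seqs))) stop("empty sequence")
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  alphabet <- if (params$alphabet == "nt") "nt" else "aa"
  if (n == 2L) {
    al <- align_global(seqs[1], seqs[2], params)
    return(msa(names(seqs), c(al$row_a, al$row_b), alphabet))
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cen <- divergence_census(align_global(seqs[i], seqs[j], params))
    p <- 1 - cen$identity_fraction
    d[i, j] <- d[j, i] <- p
  }
  profiles <- vector("list", 2L * n)  # indexed by tree node id
  row_ids <- vector("list", 2L * n)
  phy <- if (n == 3L) ape::unroot(ape::nj(stats::as.dist(d)))
         else ape::nj(stats::as.dist(d))
  phy <- stats::reorder(phy, "postorder")
  for (k in seq_len(n)) {
    profiles[[k]] <- matrix(chars(seqs[phy$tip.label[k]][[1]]), nrow = 1)
    row_ids[[k]] <- phy$tip.label[k]
  }
  for (node in unique(phy$edge[, 1])) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    prof <- profiles[[kids[1]]]
    ids <- row_ids[[kids[1]]]
    for (kid in kids[-1]) {
      prof <- merge_profiles(prof, profiles[[kid]], params)
      ids <- c(ids, row_ids[[kid]])
    }
    profiles[[node]] <- prof
    row_ids[[node]] <- ids
  }
  root <- phy$edge[nrow(phy$edge), 1]
  prof <- profiles[[root]]; ids <- row_ids[[root]]
  ord <- match(names(seqs), ids)
  msa(names(seqs), apply(prof[ord, , drop = FALSE], 1, paste, collapse = ""),
      alphabet)
}

#' Per-column conservation of an alignment
#'
#' Fraction of non-gap rows carrying the modal non-gap symbol; all-gap
#' columns score 0.  Invariant to row order.
#'
#' @param m An `msa`.
#' @return Numeric vector of length `n_columns`, values in `[0, 1]`.
#' @export
conservation_profile <- function(m) {
  M <- msa_matrix(m)
  apply(M, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  })
}

#' Locate a motif in a sequence or alignment row
#'
#' `X` in the pattern is a single-residue wildcard.  Matches may overlap.
#' On a gapped alignment row the motif is searched in the ungapped
#' sequence and the corresponding alignment-column span of each match is
#' attached as the `columns` attribute (1-based inclusive).
#'
#' @param x Sequence or alignment row (string).
#' @param pattern Motif, e.g. `"GPGA"` or `"GXFRESCG"`.
#' @return Integer vector of 1-based match start positions in the
#'   ungapped sequence.
#' @export
find_motif <- function(x, pattern) {
  if (!nzchar(pattern)) stop("empty pattern")
  x <- toupper(x); pattern <- toupper(pattern)
  cx <- chars(x)
  nongap <- which(cx != "-")
  plain <- paste(cx[nongap], collapse = "")
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, plain, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    out <- integer()
    attr(out, "columns") <- matrix(integer(), 0, 2,
                                   dimnames = list(NULL, c("from", "to")))
    return(out)
  }
  pos <- as.integer(m)
  cols <- cbind(from = nongap[pos],
                to = nongap[pos + nchar(pattern) - 1L])
  structure(pos, columns = cols)
}

#' Project an embedded ORF onto protein-alignment columns
#'
#' Maps a nucleotide interval inside a gene to the codon interval
#' `[floor((start-gs)/3), ceiling((end-gs)/3))` relative to the gene
#' start, then through the alignment row's gap pattern to alignment
#' columns.
#'
#' @param orf_nt_interval 0-based half-open genome interval `c(start,
#'   end)`.
#' @param gene_annotation One-row gene table entry (0-based `start`,
#'   `end`) or a list with those fields.
#' @param msa_row Aligned row (string) whose ungapped sequence is the
#'   gene's translation.
#' @param gene_nt Optional gene nucleotide sequence; when supplied the
#'   row is checked against its translation.
#' @return 0-based half-open alignment column interval `c(from, to)`.
#' @export
project_orf_to_alignment <- function(orf_nt_interval, gene_annotation,
                                     msa_row, gene_nt = NULL) {
  a <- as.integer(orf_nt_interval[1]); b <- as.integer(orf_nt_interval[2])
  gs <- as.integer(gene_annotation$start); ge <- as.integer(gene_annotation$end)
  if (a < gs || b > ge) stop("ORF [", a, ",", b, ") not inside gene [",
                             gs, ",", ge, ")")
  row_chars <- chars(toupper(msa_row))
  res_cols <- which(row_chars != "-")
  nres <- length(res_cols)
  if (!is.null(gene_nt)) {
    tr <- as.character(translate_cds(gene_nt, as_initiator = TRUE))
    if (tr != paste(row_chars[res_cols], collapse = ""))
      stop("alignment row does not match the gene translation")
  }
  cs <- (a - gs) %/% 3L
  ce <- as.integer(ceiling((b - gs) / 3))
  ce <- min(ce, nres)  # an ORF ending in the gene's stop codon
  if (cs >= nres) stop("ORF codon interval outside the aligned protein")
  c(res_cols[cs + 1L] - 1L, res_cols[ce])
}

# ---- trees ------------------------------------------------------------

#' Pairwise distance matrix from an alignment
#'
#' p-distance (fraction of differing columns, pairwise deletion of gap
#' columns) or its Jukes-Cantor correction.
#'
#' @param m An `msa`.
#' @param model `"p"` or `"JC"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
msa_distances <- function(m, model = c("p", "JC")) {
  model <- match.arg(model)
  M <- msa_matrix(m)
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    p <- if (any(ok)) mean(M[i, ok] != M[j, ok]) else 0
    if (model == "JC") p <- -3 / 4 * log(1 - 4 / 3 * min(p, 0.749))
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero and flagged through the `clamped`
#' attribute.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal, n >= 3,
#'   with row/col names as taxon labels.
#' @return An \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("need a square matrix with at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  phy <- ape::nj(stats::as.dist(d))
  clamped <- any(phy$edge.length < 0)
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- clamped
  phy
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates recovering its bipartition.  Supports are
#' stored in `tree$node.label` (root label empty).
#'
#' @param m An `msa` with >= 4 rows.
#' @param n Number of replicates (default 1000).
#' @param seed RNG seed (reproducible supports).
#' @param model Distance model passed to [msa_distances()].
#' @return The NJ tree (`phylo`) with `node.label` supports in 0..100.
#' @export
bootstrap_support <- function(m, n = 1000L, seed = 1L, model = "p") {
  if (length(m$ids) < 4L) stop("need at least 4 rows")
  if (n <= 0L) stop("n must be positive")
  M <- msa_matrix(m)
  base_msa_from <- function(cols) {
    msa(m$ids, apply(M[, cols, drop = FALSE], 1, paste, collapse = ""),
        m$alphabet)
  }
  tree <- nj_tree(msa_distances(m, model))
  set.seed(as.integer(seed))
  reps <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    reps[[b]] <- nj_tree(msa_distances(base_msa_from(cols), model))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / n, 1)
  tree
}

#' Extract supported clades from a tree
#'
#' Reports the internal edges whose bootstrap support strictly exceeds
#' `cutoff`, as leaf sets.  The tree is rooted at `outgroup` (default:
#' its first tip) so each internal edge maps to one leaf set.  With
#' `maximal = TRUE` supported sets nested inside another supported set
#' are dropped; the default reports every supported edge, because on a
#' poorly resolved backbone a weakly supported superset would otherwise
#' mask a strongly supported clade nested within it.
#'
#' @param tree `phylo` with numeric `node.label` supports (see
#'   [bootstrap_support()]).
#' @param cutoff Support threshold in 0..100 (strict inequality).
#' @param outgroup Tip label used to orient the tree.
#' @param maximal Keep only clades not nested in another supported clade.
#' @return List of character vectors (sorted leaf labels); each has a
#'   `support` attribute.
#' @export
clades_at_support <- function(tree, cutoff, outgroup = NULL,
                              maximal = FALSE) {
  if (cutoff < 0 || cutoff > 100) stop("cutoff must be in 0..100")
  if (is.null(tree$node.label)) stop("tree has no support labels")
  if (is.null(outgroup)) outgroup <- tree$tip.label[1]
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  supports <- suppressWarnings(as.numeric(rooted$node.label))
  parts <- ape::prop.part(rooted)
  labels <- attr(parts, "labels")
  ntip <- length(rooted$tip.label)
  keep <- list()
  for (k in seq_along(parts)) {
    node <- ntip + k
    if (node == ntip + 1L) next           # root
    sup <- supports[k]
    if (is.na(sup) || sup <= cutoff) next
    leaves <- sort(labels[parts[[k]]])
    if (length(leaves) <= 1L || length(leaves) >= ntip) next
    keep[[length(keep) + 1L]] <- structure(leaves, support = sup)
  }
  if (!length(keep) || !maximal) return(keep)
  top <- rep(TRUE, length(keep))
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (i != j && top[i] && length(keep[[i]]) < length(keep[[j]]) &&
        all(keep[[i]] %in% keep[[j]]))
      top[i] <- FALSE
  }
  keep[top]
}
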