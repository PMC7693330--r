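#' Alignment parameters
#'
#' Defaults follow the conventions of the tools the analysis mirrors:
#' nucleotide matches score +5 / mismatches -4 (EDNAFULL-equivalent),
#' proteins use BLOSUM62, and an affine gap of length k costs
#' `gap_open + gap_extend * (k - 1)` with gap open 10 and extension 1.
#'
#' @param alphabet `"nt"` or `"aa"`.
#' @param gap_open,gap_extend Affine gap costs (positive).
#' @param match,mismatch Nucleotide scores (ignored for `"aa"`).
#' @param end_gap_free Leave terminal gaps unpenalised in global mode.
#' @return List of class `align_params`.
#' @export
align_params <- function(alphabet = c("nt", "aa"), gap_open = 10,
                         gap_extend = 1, match = 5, mismatch = -4,
                         end_gap_free = FALSE) {
  alphabet <- match.arg(alphabet)
  sub <- if (alphabet == "nt") nt_submatrix(match, mismatch) else aa_submatrix()
  structure(list(alphabet = alphabet, gap_open = gap_open,
                 gap_extend = gap_extend, submatrix = sub,
                 matrix_id = if (alphabet == "nt") "EDNAFULL+5/-4"
                             else "BLOSUM62",
                 end_gap_free = isTRUE(end_gap_free)),
            class = "align_params")
}

build_alignment <- function(a, b, res, params, mode,
                            id_a = "a", id_b = "b") {
  path <- res$path
  ca <- chars(a); cb <- chars(b)
  ia <- res$a_start; ib <- res$b_start
  ra <- character(length(path)); rb <- character(length(path))
  pa <- ia; pb <- ib
  for (k in seq_along(path)) {
    if (path[k] == 0L) { pa <- pa + 1L; pb <- pb + 1L
      ra[k] <- ca[pa]; rb[k] <- cb[pb]
    } else if (path[k] == 1L) { pa <- pa + 1L
      ra[k] <- ca[pa]; rb[k] <- "-"
    } else { pb <- pb + 1L
      ra[k] <- "-"; rb[k] <- cb[pb] }
  }
  structure(list(id_a = id_a, id_b = id_b,
                 row_a = paste(ra, collapse = ""),
                 row_b = paste(rb, collapse = ""),
                 score = res$score, matrix_id = params$matrix_id,
                 gap_open = params$gap_open, gap_extend = params$gap_extend,
                 mode = mode,
                 a_range = c(res$a_start, res$a_end),
                 b_range = c(res$b_start, res$b_end)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$mode, ", score ", x$score,
      " (", x$matrix_id, ", gap ", x$gap_open, "/", x$gap_extend, ")\n",
      sep = "")
  w <- 60L
  n <- nchar(x$row_a)
  for (o in seq(1L, max(n, 1L), by = w)) {
    cat(substr(x$row_a, o, min(o + w - 1L, n)), "\n")
    cat(substr(x$row_b, o, min(o + w - 1L, n)), "\n\n")
  }
  invisible(x)
}

align_encode <- function(x, params) {
  encode_seq(toupper(x), rownames(params$submatrix))
}

#' Optimal global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Deterministic traceback tie-break: diagonal, then up (gap in `b`), then
#' left.  Terminal gaps are penalised unless `params$end_gap_free`.
#'
#' @param a,b Sequences (strings).
#' @param params An [align_params()].
#' @param id_a,id_b Sequence identifiers carried into the result.
#' @return A `pairwise_alignment`.
#' @export
align_global <- function(a, b, params = align_params(),
                         id_a = "a", id_b = "b") {
  stopifnot(nzchar(a), nzchar(b))
  res <- gotoh_pair_cpp(align_encode(a, params), align_encode(b, params),
                        params$submatrix, params$gap_open, params$gap_extend,
                        FALSE, params$end_gap_free)
  build_alignment(toupper(a), toupper(b), res, params, "global", id_a, id_b)
}

#' Optimal local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' The empty alignment (score 0) is returned when no positive-scoring
#' segment pair exists.
#'
#' @inheritParams align_global
#' @return A `pairwise_alignment` with the aligned segment coordinates
#'   (0-based half-open) in `a_range` / `b_range`.
#' @export
align_local <- function(a, b, params = align_params(),
                        id_a = "a", id_b = "b") {
  stopifnot(nzchar(a), nzchar(b))
  res <- gotoh_pair_cpp(align_encode(a, params), align_encode(b, params),
                        params$submatrix, params$gap_open, params$gap_extend,
                        TRUE, FALSE)
  build_alignment(toupper(a), toupper(b), res, params, "local", id_a, id_b)
}

#' Re-score an alignment from its columns
#'
#' Sums substitution scores over aligned columns and affine costs over gap
#' runs; used as a consistency check against the DP score.
#'
#' @param alignment A `pairwise_alignment`.
#' @param params Matching [align_params()].
#' @return Numeric score.
#' @export
score_alignment <- function(alignment, params = align_params()) {
  ra <- chars(alignment$row_a); rb <- chars(alignment$row_b)
  stopifnot(length(ra) == length(rb))
  sub <- params$submatrix
  score <- 0
  for (run in gap_runs(ra)) score <- score -
    (params$gap_open + (unname(run["len"]) - 1) * params$gap_extend)
  for (run in gap_runs(rb)) score <- score -
    (params$gap_open + (unname(run["len"]) - 1) * params$gap_extend)
  both <- ra != "-" & rb != "-"
  if (any(both))
    score <- score + sum(sub[cbind(ra[both], rb[both])])
  score
}

# maximal runs of '-' in a character vector; list of c(start, len), 1-based
gap_runs <- function(x) {
  r <- rle(x == "-")
  out <- list()
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) out[[length(out) + 1L]] <- c(start = pos,
                                                  len = r$lengths[k])
    pos <- pos + r$lengths[k]
  }
  out
}

#' Dot plot of two sequences (dotmatcher semantics)
#'
#' Every placement of a `window`-long diagonal window whose summed pairwise
#' substitution score reaches `threshold` contributes its midpoint.  The
#' scan is plus-strand only.
#'
#' @param a,b Sequences.
#' @param window Window length (default 40).
#' @param threshold Minimum summed window score (default 50).
#' @param params An [align_params()] supplying the substitution matrix.
#' @return Object of class `dot_plot`: list with `points` (two-column
#'   matrix of 0-based window-midpoint coordinates), `window`, `threshold`,
#'   `matrix_id`, `n_a`, `n_b`.
#' @export
dotplot <- function(a, b, window = 40L, threshold = 50,
                    params = align_params()) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (nchar(a) < window || nchar(b) < window)
    stop("window (", window, ") larger than a sequence (",
         nchar(a), ", ", nchar(b), ")")
  pts <- dotplot_cpp(align_encode(a, params), align_encode(b, params),
                     params$submatrix, window, threshold)
  structure(list(points = pts, window = window, threshold = threshold,
                 matrix_id = params$matrix_id,
                 n_a = nchar(a), n_b = nchar(b)),
            class = "dot_plot")
}

#' @export
print.dot_plot <- function(x, ...) {
  cat("<dot_plot> ", nrow(x$points), " points (window ", x$window,
      ", threshold ", x$threshold, ", ", x$n_a, " x ", x$n_b, ")\n", sep = "")
  invisible(x)
}

#' All-vs-all dot-plot grid (MIST-style NxN)
#'
#' Computes the dot plot of every ordered genome pair; symmetry is
#' exploited (the (j,i) plot is the transpose of the (i,j) plot).
#'
#' @param genomes List of `genome_record` (>= 2).
#' @param window,threshold,params As in [dotplot()].
#' @param out_dir Optional directory: per-pair point TSVs plus an
#'   `index.tsv` are written there.
#' @return Named list (names `"idA|idB"`) of `dot_plot` objects covering
#'   all ordered pairs including self-pairs.
#' @export
mist_matrix <- function(genomes, window = 40L, threshold = 50,
                        params = align_params(), out_dir = NULL) {
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  out <- list()
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    key <- paste0(ids[i], "|", ids[j])
    if (j < i) {
      tp <- out[[paste0(ids[j], "|", ids[i])]]
      pts <- tp$points[, c(2L, 1L), drop = FALSE]
      colnames(pts) <- c("i", "j")
      out[[key]] <- structure(
        list(points = pts, window = tp$window, threshold = tp$threshold,
             matrix_id = tp$matrix_id, n_a = tp$n_b, n_b = tp$n_a),
        class = "dot_plot")
    } else {
      out[[key]] <- dotplot(genomes[[i]]$sequence, genomes[[j]]$sequence,
                            window, threshold, params)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    idx <- data.frame(id_a = rep(ids, each = length(ids)),
                      id_b = rep(ids, times = length(ids)))
    idx$file <- paste0("dotplot_", idx$id_a, "_", idx$id_b, ".tsv")
    idx$n_points <- vapply(paste0(idx$id_a, "|", idx$id_b),
                           function(k) nrow(out[[k]]$points), 0L)
    utils::write.table(idx, file.path(out_dir, "index.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (r in seq_len(nrow(idx)))
      utils::write.table(
        out[[paste0(idx$id_a[r], "|", idx$id_b[r])]]$points,
        file.path(out_dir, idx$file[r]),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Substitution and indel census of a global alignment
#'
#' Substitutions are mismatched both-aligned columns; each maximal run of
#' gap characters in either row is one indel event of its run length.
#' Identity is computed over both-aligned (non-gap) columns.
#'
#' @param alignment A global `pairwise_alignment`.
#' @return List of class `divergence_census`: `substitutions`, `matches`,
#'   `indel_events` (integer lengths, 5'->3', row a then row b),
#'   `identity_fraction`, `min_indel`, `max_indel`, `alignment_length`.
#' @export
divergence_census <- function(alignment) {
  ra <- chars(alignment$row_a); rb <- chars(alignment$row_b)
  stopifnot(length(ra) == length(rb))
  if (any(ra == "-" & rb == "-")) stop("column with two gaps")
  both <- ra != "-" & rb != "-"
  subs <- sum(both & ra != rb)
  matches <- sum(both & ra == rb)
  ev <- c(vapply(gap_runs(ra), `[`, 0, "len"),
          vapply(gap_runs(rb), `[`, 0, "len"))
  ev <- as.integer(ev)
  structure(list(substitutions = subs, matches = matches,
                 indel_events = ev,
                 identity_fraction = if (sum(both)) matches / sum(both) else NA_real_,
                 min_indel = if (length(ev)) min(ev) else NA_integer_,
                 max_indel = if (length(ev)) max(ev) else NA_integer_,
                 alignment_length = length(ra)),
            class = "divergence_census")
}

#' @export
print.divergence_census <- function(x, ...) {
  cat("<divergence_census> ", x$substitutions, " substitutions, ",
      length(x$indel_events), " indel event(s)",
      if (length(x$indel_events))
        paste0(" (", x$min_indel, "-", x$max_indel, " bp)"),
      ", identity ", round(100 * x$identity_fraction, 1), "%\n", sep = "")
  invisible(x)
}

#' Annotate point mutations between two same-length ORFs
#'
#' Labels follow the field's convention: nucleotide changes as lowercase
#' `<base><1-based position><base>` (e.g. `g15t`) and amino-acid changes
#' as `<AA><1-based codon><AA>` (e.g. `A52D`); silent changes carry an
#' empty amino-acid label.  Classification (silent / missense / nonsense)
#' is per codon, using the full mutant codon.
#'
#' @param wt_orf_nt,mut_orf_nt Equal-length in-frame nucleotide sequences
#'   (indel-containing mutants are out of scope).
#' @return data.frame with columns `nt_pos`, `nt_label`, `codon`,
#'   `aa_label`, `kind`; zero rows when the sequences are identical.
#' @export
annotate_mutations <- function(wt_orf_nt, mut_orf_nt) {
  wt <- toupper(wt_orf_nt); mu <- toupper(mut_orf_nt)
  if (nchar(wt) != nchar(mu))
    stop("sequences differ in length (", nchar(wt), " vs ", nchar(mu), ")")
  if (nchar(wt) %% 3L != 0L) stop("ORF length not divisible by 3")
  cw <- chars(wt); cm <- chars(mu)
  diffs <- which(cw != cm)
  if (!length(diffs))
    return(data.frame(nt_pos = integer(), nt_label = character(),
                      codon = integer(), aa_label = character(),
                      kind = character(), stringsAsFactors = FALSE))
  gc <- genetic_code()
  out <- lapply(diffs, function(p) {
    cod <- (p - 1L) %/% 3L + 1L
    from <- 3L * (cod - 1L) + 1L
    wt_cod <- substr(wt, from, from + 2L)
    mu_cod <- substr(mu, from, from + 2L)
    wt_aa <- unname(gc[wt_cod]); mu_aa <- unname(gc[mu_cod])
    kind <- if (wt_aa == mu_aa) "silent"
            else if (mu_aa == "*") "nonsense" else "missense"
    data.frame(
      nt_pos = p,
      nt_label = paste0(tolower(cw[p]), p, tolower(cm[p])),
      codon = cod,
      aa_label = if (kind == "silent") "" else paste0(wt_aa, cod, mu_aa),
      kind = kind, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
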