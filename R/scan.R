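#' Screening criteria configuration
#'
#' The screen keeps ORFs that (i) encode at least `min_codons` amino acids
#' (stop excluded), (ii) carry an upstream Shine-Dalgarno-like motif --
#' operationalised as at least `sd_min_core` contiguous positional matches
#' to the `AGGAGG` consensus placed 4..16 nt upstream of the start codon --
#' and (iii) contain a hydrophobic, transmembrane-like stretch: a
#' `kd_window`-residue window whose mean Kyte-Doolittle hydropathy reaches
#' `kd_threshold`.  Relaxed thresholds drive the relaxed screening mode in
#' [apply_criteria()].
#'
#' @param min_codons Minimum protein length in amino acids (strict).
#' @param start_codons Accepted start codons.
#' @param sd_min_core Minimum contiguous match to AGGAGG (strict).
#' @param sd_spacer_range Allowed spacer (nt between SD core 3' end and the
#'   start codon), inclusive range.
#' @param kd_window Hydropathy window in residues.
#' @param kd_threshold Minimum windowed mean Kyte-Doolittle score (strict).
#' @param relaxed_min_codons,relaxed_sd_min_core,relaxed_kd_threshold
#'   Relaxed-mode thresholds.
#' @param require_stop Drop ORFs lacking an in-frame stop (set `FALSE` for
#'   partial contigs).
#' @return A list of class `criteria_config`.
#' @export
criteria_config <- function(min_codons = 25L,
                            start_codons = c("ATG", "GTG", "TTG"),
                            sd_min_core = 4L,
                            sd_spacer_range = c(4L, 16L),
                            kd_window = 19L,
                            kd_threshold = 1.6,
                            relaxed_min_codons = 10L,
                            relaxed_sd_min_core = 3L,
                            relaxed_kd_threshold = 1.0,
                            require_stop = TRUE) {
  stopifnot(min_codons > 0, sd_min_core > 0, kd_window > 0, kd_threshold > 0,
            relaxed_min_codons > 0, relaxed_sd_min_core > 0,
            relaxed_kd_threshold > 0,
            length(sd_spacer_range) == 2L,
            sd_spacer_range[1] <= sd_spacer_range[2],
            sd_spacer_range[1] >= 0)
  structure(list(min_codons = as.integer(min_codons),
                 start_codons = toupper(start_codons),
                 sd_min_core = as.integer(sd_min_core),
                 sd_spacer_range = as.integer(sd_spacer_range),
                 kd_window = as.integer(kd_window),
                 kd_threshold = kd_threshold,
                 relaxed_min_codons = as.integer(relaxed_min_codons),
                 relaxed_sd_min_core = as.integer(relaxed_sd_min_core),
                 relaxed_kd_threshold = relaxed_kd_threshold,
                 require_stop = isTRUE(require_stop)),
            class = "criteria_config")
}

#' Enumerate open reading frames on the plus strand
#'
#' Scans all three plus-strand frames.  Each maximal ORF per (frame, stop)
#' is reported once at its 5'-most qualifying start codon; with
#' `all_starts = TRUE` every alternate downstream start is listed as well.
#' ORFs lacking an in-frame stop (running off the 3' end) are reported only
#' when `config$require_stop` is `FALSE`, with `has_stop = FALSE`.
#' Intervals are 0-based half-open and include the stop codon.
#'
#' @param genome A `genome_record` or a nucleotide string.
#' @param config A [criteria_config()].
#' @param all_starts Also report nested same-frame alternate starts.
#' @return Candidate table with screening flags unset (`NA`).
#' @export
find_orfs <- function(genome, config = criteria_config(), all_starts = FALSE) {
  if (is.character(genome)) genome <- genome_record("seq", genome)
  s <- genome$sequence
  n <- nchar(s)
  rows <- list()
  for (frame in 0:2) {
    if (frame + 3L > n) next
    starts_at <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts_at, starts_at + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% config$start_codons
    if (!any(is_start)) next
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    seg_from <- c(1L, stop_idx + 1L)       # first codon index of each segment
    seg_stop <- c(stop_idx, NA_integer_)   # terminating stop codon index
    for (k in seq_along(seg_from)) {
      lo <- seg_from[k]; st <- seg_stop[k]
      hi <- if (is.na(st)) length(codons) else st - 1L
      if (hi < lo) next
      cand <- start_idx[start_idx >= lo & start_idx <= hi]
      if (!length(cand)) next
      if (is.na(st) && config$require_stop) next
      use <- if (all_starts) cand else cand[1]
      for (ci in use) {
        a <- starts_at[ci] - 1L                       # 0-based start
        b <- if (is.na(st)) starts_at[hi] + 2L else starts_at[st] + 2L
        nt <- substr(s, a + 1L, b)
        prot <- translate_cds(nt, as_initiator = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = genome$genome_id, start = a, end = b,
          frame = frame, start_codon = codons[ci],
          protein = as.character(prot),
          has_stop = attr(prot, "stop_present"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_candidate_table())
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$frame), , drop = FALSE]
  as_candidate_table(df)
}

#' Score the Shine-Dalgarno context of an ORF start
#'
#' For every spacer in `config$sd_spacer_range`, the 6-nt window ending
#' `spacer` nt upstream of the start codon is compared position-by-position
#' with the `AGGAGG` anti-SD consensus; the score is the longest contiguous
#' run of identities over all spacer placements.  The window is truncated
#' (padded with non-matching `N`) at the genome 5' end.
#'
#' @param genome `genome_record` or nucleotide string.
#' @param orf One candidate row (or a list with a 0-based `start`).
#' @param config A [criteria_config()].
#' @return List with `best_core_match`, `spacer`, `window_seq`, `passes`.
#' @export
score_sd <- function(genome, orf, config = criteria_config()) {
  if (is.character(genome)) genome <- genome_record("seq", genome)
  sd_score_at(genome$sequence, as.integer(orf$start), config)
}

sd_score_at <- function(seq, start0, config) {
  sp <- config$sd_spacer_range
  consensus <- chars(SD_CONSENSUS)
  win_from <- start0 - sp[2] - 6L            # 0-based, may be negative
  win_chars <- character(start0 - win_from)
  for (i in seq_along(win_chars)) {
    p <- win_from + i - 1L
    win_chars[i] <- if (p < 0L) "N" else substr(seq, p + 1L, p + 1L)
  }
  best <- 0L; best_spacer <- NA_integer_
  for (s in sp[1]:sp[2]) {
    hex_from <- start0 - s - 6L
    off <- hex_from - win_from
    hex <- win_chars[(off + 1L):(off + 6L)]
    run <- 0L; mx <- 0L
    for (k in 1:6) {
      if (identical(hex[k], consensus[k])) run <- run + 1L else run <- 0L
      if (run > mx) mx <- run
    }
    if (mx > best) { best <- mx; best_spacer <- s }
  }
  list(best_core_match = best, spacer = best_spacer,
       window_seq = paste(win_chars, collapse = ""),
       passes = best >= config$sd_min_core)
}

#' Predict a transmembrane-like hydrophobic segment
#'
#' Slides a `config$kd_window`-residue window over the protein computing
#' mean Kyte-Doolittle hydropathy; returns the maximum and its segment
#' (1-based inclusive residue coordinates).  Proteins shorter than the
#' window are scored with a single full-length window and flagged
#' `short_window`.
#'
#' @param protein Amino-acid string (no stop).
#' @param config A [criteria_config()].
#' @return List with `max_window_hydropathy`, `segment`, `window_size`,
#'   `short_window`, `passes`.
#' @export
predict_tmd <- function(protein, config = criteria_config()) {
  aa <- chars(protein)
  if (!length(aa)) stop("empty protein")
  kd <- unname(KD_HYDROPATHY[aa])
  if (anyNA(kd)) {
    bad <- which(is.na(kd))[1]
    stop("unknown residue '", aa[bad], "' at position ", bad)
  }
  w <- min(config$kd_window, length(kd))
  cs <- c(0, cumsum(kd))
  means <- (cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]) / w
  i <- which.max(means)
  list(max_window_hydropathy = means[i],
       segment = c(i, i + w - 1L),
       window_size = w,
       short_window = w < config$kd_window,
       passes = means[i] >= config$kd_threshold)
}

#' Apply the three screening criteria
#'
#' Strict mode keeps candidates passing all three criteria (length, SD,
#' TMD).  Relaxed mode keeps candidates failing at most one criterion
#' under the relaxed thresholds; the `relaxed_fail` column names the
#' strict criteria a retained candidate misses (`no_RBS`, `no_TMD`,
#' `short`, comma-joined; `none` when all strict criteria hold).
#'
#' @param candidates Candidate table with `sd_best` and `kd_max` populated
#'   (see [scan_genome()]).
#' @param config A [criteria_config()].
#' @param mode `"strict"` or `"relaxed"`.
#' @return Filtered candidate table with all flags recorded.
#' @export
apply_criteria <- function(candidates, config = criteria_config(),
                           mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  df <- as_candidate_table(candidates)
  if (!nrow(df)) return(df)
  if (anyNA(df$sd_best) || anyNA(df$kd_max))
    stop("SD and TMD scores must be populated before apply_criteria()")
  plen <- nchar(df$protein)
  df$len_pass <- plen >= config$min_codons
  df$sd_pass <- df$sd_best >= config$sd_min_core
  df$tmd_pass <- df$kd_max >= config$kd_threshold
  df$strict_pass <- df$len_pass & df$sd_pass & df$tmd_pass
  fails <- cbind(short = !df$len_pass, no_RBS = !df$sd_pass,
                 no_TMD = !df$tmd_pass)
  df$relaxed_fail <- apply(fails, 1, function(f)
    if (any(f)) paste(colnames(fails)[f], collapse = ",") else "none")
  if (mode == "strict") return(df[df$strict_pass, , drop = FALSE])
  r_len <- plen >= config$relaxed_min_codons
  r_sd <- df$sd_best >= config$relaxed_sd_min_core
  r_tmd <- df$kd_max >= config$relaxed_kd_threshold
  n_relaxed_fail <- (!r_len) + (!r_sd) + (!r_tmd)
  df[n_relaxed_fail <= 1L, , drop = FALSE]
}

#' Scan a genome for sgl candidates
#'
#' Convenience wrapper: [find_orfs()], then [score_sd()] and
#' [predict_tmd()] per ORF, then [apply_criteria()], then (when core genes
#' are annotated) genomic-context assignment via [classify_region()].
#'
#' @param genome A `genome_record`.
#' @param config A [criteria_config()].
#' @param mode `"strict"` or `"relaxed"`.
#' @param classify Assign 18-region genomic context when mat/coat/rep are
#'   annotated.
#' @return Candidate table.
#' @export
scan_genome <- function(genome, config = criteria_config(),
                        mode = c("strict", "relaxed"), classify = TRUE) {
  mode <- match.arg(mode)
  df <- find_orfs(genome, config)
  if (!nrow(df)) return(df)
  for (i in seq_len(nrow(df))) {
    sd <- sd_score_at(genome$sequence, df$start[i], config)
    df$sd_best[i] <- sd$best_core_match
    df$sd_spacer[i] <- if (is.na(sd$spacer)) NA_integer_ else sd$spacer
    df$sd_window[i] <- sd$window_seq
    tm <- predict_tmd(df$protein[i], config)
    df$kd_max[i] <- tm$max_window_hydropathy
    df$kd_start[i] <- tm$segment[1]
    df$kd_end[i] <- tm$segment[2]
    df$kd_window[i] <- tm$window_size
    df$kd_short[i] <- tm$short_window
  }
  df <- apply_criteria(df, config, mode)
  if (classify && nrow(df) &&
      all(c("mat", "coat", "rep") %in% genome$genes$gene_name)) {
    for (i in seq_len(nrow(df))) {
      ra <- classify_region(c(df$start[i], df$end[i]), genome$genes)
      df$region[i] <- ra$region
      df$host_gene[i] <- ra$host_gene
      df$frame_offset[i] <- ra$frame_offset
    }
  }
  df
}
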