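# Cohorts with planted clade structure and S/D genome pairs.

#' Cohort structure configuration
#'
#' @param clade_size Members of the planted clade (diverged from a shared
#'   ancestor).
#' @param clade_sub_rate,clade_indel_rate Within-clade divergence rates.
#' @param n_s_pairs,n_d_pairs Number of S-class (same sgl context) and
#'   D-class (relocated sgl) genome pairs.
#' @param pair_sub_rate,pair_indel_rate Within-pair divergence rates.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(clade_size = 12L, clade_sub_rate = 0.02,
                          clade_indel_rate = 0.001,
                          n_s_pairs = 1L, n_d_pairs = 1L,
                          pair_sub_rate = 0.08, pair_indel_rate = 0.002) {
  structure(list(clade_size = as.integer(clade_size),
                 clade_sub_rate = clade_sub_rate,
                 clade_indel_rate = clade_indel_rate,
                 n_s_pairs = as.integer(n_s_pairs),
                 n_d_pairs = as.integer(n_d_pairs),
                 pair_sub_rate = pair_sub_rate,
                 pair_indel_rate = pair_indel_rate),
            class = "cohort_config")
}

# rewrite a window of an existing genome under sgl-frame constraints;
# returns the modified sequence (character scalar) or NULL if infeasible.
rewrite_window <- function(genome, grid_org, lay, offset,
                           unary_extra = NULL) {
  s <- chars(genome$sequence)
  genes <- genome$genes
  gc <- genetic_code()
  win_lo <- min(lay$window[1], min(lay$q) - 3L)
  u_from <- (win_lo - grid_org) %/% 3L
  u_to <- (lay$window[2] - 1L - grid_org) %/% 3L + 1L
  K <- u_to - u_from
  if (grid_org + 3L * u_from < 0L ||
      grid_org + 3L * (u_from + K) > length(s)) return(NULL)
  cost <- matrix(NA_real_, 64, K)
  for (u in seq_len(K)) {
    slot <- grid_org + 3L * (u_from + u - 1L)
    cod <- paste(s[(slot + 1L):(slot + 3L)], collapse = "")
    gi <- which(genes$start <= slot & slot + 3L <= genes$end &
                  genes$gene_name %in% c("mat", "coat", "rep"))
    if (length(gi)) {
      g <- gi[1]
      if ((slot - genes$start[g]) %% 3L != 0L) return(NULL)
      ci <- (slot - genes$start[g]) %/% 3L + 1L
      n_cod <- (genes$end[g] - genes$start[g]) %/% 3L
      aa <- gc[cod]
      if (ci == 1L || ci >= n_cod || is.na(aa) || aa == "*") {
        cost[, u] <- cost_fixed(cod)
      } else {
        cost[, u] <- cost_gene(unname(aa), current = cod)
      }
    } else {
      cost[, u] <- cost_free()
    }
  }
  unary <- rbind(lay$unary, unary_extra)
  if (!is.null(unary)) for (r in seq_len(nrow(unary))) {
    pos <- unary$pos[r]
    u <- (pos - grid_org) %/% 3L - u_from + 1L
    if (u < 1L || u > K) next
    cost[, u] <- apply_unary(
      cost[, u], pos - (grid_org + 3L * (u_from + u - 1L)) + 1L,
      chars(unary$chars[r]))
  }
  classes <- rep("any", K - 1L)
  for (ii in seq_along(lay$q)) {
    b <- (lay$q[ii] - grid_org) %/% 3L - u_from + 1L
    if (b < 1L || b > K - 1L) return(NULL)
    classes[b] <- lay$class[ii]
  }
  sol <- dp_solve(cost, classes, offset)
  if (is.null(sol)) return(NULL)
  for (u in seq_len(K)) {
    slot <- grid_org + 3L * (u_from + u - 1L)
    s[(slot + 1L):(slot + 3L)] <- chars(sol$codons[u])
  }
  paste(s, collapse = "")
}

# disable an existing planted sgl in place: remove its start codon and
# interrupt the reading frame with stops every 20 codons, leaving the
# rest of the sequence (SD, hydrophobic stretch) as a detectable remnant
degrade_sgl <- function(genome, sgl_row, grid_org) {
  p <- sgl_row$start
  n <- sgl_row$n_codons
  q <- c(p, p + 3L * (seq.int(2L, n, by = 20L) - 1L), p + 3L * n)
  class <- c("nostart", rep("stop", length(q) - 2L), "stop")
  lay <- list(q = q, class = class, unary = NULL,
              window = c(p - 3L, p + 3L * (n + 1L)))
  off <- (p - grid_org) %% 3L
  rewrite_window(genome, grid_org, lay, off)
}

# plant a fresh sgl into gene `gene_i` of an existing genome (region 4 or
# 16); returns list(seq, start, end) or NULL
replant_sgl <- function(genome, gene_i, n, offset, spacer, avoid) {
  g <- genome$genes[gene_i, ]
  total <- 3L * (n + 1L)
  k_max <- (g$end - 3L - g$start - total - offset) %/% 3L - 1L
  if (k_max < 10L) return(NULL)
  for (k2 in safe_sample(10:k_max)) {
    p <- g$start + offset + 3L * k2
    win <- c(p - 28L, p + total)
    clash <- FALSE
    for (iv in avoid)
      if (win[1] < iv[2] + 9L && iv[1] < win[2] + 9L) clash <- TRUE
    if (clash) next
    lay <- sgl_layout(p, n, spacer, "sgl")
    s2 <- rewrite_window(genome, g$start, lay, offset)
    if (is.null(s2)) next
    return(list(seq = s2, start = p, end = p + total))
  }
  NULL
}

lift_truth <- function(truth, shift_interval, new_id) {
  lift_df <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    for (i in seq_len(nrow(df))) {
      iv <- shift_interval(c(df$start[i], df$end[i]))
      df$start[i] <- iv[1]; df$end[i] <- iv[2]
    }
    df
  }
  truth$genome_id <- new_id
  truth$sgls <- lift_df(truth$sgls)
  truth$decoys <- lift_df(truth$decoys)
  truth$windows <- lift_df(truth$windows)
  truth
}

# derive a diverged copy whose truth still verifies (attempt-indexed)
derive_member <- function(parent, parent_truth, sub_rate, indel_rate,
                          seed, new_id, criteria, max_attempts = 20L) {
  protect <- parent_truth$windows
  protect_genes <- lapply(seq_len(nrow(parent$genes)), function(i)
    c(parent$genes$start[i], parent$genes$end[i]))
  for (attempt in seq_len(max_attempts)) {
    mp <- mutate_pair(parent, sub_rate, indel_rate,
                      seed = (seed + 7919L * attempt) %% 2147483629L,
                      protect = protect, protect_indels = protect_genes,
                      new_id = new_id)
    truth <- lift_truth(parent_truth, mp$shift_interval, new_id)
    truth$genes <- mp$genome$genes
    if (verify_truth(mp$genome, truth, criteria))
      return(list(genome = mp$genome, truth = truth, edit_log = mp$edit_log))
  }
  NULL
}

#' Generate a cohort with planted clade structure and S/D pairs
#'
#' Emits `n` genomes: unrelated "independent" genomes first (so default
#' tree rooting lands outside the planted structure), then `clade_size`
#' members diverged from a hidden common ancestor, then S-class pairs
#' (diverged copies sharing their sgl context) and D-class pairs, where
#' the second member's original sgl is degraded in place -- leaving a
#' locally alignable remnant -- and a new sgl is planted in a different
#' genomic region.
#'
#' @param config A [generator_config()].
#' @param n Total cohort size (>= clade_size + 2*(pairs) + 1).
#' @param seed Integer seed.
#' @param cohort A [cohort_config()].
#' @return List with `genomes` (named list of `genome_record`) and
#'   `truth` (`per_genome` truth ledgers, `clade` member ids, `pairs`
#'   records with class, sgl rows and remnant info).
#' @export
generate_cohort <- function(config = generator_config(), n = 20L,
                            seed = 1L, cohort = cohort_config()) {
  need <- cohort$clade_size + 2L * (cohort$n_s_pairs + cohort$n_d_pairs)
  n_indep <- n - need
  if (n_indep < if (need > 0L) 1L else 0L)
    stop("n = ", n, " too small for the configured cohort (need >= ",
         need + 1L, ")")
  base <- as.integer(seed) %% 1000003L
  sub_seed <- function(i) (base * 131L + i * 524287L) %% 2147483629L
  crit <- config$criteria
  # pair members carry exactly one rep-embedded sgl so the designated
  # (relocatable) sgl is unambiguous
  pair_config <- config
  pair_config$n_sgls <- c(1L, 1L)
  pair_config$sgl_regions <- 16L

  genomes <- list(); per_genome <- list()
  idx <- 0L
  add <- function(g, truth) {
    genomes[[g$genome_id]] <<- g
    per_genome[[g$genome_id]] <<- truth
  }

  for (i in seq_len(n_indep)) {
    idx <- idx + 1L
    res <- generate_genome(config, sub_seed(idx),
                           genome_id = sprintf("indep_%02d", i))
    add(res$genome, res$truth)
  }

  clade_ids <- character()
  if (cohort$clade_size > 0L) {
    idx <- idx + 1L
    anc <- generate_genome(config, sub_seed(idx), genome_id = "clade_anc")
    clade_ids <- sprintf("clade_%02d", seq_len(cohort$clade_size))
    for (j in seq_along(clade_ids)) {
      idx <- idx + 1L
      mem <- derive_member(anc$genome, anc$truth, cohort$clade_sub_rate,
                           cohort$clade_indel_rate, sub_seed(idx),
                           clade_ids[j], crit)
      if (is.null(mem)) stop("could not derive clade member ", clade_ids[j])
      add(mem$genome, mem$truth)
    }
  }

  pairs <- list()
  for (sp in seq_len(cohort$n_s_pairs)) {
    idx <- idx + 1L
    a <- generate_genome(pair_config, sub_seed(idx),
                         genome_id = sprintf("spair%d_a", sp))
    idx <- idx + 1L
    b <- derive_member(a$genome, a$truth, cohort$pair_sub_rate,
                       cohort$pair_indel_rate, sub_seed(idx),
                       sprintf("spair%d_b", sp), crit)
    if (is.null(b)) stop("could not derive S-pair member")
    add(a$genome, a$truth); add(b$genome, b$truth)
    pairs[[length(pairs) + 1L]] <- list(
      id_a = a$genome$genome_id, id_b = b$genome$genome_id, class = "S",
      sgl_a = a$truth$sgls[1, ], sgl_b = b$truth$sgls[1, ])
  }

  for (dp in seq_len(cohort$n_d_pairs)) {
    idx <- idx + 1L
    a <- generate_genome(pair_config, sub_seed(idx),
                         genome_id = sprintf("dpair%d_a", dp))
    idx <- idx + 1L
    b <- NULL
    for (attempt in seq_len(20L)) {
      b0 <- derive_member(a$genome, a$truth, cohort$pair_sub_rate,
                          cohort$pair_indel_rate,
                          (sub_seed(idx) + attempt) %% 2147483629L,
                          sprintf("dpair%d_b", dp), crit)
      if (is.null(b0)) next
      old <- b0$truth$sgls[1, ]          # rep-embedded (region 16)
      rep_row <- which(b0$genome$genes$gene_name == "rep")
      set.seed((sub_seed(idx) + 100000L * attempt) %% 2147483629L)
      s_deg <- degrade_sgl(b0$genome, old,
                           b0$genome$genes$start[rep_row])
      if (is.null(s_deg)) next
      g_deg <- genome_record(b0$genome$genome_id, s_deg,
                             genes = b0$genome$genes)
      avoid <- lapply(seq_len(nrow(b0$truth$windows)), function(i)
        c(b0$truth$windows$start[i], b0$truth$windows$end[i]))
      pl <- replant_sgl(g_deg, which(g_deg$genes$gene_name == "mat"),
                        n = rint(config$sgl_codons), offset = rint(c(1L, 2L)),
                        spacer = rint(config$spacer_range), avoid = avoid)
      if (is.null(pl)) next
      g_new <- genome_record(g_deg$genome_id, pl$seq, genes = g_deg$genes)
      new_sgl <- data.frame(start = pl$start, end = pl$end,
                            frame = pl$start %% 3L, region = 4L,
                            n_codons = (pl$end - pl$start) %/% 3L - 1L,
                            spacer = NA_integer_,
                            frame_offset = (pl$start -
                              g_new$genes$start[g_new$genes$gene_name == "mat"]) %% 3L,
                            stringsAsFactors = FALSE)
      truth_b <- b0$truth
      truth_b$sgls <- new_sgl
      truth_b$windows <- rbind(truth_b$windows,
                               data.frame(start = pl$start - 28L,
                                          end = pl$end))
      if (!verify_truth(g_new, truth_b, crit)) next
      b <- list(genome = g_new, truth = truth_b,
                remnant_interval = c(old$start, old$end))
      break
    }
    if (is.null(b)) stop("could not derive D-pair member")
    add(a$genome, a$truth); add(b$genome, b$truth)
    src <- substr(a$genome$sequence, a$truth$sgls$start[1] + 1L,
                  a$truth$sgls$end[1])
    pairs[[length(pairs) + 1L]] <- list(
      id_a = a$genome$genome_id, id_b = b$genome$genome_id, class = "D",
      sgl_a = a$truth$sgls[1, ], sgl_b = b$truth$sgls[1, ],
      remnant = list(source_seq = src, interval = b$remnant_interval))
  }

  list(genomes = genomes,
       truth = list(per_genome = per_genome, clade = clade_ids,
                    pairs = pairs))
}

#' Rep (replicase) protein sequences of a genome set
#'
#' @param genomes List of `genome_record` with `rep` annotated.
#' @return Named character vector of Rep amino-acid sequences.
#' @export
rep_proteins <- function(genomes) {
  out <- vapply(genomes, function(g)
    as.character(translate_cds(gene_seq(g, "rep"), as_initiator = TRUE)), "")
  names(out) <- vapply(genomes, `[[`, "", "genome_id")
  out
}
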