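# Synthetic levivirus-like genomes with planted dual-frame lysis ORFs.
#
# Planting works on "units": consecutive 3-nt slots on a common codon grid
# (host-gene codons, or free intergenic slots padded to the grid).  Every
# candidate codon of the planted ORF sits in a shifted frame (+1/+2) and
# therefore straddles exactly one unit boundary, so all ORF requirements
# (start codon, no internal stop, hydrophobic stretch, terminal stop, the
# guard stop / no-upstream-start region) become pairwise constraints
# between adjacent unit choices; the Shine-Dalgarno hexamer and
# composition windows are unary nucleotide constraints.  A small dynamic
# programme minimises the number of host amino-acid swaps subject to all
# constraints.

.sgl_cache <- new.env(parent = emptyenv())

HYDRO_AAS <- c("I", "V", "L", "F")            # KD >= 2.8 each
PHIL_AAS <- c("D", "E", "K", "N", "Q", "R")   # KD <= -3.5 each

codon_chars <- function() {
  if (is.null(.sgl_cache$codon_chars)) {
    cc <- do.call(rbind, strsplit(all_codons(), "", fixed = TRUE))
    rownames(cc) <- all_codons()
    .sgl_cache$codon_chars <- cc
  }
  .sgl_cache$codon_chars
}

# 64x64 logical: is the sgl-frame codon straddling a unit boundary
# (offset nt into the first unit) admissible for `class`?
compat_matrix <- function(offset, class) {
  key <- paste0("compat_", offset, "_", class)
  if (!is.null(.sgl_cache[[key]])) return(.sgl_cache[[key]])
  cods <- all_codons()
  cc <- codon_chars()
  gc <- genetic_code()
  m <- matrix(FALSE, 64, 64, dimnames = list(cods, cods))
  for (i in 1:64) for (j in 1:64) {
    sgl <- if (offset == 1L) paste0(cc[i, 2], cc[i, 3], cc[j, 1])
           else paste0(cc[i, 3], cc[j, 1], cc[j, 2])
    m[i, j] <- switch(class,
      any = TRUE,
      nostop = !(sgl %in% STOP_CODONS),
      nostart = !(sgl %in% c("ATG", "GTG", "TTG")),
      start = sgl == "ATG",
      stop = sgl %in% STOP_CODONS,
      hydro = !is.na(gc[sgl]) && gc[sgl] %in% HYDRO_AAS,
      phil = !is.na(gc[sgl]) && gc[sgl] %in% PHIL_AAS,
      stop("unknown constraint class: ", class))
  }
  .sgl_cache[[key]] <- m
  m
}

penal_matrix <- function(offset, class) {
  key <- paste0("penal_", offset, "_", class)
  if (is.null(.sgl_cache[[key]])) {
    p <- matrix(Inf, 64, 64)
    p[compat_matrix(offset, class)] <- 0
    .sgl_cache[[key]] <- p
  }
  .sgl_cache[[key]]
}

# minimise sum of per-unit choice costs subject to pairwise classes.
# cost: 64 x K matrix (Inf = disallowed); classes: length K-1.
# Ties are broken by RNG-drawn priorities (deterministic under set.seed).
dp_solve <- function(cost, classes, offset) {
  K <- ncol(cost)
  ptr <- matrix(NA_integer_, 64, K)
  f <- cost[, 1]
  if (!any(is.finite(f))) return(NULL)
  if (K > 1) for (k in 2:K) {
    tmp <- penal_matrix(offset, classes[k - 1]) + f  # rows = prev choice
    prio <- stats::runif(64)
    newf <- rep(Inf, 64)
    for (cix in which(is.finite(cost[, k]))) {
      col <- tmp[, cix]
      mn <- min(col)
      if (!is.finite(mn)) next
      cands <- which(col == mn)
      ptr[cix, k] <- cands[which.max(prio[cands])]
      newf[cix] <- mn + cost[cix, k]
    }
    f <- newf
    if (!any(is.finite(f))) return(NULL)
  }
  prio <- stats::runif(64)
  mn <- min(f)
  if (!is.finite(mn)) return(NULL)
  cands <- which(f == mn)
  ci <- integer(K)
  ci[K] <- cands[which.max(prio[cands])]
  if (K > 1) for (k in K:2) ci[k - 1] <- ptr[ci[k], k]
  list(codons = all_codons()[ci], cost = mn)
}

# per-unit choice-cost vectors ------------------------------------------

cost_free <- function() rep(0, 64)

cost_gene <- function(aa, synonymous_only = FALSE, current = NULL) {
  cods <- all_codons()
  cost <- rep(if (synonymous_only) Inf else 1, 64)
  cost[cods %in% STOP_CODONS] <- Inf
  syn <- codons_by_aa()[[aa]]
  if (!is.null(syn)) cost[cods %in% syn] <- 0
  if (!is.null(current)) {
    # minimal-perturbation mode: deviating from the existing codon at
    # all carries a small cost, so only constrained positions change
    cost[cost == 0 & cods != current] <- 1 / 1024
    cost[cods == current] <- min(cost[cods == current], 0)
  }
  cost
}

cost_fixed <- function(codon) {
  cost <- rep(Inf, 64)
  cost[match(codon, all_codons())] <- 0
  cost
}

# restrict a cost vector so nt position `pos` (1..3) is in `allowed`
apply_unary <- function(cost, pos, allowed) {
  cost[!(codon_chars()[, pos] %in% allowed)] <- Inf
  cost
}

# ---- planting layouts -------------------------------------------------

safe_sample <- function(x, n = length(x), ...) x[sample.int(length(x), n, ...)]

# sgl-frame codon classes for a planted ORF (absolute coordinates).
# Returns list(q = codon start positions, class = classes, unary =
# data.frame(pos, chars)).  p: ORF start; n: protein length in aa.
# tmd_tail puts the hydrophobic stretch at the C-terminal end (used when
# the ORF spans the coat/rep boundary and its 5' half is constrained).
sgl_layout <- function(p, n, spacer, kind = c("sgl", "no_RBS", "no_TMD"),
                       tmd_tail = FALSE) {
  kind <- match.arg(kind)
  guard <- p - 3L * as.integer(ceiling((spacer + 6L) / 3)) - 3L
  if (kind == "no_RBS") guard <- p - 27L
  q <- seq.int(guard, p + 3L * n, by = 3L)
  class <- rep("nostart", length(q))
  class[1] <- "stop"
  class[q == p] <- "start"
  body <- q > p & q < p + 3L * n
  class[body] <- "nostop"
  if (kind == "no_TMD") {
    class[body] <- "phil"
  } else if (tmd_tail) {
    tmd <- q >= p + 3L * (n - 19L) & q <= p + 3L * (n - 1L)
    class[body & tmd] <- "hydro"
  } else {
    tmd <- q >= p + 6L & q <= p + 60L   # residues 3..21: 19 hydrophobic aa
    class[body & tmd] <- "hydro"
  }
  class[q == p + 3L * n] <- "stop"
  unary <- NULL
  if (kind == "no_RBS") {
    unary <- data.frame(pos = seq.int(p - 22L, p - 5L),
                        chars = "CT", stringsAsFactors = FALSE)
  } else {
    hex_from <- p - spacer - 6L
    unary <- data.frame(pos = seq.int(hex_from, hex_from + 5L),
                        chars = chars(SD_CONSENSUS),
                        stringsAsFactors = FALSE)
  }
  list(q = q, class = class, unary = unary, guard = guard,
       window = c(min(guard, if (is.null(unary)) guard else min(unary$pos)),
                  p + 3L * (n + 1L)))
}

# unary rows for the pyrimidine tract + in-frame guard stop upstream of a
# host gene start (keeps the core genes below the SD threshold)
gene_start_shield <- function(gs) {
  list(fixed = data.frame(pos = seq.int(gs - 24L, gs - 22L),
                          chars = c("T", "A", "A"), stringsAsFactors = FALSE),
       pyr = data.frame(pos = seq.int(gs - 21L, gs - 5L),
                        chars = "CT", stringsAsFactors = FALSE))
}

# ---- generator configuration ------------------------------------------

#' Synthetic-genome generator configuration
#'
#' Defaults emulate the canonical levivirus architecture: a 3.4-4.3 kb
#' plus-strand genome carrying mat, coat and rep in 5'->3' order, with
#' 1-3 planted sgl ORFs in shifted reading frames (regions 4, 10, 16 or
#' 12 of the genomic-context taxonomy), each with an AGGAGG
#' Shine-Dalgarno at spacer 6-8 and a 19-codon hydrophobic stretch, plus
#' two decoy ORFs violating exactly one screening criterion each.
#'
#' @param mat_codons,coat_codons,rep_codons Gene length ranges (codons,
#'   excluding the stop).
#' @param utr5,intergenic,utr3 Untranslated/intergenic length ranges (nt).
#' @param n_sgls Range for the number of planted sgls per genome.
#' @param sgl_regions Regions eligible for planting (subset of
#'   `c(4, 10, 16, 12)`; at most one sgl per region per genome).
#' @param sgl_codons Planted protein length range (aa); region 10 is
#'   capped to fit inside coat, region 12 floored to reach across the
#'   coat/rep boundary.
#' @param spacer_range SD spacer range for planted sgls.
#' @param n_decoys Decoys per genome (each violates exactly one criterion,
#'   drawn from short / no_RBS / no_TMD).
#' @param dirichlet_alpha Concentration of the per-amino-acid Dirichlet
#'   from which each genome's codon usage is drawn.
#' @param aa_freqs Amino-acid frequencies for host proteins (default
#'   uniform over the 20 standard residues).
#' @param criteria [criteria_config()] used for self-verification.
#' @param max_attempts Deterministic re-draws allowed before giving up
#'   when a random background ORF collides with the planted truth.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(mat_codons = c(390L, 450L),
                             coat_codons = c(120L, 140L),
                             rep_codons = c(530L, 560L),
                             utr5 = c(33L, 60L),
                             intergenic = c(27L, 45L),
                             utr3 = c(30L, 80L),
                             n_sgls = c(1L, 3L),
                             sgl_regions = c(4L, 10L, 16L, 12L),
                             sgl_codons = c(25L, 50L),
                             spacer_range = c(6L, 8L),
                             n_decoys = 2L,
                             dirichlet_alpha = 1,
                             aa_freqs = NULL,
                             criteria = criteria_config(),
                             max_attempts = 40L) {
  stopifnot(all(sgl_regions %in% c(4L, 10L, 16L, 12L)),
            sgl_codons[1] >= 25L, spacer_range[1] >= 4L,
            utr5[1] >= 25L, intergenic[1] >= 25L)
  if (is.null(aa_freqs)) {
    aa_freqs <- rep(1 / 20, 20)
    names(aa_freqs) <- setdiff(unique(unname(genetic_code())), "*")
  }
  structure(list(mat_codons = mat_codons, coat_codons = coat_codons,
                 rep_codons = rep_codons, utr5 = utr5,
                 intergenic = intergenic, utr3 = utr3,
                 n_sgls = n_sgls, sgl_regions = sgl_regions,
                 sgl_codons = sgl_codons, spacer_range = spacer_range,
                 n_decoys = n_decoys, dirichlet_alpha = dirichlet_alpha,
                 aa_freqs = aa_freqs, criteria = criteria,
                 max_attempts = as.integer(max_attempts)),
            class = "generator_config")
}

rdirichlet_usage <- function(alpha) {
  fam <- codons_by_aa()
  usage <- numeric(61L)
  names(usage) <- sense_codons()
  for (aa in names(fam)) {
    g <- stats::rgamma(length(fam[[aa]]), shape = alpha)
    if (sum(g) == 0) g <- rep(1, length(g))
    usage[fam[[aa]]] <- g / sum(g)
  }
  usage
}

sample_codon <- function(aa, usage) {
  cods <- codons_by_aa()[[aa]]
  if (length(cods) == 1L) return(cods)
  sample(cods, 1L, prob = usage[cods])
}

rint <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample.int(range[2] - range[1] + 1L, 1L) + range[1] - 1L
}

# ---- single-genome construction ---------------------------------------

build_genome_once <- function(config, genome_id) {
  # layout
  n_mat <- rint(config$mat_codons)
  n_coat <- rint(config$coat_codons)
  n_rep <- rint(config$rep_codons)
  utr5 <- rint(config$utr5)
  ig1 <- rint(config$intergenic)
  ig2 <- rint(config$intergenic)
  utr3 <- rint(config$utr3)

  k <- rint(config$n_sgls)
  regions <- sort(safe_sample(config$sgl_regions,
                              min(k, length(config$sgl_regions))))
  if (12L %in% regions) ig2 <- ig2 + (3L - ig2 %% 3L) %% 3L  # grid-align rep

  mat_s <- utr5; mat_e <- mat_s + 3L * (n_mat + 1L)
  coat_s <- mat_e + ig1; coat_e <- coat_s + 3L * (n_coat + 1L)
  rep_s <- coat_e + ig2; rep_e <- rep_s + 3L * (n_rep + 1L)
  glen <- rep_e + utr3
  genes <- data.frame(gene_name = c("mat", "coat", "rep"),
                      start = c(mat_s, coat_s, rep_s),
                      end = c(mat_e, coat_e, rep_e),
                      start_truncated = FALSE, end_truncated = FALSE,
                      stringsAsFactors = FALSE)

  usage <- rdirichlet_usage(config$dirichlet_alpha)
  aas <- names(config$aa_freqs)

  nt <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  gene_aa <- list()
  for (i in 1:3) {
    n_cod <- c(n_mat, n_coat, n_rep)[i]
    aa_seq <- c("M", sample(aas, n_cod - 1L, replace = TRUE,
                            prob = config$aa_freqs))
    cods <- vapply(aa_seq, sample_codon, "", usage = usage)
    cods[1] <- "ATG"
    cods <- c(cods, sample(STOP_CODONS, 1L))
    nt[(genes$start[i] + 1L):genes$end[i]] <- unlist(strsplit(cods, ""))
    gene_aa[[genes$gene_name[i]]] <- aa_seq
  }
  # shield every gene start from the SD criterion
  for (gs in genes$start) {
    sh <- gene_start_shield(gs)
    nt[sh$fixed$pos + 1L] <- sh$fixed$chars
    nt[sh$pyr$pos + 1L] <- sample(c("C", "T"), nrow(sh$pyr), replace = TRUE)
  }

  occupied <- list()  # absolute half-open windows already used
  overlaps_occupied <- function(win) {
    for (o in occupied)
      if (win[1] < o[2] + 9L && o[1] < win[2] + 9L) return(TRUE)
    FALSE
  }

  plant <- function(p, n, offset, grid_org, kind, spacer,
                    unary_extra = NULL, tmd_tail = FALSE) {
    lay <- sgl_layout(p, n, spacer, kind, tmd_tail)
    u_from <- (min(lay$window[1], p - 28L) - grid_org) %/% 3L
    u_to <- (lay$window[2] - 1L - grid_org) %/% 3L + 1L  # exclusive
    K <- u_to - u_from
    cost <- matrix(NA_real_, 64, K)
    for (u in seq_len(K)) {
      slot <- grid_org + 3L * (u_from + u - 1L)
      gi <- which(genes$start <= slot & slot + 3L <= genes$end)
      if (length(gi)) {
        g <- gi[1]
        if ((slot - genes$start[g]) %% 3L != 0L)
          stop("slot off the host codon grid")
        ci <- (slot - genes$start[g]) %/% 3L + 1L
        n_cod <- length(gene_aa[[genes$gene_name[g]]])
        if (ci == 1L || ci > n_cod) {       # gene start ATG / terminal stop
          cost[, u] <- cost_fixed(paste(nt[(slot + 1L):(slot + 3L)],
                                        collapse = ""))
        } else {
          cost[, u] <- cost_gene(gene_aa[[genes$gene_name[g]]][ci])
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
      cost[, u] <- apply_unary(cost[, u], pos - (grid_org + 3L * (u_from + u - 1L)) + 1L,
                               chars(unary$chars[r]))
    }
    classes <- rep("any", K - 1L)
    for (ii in seq_along(lay$q)) {
      b <- (lay$q[ii] - grid_org) %/% 3L - u_from + 1L
      stopifnot(b >= 1L, b <= K - 1L)
      classes[b] <- lay$class[ii]
    }
    sol <- dp_solve(cost, classes, offset)
    if (is.null(sol)) return(NULL)
    for (u in seq_len(K)) {
      slot <- grid_org + 3L * (u_from + u - 1L)
      nt[(slot + 1L):(slot + 3L)] <<- chars(sol$codons[u])
      gi <- which(genes$start <= slot & slot + 3L <= genes$end)
      if (length(gi)) {
        g <- gi[1]
        ci <- (slot - genes$start[g]) %/% 3L + 1L
        n_cod <- length(gene_aa[[genes$gene_name[g]]])
        if (ci > 1L && ci <= n_cod)
          gene_aa[[genes$gene_name[g]]][ci] <<-
            unname(genetic_code()[sol$codons[u]])
      }
    }
    occupied[[length(occupied) + 1L]] <<- c(min(lay$window[1], p - 28L),
                                            lay$window[2])
    sol$cost
  }

  # choose an in-gene start position for an embedded ORF
  pick_embedded <- function(gene_i, total_nt, offset) {
    gs <- genes$start[gene_i]; ge <- genes$end[gene_i]
    k_max <- (ge - 3L - gs - total_nt - offset) %/% 3L - 1L
    if (k_max < 10L) return(NULL)
    for (k2 in safe_sample(10:k_max)) {
      p <- gs + offset + 3L * k2
      if (!overlaps_occupied(c(p - 28L, p + total_nt))) return(p)
    }
    NULL
  }

  sgls <- NULL
  for (region in regions) {
    offset <- rint(c(1L, 2L))
    spacer <- rint(config$spacer_range)
    n <- rint(config$sgl_codons)
    if (region == 10L) n <- min(n, (coat_e - coat_s - 120L) %/% 3L)
    gene_i <- c(`4` = 1L, `10` = 2L, `16` = 3L)[as.character(region)]
    if (region == 12L) {
      # span the coat 3' end, the (grid-aligned) intergenic and the rep 5'
      # end; the hydrophobic stretch sits at the tail, inside rep, past
      # the rep-start guard codon
      n <- max(n, as.integer(ceiling((75L + ig2) / 3)) + 1L)
      p <- coat_e - 33L + ((offset - (coat_e - 33L - coat_s)) %% 3L)
      grid_org <- coat_s
      if (overlaps_occupied(c(p - 28L, p + 3L * (n + 1L)))) next
      sh <- gene_start_shield(rep_s)
      cost <- plant(p, n, offset, grid_org, "sgl", spacer,
                    unary_extra = rbind(sh$fixed, sh$pyr), tmd_tail = TRUE)
    } else {
      grid_org <- genes$start[gene_i]
      p <- pick_embedded(gene_i, 3L * (n + 1L), offset)
      if (is.null(p)) next
      cost <- plant(p, n, offset, grid_org, "sgl", spacer)
    }
    if (is.null(cost)) next
    sgls <- rbind(sgls, data.frame(
      start = p, end = p + 3L * (n + 1L), frame = p %% 3L,
      region = region, n_codons = n, spacer = spacer,
      frame_offset = if (region == 12L) NA_integer_ else offset,
      stringsAsFactors = FALSE))
  }
  if (is.null(sgls) || !nrow(sgls)) stop("no sgl could be planted")

  decoys <- NULL
  decoy_kinds <- sample(c("short", "no_RBS", "no_TMD"), config$n_decoys,
                        replace = config$n_decoys > 3L)
  for (kind in decoy_kinds) {
    offset <- rint(c(1L, 2L))
    n <- if (kind == "short") rint(c(15L, 22L)) else rint(c(26L, 34L))
    gene_i <- sample(c(1L, 3L), 1L)   # mat or rep
    p <- pick_embedded(gene_i, 3L * (n + 1L), offset)
    if (is.null(p)) next
    layout_kind <- if (kind == "no_RBS") "no_RBS"
                   else if (kind == "no_TMD") "no_TMD" else "sgl"
    cost <- plant(p, n, offset, genes$start[gene_i], layout_kind,
                  spacer = rint(config$spacer_range))
    if (is.null(cost)) next
    decoys <- rbind(decoys, data.frame(
      start = p, end = p + 3L * (n + 1L), frame = p %% 3L,
      violated = kind, stringsAsFactors = FALSE))
  }

  genome <- genome_record(genome_id, paste(nt, collapse = ""), genes = genes)
  truth <- list(genome_id = genome_id, sgls = sgls,
                decoys = decoys %||% data.frame(start = integer(),
                                                end = integer(),
                                                frame = integer(),
                                                violated = character()),
                genes = genes,
                windows = do.call(rbind, lapply(occupied, function(w)
                  data.frame(start = w[1], end = w[2]))))
  list(genome = genome, truth = truth)
}

verify_truth <- function(genome, truth, criteria) {
  strict <- scan_genome(genome, criteria, "strict")
  want <- paste(truth$sgls$start, truth$sgls$end)
  got <- paste(strict$start, strict$end)
  if (!setequal(want, got) || length(got) != nrow(truth$sgls)) return(FALSE)
  if (nrow(truth$decoys)) {
    relaxed <- scan_genome(genome, criteria, "relaxed")
    rkey <- paste(relaxed$start, relaxed$end)
    for (i in seq_len(nrow(truth$decoys))) {
      j <- match(paste(truth$decoys$start[i], truth$decoys$end[i]), rkey)
      if (is.na(j)) return(FALSE)
      if (!identical(relaxed$relaxed_fail[j], truth$decoys$violated[i]))
        return(FALSE)
      if (relaxed$strict_pass[j]) return(FALSE)
    }
  }
  # planted region assignments must agree with the classifier
  for (i in seq_len(nrow(truth$sgls))) {
    ra <- classify_region(c(truth$sgls$start[i], truth$sgls$end[i]),
                          genome$genes)
    if (ra$region != truth$sgls$region[i]) return(FALSE)
  }
  TRUE
}

#' Generate one synthetic levivirus-like genome with ground truth
#'
#' Deterministic in `(config, seed)`.  The generator verifies its own
#' truth ledger by running the strict and relaxed scans; if a random
#' background ORF happens to satisfy all three criteria (or shifts a
#' planted coordinate), the genome is re-drawn from an attempt-indexed
#' substream.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param genome_id Identifier (default derived from the seed).
#' @return List with `genome` (a `genome_record`) and `truth` (planted
#'   sgls, decoys, gene intervals, planting windows).
#' @export
generate_genome <- function(config = generator_config(), seed = 1L,
                            genome_id = NULL) {
  if (is.null(genome_id)) genome_id <- sprintf("syn%05d", as.integer(seed))
  base <- as.integer(seed) %% 1000003L
  for (attempt in seq_len(config$max_attempts)) {
    set.seed((base * 1009L + attempt) %% 2147483629L)
    res <- tryCatch(build_genome_once(config, genome_id),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (verify_truth(res$genome, res$truth, config$criteria)) {
      res$truth$seed <- as.integer(seed)
      res$truth$attempt <- attempt
      return(res)
    }
  }
  stop("could not generate a verifiable genome for seed ", seed,
       " within ", config$max_attempts, " attempts")
}

#' Plant a dual-frame sgl ORF into an existing host gene
#'
#' Rewrites a window of host codons so that the shifted reading frame
#' (+1 or +2) carries a complete sgl ORF (ATG start, no internal stop, a
#' 19-codon hydrophobic stretch, terminal stop, upstream AGGAGG and a
#' guard stop preventing any 5' extension) while the host frame stays
#' stop-free.  Synonymous host codons are preferred; host amino-acid
#' swaps beyond `allowance` (fraction of window codons) raise an error,
#' as does planting into a masked conserved-motif region.
#'
#' @param host_gene_codons Character vector of host codons (terminal stop
#'   optional) or an in-frame nucleotide string.
#' @param sgl_spec List with `n_codons` (protein length, >= 25),
#'   `frame_offset` (1 or 2), optional `at` (0-based codon index of the
#'   sgl start within the gene) and `spacer` (default 7).
#' @param usage Unused hook for codon-usage-weighted tie-breaks (choices
#'   are RNG-tied under `seed`).
#' @param seed Integer seed.
#' @param allowance Maximum fraction of window codons whose host amino
#'   acid may change (default 0.1); `Inf` disables the check.
#' @param motif_mask Optional 0-based codon indices where only synonymous
#'   substitutions are permitted.
#' @return List with `codons` (modified host codons, stop included),
#'   `swaps` (host amino-acid changes), and `truth` (sgl interval
#'   relative to the gene start, 0-based half-open).
#' @export
plant_sgl <- function(host_gene_codons, sgl_spec, usage = NULL, seed = 1L,
                      allowance = 0.1, motif_mask = NULL) {
  if (length(host_gene_codons) == 1L && nchar(host_gene_codons[1]) > 3L) {
    s <- toupper(host_gene_codons)
    if (nchar(s) %% 3L != 0L) stop("gene length not divisible by 3")
    host_gene_codons <- substring(s, seq(1L, nchar(s) - 2L, 3L),
                                  seq(3L, nchar(s), 3L))
  }
  cods <- toupper(host_gene_codons)
  has_stop <- cods[length(cods)] %in% STOP_CODONS
  n_cod <- length(cods) - as.integer(has_stop)
  gc <- genetic_code()
  aa <- unname(gc[cods[seq_len(n_cod)]])
  if (any(aa == "*")) stop("host gene has an internal stop codon")
  n <- as.integer(sgl_spec$n_codons)
  offset <- as.integer(sgl_spec$frame_offset)
  if (!offset %in% c(1L, 2L)) stop("frame_offset must be 1 or 2")
  if (n < 25L) stop("sgl must encode at least 25 codons")
  spacer <- as.integer(sgl_spec$spacer %||% 7L)
  at <- as.integer(sgl_spec$at %||% 10L)
  p <- 3L * at + offset
  total <- 3L * (n + 1L)
  if (at < 8L || p + total > 3L * n_cod - 3L)
    stop("sgl (", n, " codons at codon ", at, ") does not fit in a ",
         n_cod, "-codon host gene")
  lay <- sgl_layout(p, n, spacer, "sgl")
  u_from <- min(lay$window[1], p - 28L) %/% 3L
  if (u_from < 1L) stop("sgl too close to the gene start for the SD region")
  u_to <- (lay$window[2] - 1L) %/% 3L + 1L
  K <- u_to - u_from
  set.seed(as.integer(seed) %% 2147483629L)
  cost <- matrix(NA_real_, 64, K)
  for (u in seq_len(K)) {
    ci <- u_from + u      # 1-based codon index
    cost[, u] <- if (ci > n_cod) cost_fixed(cods[ci])
                 else cost_gene(aa[ci], synonymous_only =
                                  (ci - 1L) %in% motif_mask)
  }
  for (r in seq_len(nrow(lay$unary))) {
    pos <- lay$unary$pos[r]
    u <- pos %/% 3L - u_from + 1L
    if (u >= 1L && u <= K)
      cost[, u] <- apply_unary(cost[, u], pos %% 3L + 1L,
                               chars(lay$unary$chars[r]))
  }
  classes <- rep("any", K - 1L)
  for (ii in seq_along(lay$q)) {
    b <- lay$q[ii] %/% 3L - u_from + 1L
    if (b < 1L || b > K - 1L) stop("sgl constraints fall outside the gene")
    classes[b] <- lay$class[ii]
  }
  sol <- dp_solve(cost, classes, offset)
  if (is.null(sol))
    stop("dual-frame constraints unsatisfiable in this window ",
         "(conserved-motif mask too restrictive or gene too short)")
  max_swaps <- if (is.finite(allowance)) ceiling(allowance * K) else Inf
  if (sol$cost > max_swaps)
    stop("planting needs ", sol$cost, " host amino-acid swaps; allowance is ",
         max_swaps, " (", allowance, " of a ", K, "-codon window)")
  out <- cods
  out[(u_from + 1L):(u_from + K)] <- sol$codons
  list(codons = out, swaps = sol$cost,
       truth = list(start = p, end = p + total, frame_offset = offset,
                    spacer = spacer, n_codons = n))
}

# ---- divergence simulation --------------------------------------------

#' Mutate a genome into a diverged copy with an exact edit log
#'
#' Applies per-site substitutions and geometric-length indels (capped at
#' `indel_cap` nt).  Indel events are drawn at least 24 nt apart and
#' substitutions never fall inside indel footprints, so the edit log is
#' identifiable after re-alignment.  Windows listed in `protect` (0-based
#' half-open intervals) receive neither substitutions nor indels;
#' `region_multipliers` scales the substitution rate over annotated genes
#' (e.g. `list(mat = 3)` to emulate elevated 5'-half divergence).
#'
#' @param genome A `genome_record`.
#' @param sub_rate,indel_rate Per-site event probabilities in `[0, 1)`.
#' @param indel_len_mean Mean of the geometric length distribution.
#' @param indel_cap Maximum indel length (nt).
#' @param seed Integer seed.
#' @param protect List/matrix/data.frame of intervals shielded from both
#'   substitutions and indels (e.g. planted sgl windows).
#' @param protect_indels Additional intervals where only indels are
#'   forbidden (e.g. coding genes, where an indel would be a frameshift).
#' @param region_multipliers Named list of substitution-rate multipliers
#'   per gene name.
#' @param new_id Identifier of the diverged copy.
#' @return List with `genome` (diverged `genome_record`, gene annotations
#'   lifted over), `edit_log` (data.frame `type`, `pos` 0-based on the
#'   original, `len`, `ref`, `alt`) and `shift_interval(iv)`, a liftover
#'   for 0-based intervals untouched by indels.
#' @export
mutate_pair <- function(genome, sub_rate, indel_rate, indel_len_mean = 3,
                        indel_cap = 12L, seed = 1L, protect = NULL,
                        protect_indels = NULL, region_multipliers = NULL,
                        new_id = paste0(genome$genome_id, "_mut")) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  set.seed(as.integer(seed) %% 2147483629L)
  s <- chars(genome$sequence)
  n <- length(s)
  interval_mask <- function(ivs) {
    m <- rep(FALSE, n)
    if (is.null(ivs)) return(m)
    if (is.matrix(ivs) || is.data.frame(ivs))
      ivs <- lapply(seq_len(nrow(ivs)), function(i) c(ivs[i, 1], ivs[i, 2]))
    for (iv in ivs) {
      lo <- max(1L, as.integer(iv[1]) + 1L); hi <- min(n, as.integer(iv[2]))
      if (hi >= lo) m[lo:hi] <- TRUE
    }
    m
  }
  prot <- interval_mask(protect)
  prot_indel <- prot | interval_mask(protect_indels)
  rate <- rep(sub_rate, n)
  if (!is.null(region_multipliers)) {
    for (nm in names(region_multipliers)) {
      g <- get_gene(genome, nm)
      if (!is.null(g)) rate[(g$start + 1L):g$end] <-
          sub_rate * region_multipliers[[nm]]
    }
  }
  # indel events: >= 24 nt apart, outside protected windows
  cand <- which(stats::runif(n) < indel_rate & !prot_indel)
  ipos <- integer()
  last <- -1e9
  for (p in cand) {
    if (p - last >= 24L) { ipos <- c(ipos, p); last <- p }
  }
  ilen <- pmin(stats::rgeom(length(ipos), 1 / indel_len_mean) + 1L,
               as.integer(indel_cap))
  is_del <- stats::runif(length(ipos)) < 0.5
  footprint <- rep(FALSE, n)
  keep <- rep(TRUE, length(ipos))
  for (k in seq_along(ipos)) {
    if (is_del[k]) {
      to <- ipos[k] + ilen[k] - 1L
      if (to > n || any(prot_indel[ipos[k]:to])) { keep[k] <- FALSE; next }
      footprint[ipos[k]:to] <- TRUE
    }
  }
  ipos <- ipos[keep]; ilen <- ilen[keep]; is_del <- is_del[keep]
  # substitutions
  spos <- which(stats::runif(n) < rate & !prot & !footprint)
  alt <- vapply(s[spos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  log <- data.frame(type = character(), pos = integer(), len = integer(),
                    ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  if (length(spos))
    log <- rbind(log, data.frame(type = "sub", pos = spos - 1L, len = 1L,
                                 ref = s[spos], alt = alt,
                                 stringsAsFactors = FALSE))
  s2 <- s
  s2[spos] <- alt
  if (length(ipos)) {
    ins_seq <- lapply(seq_along(ipos), function(k)
      if (is_del[k]) "" else paste(sample(c("A", "C", "G", "T"), ilen[k],
                                          replace = TRUE), collapse = ""))
    log <- rbind(log, data.frame(
      type = ifelse(is_del, "del", "ins"), pos = ipos - 1L, len = ilen,
      ref = vapply(seq_along(ipos), function(k)
        if (is_del[k]) paste(s[ipos[k]:(ipos[k] + ilen[k] - 1L)],
                             collapse = "") else "", ""),
      alt = unlist(ins_seq), stringsAsFactors = FALSE))
    for (k in rev(order(ipos))) {   # apply 3' -> 5' to keep coordinates
      if (is_del[k]) {
        s2 <- s2[-(ipos[k]:(ipos[k] + ilen[k] - 1L))]
      } else {
        s2 <- append(s2, chars(ins_seq[[k]]), after = ipos[k] - 1L)
      }
    }
  }
  log <- log[order(log$pos), , drop = FALSE]
  rownames(log) <- NULL
  shift_interval <- function(iv) {
    d0 <- sum(log$len[log$type == "ins" & log$pos <= iv[1]]) -
      sum(log$len[log$type == "del" & log$pos < iv[1]])
    c(iv[1] + d0, iv[2] + d0)
  }
  genes2 <- genome$genes
  for (i in seq_len(nrow(genes2))) {
    iv <- shift_interval(c(genes2$start[i], genes2$end[i]))
    genes2$start[i] <- iv[1]; genes2$end[i] <- iv[2]
  }
  g2 <- genome_record(new_id, paste(s2, collapse = ""),
                      genes = genes2, is_partial = genome$is_partial)
  list(genome = g2, edit_log = log, shift_interval = shift_interval)
}
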