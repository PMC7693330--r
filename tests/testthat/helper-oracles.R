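# Independent oracles, deliberately coded differently from the package
# implementations they check.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# -- brute-force triple-frame ORF scan ----------------------------------
# For every position carrying a start codon, walk codon-by-codon to the
# stop; afterwards keep only the 5'-most start per (frame, stop).
oracle_find_orfs <- function(seq, start_codons = c("ATG", "GTG", "TTG"),
                             require_stop = TRUE) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (i in 0:(n - 3L)) {
    cod <- substr(seq, i + 1L, i + 3L)
    if (!cod %in% start_codons) next
    j <- i
    end <- NA_integer_
    repeat {
      j <- j + 3L
      if (j + 3L > n) break
      if (substr(seq, j + 1L, j + 3L) %in% stops) { end <- j + 3L; break }
    }
    if (is.na(end)) {
      if (require_stop) next
      end <- i + 3L * ((n - i) %/% 3L)
    }
    hits[[length(hits) + 1L]] <- c(start = i, end = end,
                                   frame = i %% 3L)
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer()))
  df <- as.data.frame(do.call(rbind, hits))
  # 5'-most start per (frame, end)
  df <- df[order(df$start), ]
  df <- df[!duplicated(df[, c("frame", "end")]), ]
  df <- df[order(df$start, df$frame), ]
  rownames(df) <- NULL
  df
}

# -- independently coded 18-region geometric rule table -----------------
# Works from boolean overlap features, evaluated in a fixed order.
oracle_region <- function(a, b, genes) {
  g <- lapply(c("mat", "coat", "rep"), function(nm) {
    r <- genes[genes$gene_name == nm, ]
    c(r$start[1], r$end[1])
  })
  feats <- function(iv) {
    s <- iv[1]; e <- iv[2]
    c(before = b <= s, after = a >= e,
      inside = a >= s && b <= e,
      covers = a <= s && b >= e && !(a >= s && b <= e),
      ovl = a < e && b > s)
  }
  f1 <- feats(g[[1]]); f2 <- feats(g[[2]]); f3 <- feats(g[[3]])
  if (f1["before"]) return(1L)
  if (f3["after"]) return(18L)
  # spans: 5'-most fully covered gene wins
  if (f1["covers"]) return(3L)
  if (f2["covers"]) return(9L)
  if (f3["covers"]) return(15L)
  # embedded: 3'-most containing gene wins (matters only for overlapping
  # gene annotations)
  if (f3["inside"]) return(16L)
  if (f2["inside"]) return(10L)
  if (f1["inside"]) return(4L)
  # bridges (5'-most overlapped pair)
  if (f1["ovl"] && f2["ovl"]) return(6L)
  if (f2["ovl"] && f3["ovl"]) return(12L)
  # single-gene end overlaps
  if (f1["ovl"]) return(if (a < g[[1]][1]) 2L else 5L)
  if (f2["ovl"]) return(if (a < g[[2]][1]) 8L else 11L)
  if (f3["ovl"]) return(if (a < g[[3]][1]) 14L else 17L)
  if (a >= g[[1]][2] && b <= g[[2]][1]) return(7L)
  if (a >= g[[2]][2] && b <= g[[3]][1]) return(13L)
  NA_integer_
}

# -- straight-line MILC ------------------------------------------------
oracle_milc <- function(o, ref, pseudo = 0.5) {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  aas <- unique(unname(gc))
  L <- sum(o)
  total <- 0
  degen <- 0
  for (aa in aas) {
    cods <- names(gc)[gc == aa]
    oc <- o[cods]; oc[is.na(oc)] <- 0
    if (sum(oc) == 0) next
    degen <- degen + (length(cods) - 1)
    if (length(cods) == 1) next
    gcount <- ref[cods]; gcount[is.na(gcount)] <- 0
    gcount[gcount == 0] <- pseudo
    f <- oc / sum(oc)
    g <- gcount / sum(gcount)
    for (k in seq_along(cods))
      if (oc[k] > 0) total <- total + 2 * as.numeric(oc[k]) *
          log(f[k] / g[k])
  }
  unname(total / L - (degen / L - 0.5))
}

random_codon_counts <- function(n_codons = 120) {
  cods <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA"))
  tab <- table(sample(cods, n_codons, replace = TRUE,
                      prob = stats::runif(61, 0.2, 1)))
  o <- integer(61); names(o) <- cods
  o[names(tab)] <- as.integer(tab)
  o
}

# -- Waterman-Smith-Beyer affine DP (explicit gap-length scan) ----------
# Algorithmically distinct from the package's Gotoh kernel.
wsb_score <- function(a, b, match = 5, mismatch = -4, open = 10, ext = 1,
                      local = FALSE) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  gp <- function(k) open + (k - 1) * ext
  M <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(n)) M[i + 1, 1] <- -gp(i)
    for (j in seq_len(m)) M[1, j + 1] <- -gp(j)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (ca[i] == cb[j]) match else mismatch
    v <- M[i, j] + s
    for (k in seq_len(i)) v <- max(v, M[i - k + 1, j + 1] - gp(k))
    for (k in seq_len(j)) v <- max(v, M[i + 1, j - k + 1] - gp(k))
    if (local) v <- max(v, 0)
    M[i + 1, j + 1] <- v
    if (v > best) best <- v
  }
  if (local) best else M[n + 1, m + 1]
}

# -- exhaustive alignment enumeration (tiny inputs) ---------------------
enum_global_score <- function(a, b, match = 5, mismatch = -4,
                              open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    out <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      out <- max(out, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca))
      out <- max(out, -(if (last == "U") ext else open) + rec(i + 1, j, "U"))
    if (j <= length(cb))
      out <- max(out, -(if (last == "L") ext else open) + rec(i, j + 1, "L"))
    out
  }
  rec(1, 1, "M")
}

# random candidate table for round-trip tests
random_candidate_table <- function(n) {
  df <- empty_candidate_table()
  starts <- sort(sample.int(5000, n)) * 3L
  for (i in seq_len(n)) {
    len <- sample(26:60, 1) * 3L
    prot <- paste(sample(names(sglscan:::KD_HYDROPATHY), len / 3 - 1,
                         replace = TRUE), collapse = "")
    df <- rbind(df, data.frame(
      genome_id = paste0("g", sample(1:3, 1)), start = starts[i],
      end = starts[i] + len, frame = starts[i] %% 3L,
      start_codon = sample(c("ATG", "GTG", "TTG"), 1), protein = prot,
      has_stop = TRUE, sd_best = sample(0:6, 1), sd_spacer = sample(4:16, 1),
      sd_window = random_dna(22), sd_pass = sample(c(TRUE, FALSE), 1),
      kd_max = round(stats::runif(1, -4, 4), 6), kd_start = 1L,
      kd_end = 19L, kd_window = 19L, kd_short = FALSE,
      tmd_pass = sample(c(TRUE, FALSE), 1), len_pass = TRUE,
      strict_pass = sample(c(TRUE, FALSE), 1), relaxed_fail = "none",
      region = sample(1:18, 1), host_gene = "rep", frame_offset = 1L,
      stringsAsFactors = FALSE))
  }
  as_candidate_table(df)
}

# toy genome annotation used by region tests
toy_genes <- function() {
  data.frame(gene_name = c("mat", "coat", "rep"),
             start = c(6L, 30L, 54L), end = c(24L, 48L, 78L),
             start_truncated = FALSE, end_truncated = FALSE,
             stringsAsFactors = FALSE)
}
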