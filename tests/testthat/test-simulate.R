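test_that("generation is a pure function of (config, seed)", {
  a <- generate_genome(seed = 61)
  b <- generate_genome(seed = 61)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth$sgls, b$truth$sgls)
  c <- generate_genome(seed = 62)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("generated genomes have the canonical architecture", {
  res <- generate_genome(seed = 63)
  g <- res$genome
  expect_equal(g$genes$gene_name, c("mat", "coat", "rep"))
  expect_true(all(diff(g$genes$start) > 0))
  for (nm in g$genes$gene_name) {
    p <- translate_cds(gene_seq(g, nm), as_initiator = TRUE)
    expect_true(attr(p, "stop_present"))
    expect_false(attr(p, "internal_stop"))
  }
  expect_true(all(res$truth$sgls$region %in% c(4L, 10L, 16L, 12L)))
})

test_that("host genes stay stop-free across many random draws", {
  for (s in 101:110) {
    g <- generate_genome(seed = s)$genome
    for (nm in c("mat", "coat", "rep"))
      expect_false(attr(translate_cds(gene_seq(g, nm)), "internal_stop"),
                   label = paste("seed", s, nm))
  }
})

test_that("strict scan recovers exactly the planted sgls; decoys only relaxed", {
  for (s in 71:75) {
    res <- generate_genome(seed = s)
    strict <- scan_genome(res$genome, mode = "strict")
    expect_setequal(paste(strict$start, strict$end),
                    paste(res$truth$sgls$start, res$truth$sgls$end))
    relaxed <- scan_genome(res$genome, mode = "relaxed")
    rkey <- paste(relaxed$start, relaxed$end)
    for (i in seq_len(nrow(res$truth$decoys))) {
      j <- match(paste(res$truth$decoys$start[i], res$truth$decoys$end[i]),
                 rkey)
      expect_false(is.na(j))
      expect_equal(relaxed$relaxed_fail[j], res$truth$decoys$violated[i])
      expect_false(relaxed$strict_pass[j])
    }
  }
})

test_that("planted sgls satisfy all construction guarantees", {
  res <- generate_genome(seed = 76)
  g <- res$genome
  cfg <- criteria_config()
  for (i in seq_len(nrow(res$truth$sgls))) {
    tr <- res$truth$sgls[i, ]
    nt <- substr(g$sequence, tr$start + 1L, tr$end)
    expect_equal(substr(nt, 1, 3), "ATG")
    prot <- translate_cds(nt, as_initiator = TRUE)
    expect_true(attr(prot, "stop_present"))
    expect_false(attr(prot, "internal_stop"))
    expect_gte(nchar(prot), 25)
    expect_gte(predict_tmd(as.character(prot), cfg)$max_window_hydropathy,
               2.0)
    sd <- score_sd(g$sequence, list(start = tr$start), cfg)
    expect_equal(sd$best_core_match, 6L)
    expect_true(sd$spacer %in% 6:8)
  }
})

test_that("plant_sgl rewrites a host window under the dual-frame constraints", {
  set.seed(81)
  aas <- names(sglscan:::KD_HYDROPATHY)
  host_aa <- c("M", sample(aas, 119, replace = TRUE))
  gc_map <- sglscan:::codons_by_aa()
  host <- c(vapply(host_aa, function(a) gc_map[[a]][1], ""), "TAA")
  host[1] <- "ATG"
  res <- plant_sgl(host, list(n_codons = 30L, frame_offset = 1L, at = 15L),
                   seed = 5, allowance = Inf)
  expect_equal(length(res$codons), length(host))
  gene_nt <- paste(res$codons, collapse = "")
  hp <- translate_cds(gene_nt, as_initiator = TRUE)
  expect_false(attr(hp, "internal_stop"))   # host frame intact
  sgl_nt <- substr(gene_nt, res$truth$start + 1L, res$truth$end)
  sp <- translate_cds(sgl_nt, as_initiator = TRUE)
  expect_equal(substr(sgl_nt, 1, 3), "ATG")
  expect_equal(nchar(sp), 30)
  expect_false(attr(sp, "internal_stop"))
  expect_gte(predict_tmd(as.character(sp))$max_window_hydropathy, 2.0)
  # and the scanner sees it at exactly the planted coordinates
  found <- find_orfs(gene_nt)
  expect_true(any(found$start == res$truth$start &
                    found$end == res$truth$end))
})

test_that("plant_sgl enforces the swap allowance and the motif mask", {
  set.seed(82)
  host <- c("ATG", rep("AAA", 118), "TAA")   # all-Lys host: swaps required
  expect_error(plant_sgl(host, list(n_codons = 30L, frame_offset = 1L,
                                    at = 15L), allowance = 0),
               "allowance")
  expect_error(plant_sgl(host, list(n_codons = 30L, frame_offset = 1L,
                                    at = 15L), allowance = Inf,
                         motif_mask = 10:80),
               "unsatisfiable")
  expect_error(plant_sgl(host, list(n_codons = 30L, frame_offset = 0L)),
               "frame_offset")
  expect_error(plant_sgl(c("ATG", rep("AAA", 20), "TAA"),
                         list(n_codons = 30L, frame_offset = 1L)),
               "fit")
})

test_that("mutate_pair with zero rates is the identity with an empty log", {
  g <- generate_genome(seed = 83)$genome
  mp <- mutate_pair(g, 0, 0, seed = 1)
  expect_identical(mp$genome$sequence, g$sequence)
  expect_equal(nrow(mp$edit_log), 0)
})

test_that("substitution counts follow the binomial expectation", {
  g <- generate_genome(seed = 84)$genome
  n <- nchar(g$sequence)
  mp <- mutate_pair(g, 0.05, 0, seed = 2)
  subs <- sum(mp$edit_log$type == "sub")
  expect_lt(abs(subs - 0.05 * n), 4 * sqrt(n * 0.05 * 0.95))
  # substitutions recorded faithfully
  s_old <- strsplit(g$sequence, "")[[1]]
  s_new <- strsplit(mp$genome$sequence, "")[[1]]
  expect_equal(which(s_old != s_new) - 1L, mp$edit_log$pos)
})

test_that("the edit log replays indels consistently", {
  g <- generate_genome(seed = 85)$genome
  mp <- mutate_pair(g, 0.03, 0.008, seed = 3)
  log <- mp$edit_log
  expect_equal(nchar(mp$genome$sequence),
               nchar(g$sequence) + sum(log$len[log$type == "ins"]) -
                 sum(log$len[log$type == "del"]))
  expect_true(all(log$len[log$type != "sub"] >= 1))
  expect_true(all(log$len[log$type != "sub"] <= 12))
  ipos <- sort(log$pos[log$type != "sub"])
  if (length(ipos) > 1) expect_true(all(diff(ipos) >= 24))
  # protected windows untouched
  win <- c(g$genes$start[1] + 30L, g$genes$start[1] + 120L)
  mp2 <- mutate_pair(g, 0.2, 0.02, seed = 4, protect = list(win))
  expect_equal(substr(mp2$genome$sequence,
                      mp2$shift_interval(win)[1] + 1L,
                      mp2$shift_interval(win)[2]),
               substr(g$sequence, win[1] + 1L, win[2]))
})

test_that("cohorts carry a verifiable clade and correctly classed pairs", {
  coh <- generate_cohort(n = 13, seed = 86,
                         cohort = cohort_config(clade_size = 6,
                                                n_s_pairs = 1,
                                                n_d_pairs = 1))
  expect_length(coh$genomes, 13)
  expect_length(coh$truth$clade, 6)
  classes <- vapply(coh$truth$pairs, `[[`, "", "class")
  expect_setequal(classes, c("S", "D"))
  for (p in coh$truth$pairs) {
    pc <- classify_pair_context(p$sgl_a, coh$genomes[[p$id_a]],
                                p$sgl_b, coh$genomes[[p$id_b]])
    expect_equal(pc$class, p$class)
    if (p$class == "D") {
      hit <- align_local(p$remnant$source_seq,
                         coh$genomes[[p$id_b]]$sequence)
      expect_gt(divergence_census(hit)$identity_fraction, 0.70)
    }
  }
  # every member genome still verifies against its own ledger
  for (id in names(coh$genomes)) {
    strict <- scan_genome(coh$genomes[[id]], mode = "strict")
    tr <- coh$truth$per_genome[[id]]
    expect_setequal(paste(strict$start, strict$end),
                    paste(tr$sgls$start, tr$sgls$end))
  }
})
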