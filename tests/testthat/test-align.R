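test_that("global alignment hand-computed examples", {
  expect_equal(align_global("ACGT", "ACGT")$score, 20)
  al <- align_global("ACGT", "AGT")
  expect_equal(al$score, 15 - 10)
  expect_equal(nchar(al$row_a), 4)
  expect_equal(align_global("A", "A")$score, 5)
  # gap of length k costs open + extend*(k-1)
  expect_equal(align_global("AAAAA", "AA")$score, 2 * 5 - (10 + 2 * 1))
})

test_that("local alignment returns segments and allows the empty alignment", {
  al <- align_local("ACGTACGT", "ACGTACGT")
  expect_equal(al$score, 40)
  expect_equal(al$a_range, c(0, 8))
  # deeply mismatched pair: empty alignment at score 0
  al2 <- align_local("AAAA", "TTTT")
  expect_equal(al2$score, 0)
  expect_equal(nchar(al2$row_a), 0)
  # embedded segment is found
  al3 <- align_local(paste0(strrep("T", 30), "ACACGGCACG", strrep("T", 30)),
                     "ACACGGCACG")
  expect_equal(al3$score, 50)
  expect_equal(al3$b_range, c(0, 10))
})

test_that("DP scores equal exhaustive enumeration on tiny pairs", {
  seqs <- unlist(lapply(1:3, function(l)
    apply(expand.grid(rep(list(c("A", "C")), l)), 1, paste, collapse = "")))
  for (a in seqs) for (b in seqs) {
    expect_equal(align_global(a, b)$score, enum_global_score(a, b),
                 label = paste("global", a, b))
  }
})

test_that("DP scores equal an independent gap-length-scan DP on length <= 5", {
  set.seed(21)
  for (r in 1:60) {
    a <- random_dna(sample(1:5, 1))
    b <- random_dna(sample(1:5, 1))
    expect_equal(align_global(a, b)$score, wsb_score(a, b),
                 label = paste("global", a, b))
    expect_equal(align_local(a, b)$score, wsb_score(a, b, local = TRUE),
                 label = paste("local", a, b))
  }
})

test_that("DP scores match Biostrings pairwiseAlignment on random pairs", {
  set.seed(22)
  mat <- matrix(-4, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 5
  for (r in 1:10) {
    a <- random_dna(80); b <- random_dna(70)
    # Biostrings charges open + extend*len for a len-long gap, so its
    # "opening" parameter is our open minus one extension
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 9, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(align_global(a, b)$score, ref)
    ref_loc <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 9,
                                             gapExtension = 1,
                                             scoreOnly = TRUE)
    expect_equal(align_local(a, b)$score, ref_loc)
  }
})

test_that("re-scoring an alignment from its columns reproduces the DP score", {
  set.seed(23)
  for (r in 1:10) {
    a <- random_dna(60); b <- random_dna(55)
    al <- align_global(a, b)
    expect_equal(score_alignment(al), al$score)
    # stripping gaps recovers the inputs
    expect_equal(gsub("-", "", al$row_a), a)
    expect_equal(gsub("-", "", al$row_b), b)
  }
})

test_that("protein alignment uses BLOSUM62", {
  al <- align_global("MKV", "MKV", align_params("aa"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  expect_equal(al$score, BLOSUM62["M", "M"] + BLOSUM62["K", "K"] +
                 BLOSUM62["V", "V"])
})

test_that("dot plots follow dotmatcher window/threshold semantics", {
  set.seed(24)
  a <- random_dna(200)
  dp <- dotplot(a, a)                     # window 40, threshold 50
  # self comparison: every window on the main diagonal scores 200
  diag_pts <- dp$points[dp$points[, 1] == dp$points[, 2], , drop = FALSE]
  expect_equal(sort(diag_pts[, 1]), 20:180)

  # plus-strand-only scan: the reverse complement clears the diagonal
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(a, "")[[1]]),
                                     collapse = ""))
  dp_rc <- dotplot(a, rc)
  expect_equal(sum(dp_rc$points[, 1] == dp_rc$points[, 2]), 0)

  b <- random_dna(200)
  expect_error(dotplot(substr(a, 1, 20), b), "window")
})

test_that("dot plots are symmetric and threshold-monotone", {
  set.seed(25)
  for (r in 1:5) {
    a <- random_dna(120); b <- random_dna(120)
    pab <- dotplot(a, b, threshold = 20)$points
    pba <- dotplot(b, a, threshold = 20)$points
    expect_setequal(paste(pab[, 1], pab[, 2]), paste(pba[, 2], pba[, 1]))
    hi <- dotplot(a, b, threshold = 60)$points
    expect_true(all(paste(hi[, 1], hi[, 2]) %in%
                      paste(pab[, 1], pab[, 2])))
  }
})

test_that("the NxN grid covers all ordered pairs with transposed symmetry", {
  set.seed(26)
  gs <- lapply(1:3, function(i) genome_record(paste0("g", i),
                                              random_dna(150)))
  out_dir <- withr::local_tempdir()
  grid <- mist_matrix(gs, threshold = 30, out_dir = out_dir)
  expect_length(grid, 9)
  self <- grid[["g1|g1"]]$points
  expect_true(all((20:130) %in% self[self[, 1] == self[, 2], 1]))
  p12 <- grid[["g1|g2"]]$points; p21 <- grid[["g2|g1"]]$points
  expect_setequal(paste(p12[, 1], p12[, 2]), paste(p21[, 2], p21[, 1]))
  expect_true(file.exists(file.path(out_dir, "index.tsv")))
  expect_equal(nrow(utils::read.delim(file.path(out_dir, "index.tsv"))), 9)
})

test_that("divergence census counts substitutions and indel events", {
  al0 <- align_global("ACGTACGT", "ACGTACGT")
  cen0 <- divergence_census(al0)
  expect_equal(cen0$substitutions, 0)
  expect_equal(length(cen0$indel_events), 0)
  expect_equal(cen0$identity_fraction, 1.0)

  al <- list(row_a = "ACGT-ACGT", row_b = "ACCTTACGT", score = 0)
  cen <- divergence_census(al)
  expect_equal(cen$substitutions, 1)
  expect_equal(cen$indel_events, 1L)
  expect_equal(cen$matches, 7)
  expect_equal(cen$substitutions + cen$matches + sum(cen$indel_events),
               cen$alignment_length)

  al2 <- list(row_a = "AAAA----CCCC", row_b = "----GGGGCCCC", score = 0)
  cen2 <- divergence_census(al2)
  expect_equal(sort(cen2$indel_events), c(4L, 4L))
  expect_equal(cen2$min_indel, 4L)
  expect_equal(cen2$max_indel, 4L)
})

test_that("mutation labels follow the g15t / A52D nomenclature", {
  # codon 5 GCT -> GAT: position 14 C>A, Ala5Asp missense
  wt <- paste0("ATG", "AAA", "CCC", "GGG", "GCT", "TAA")
  mut <- paste0("ATG", "AAA", "CCC", "GGG", "GAT", "TAA")
  lab <- annotate_mutations(wt, mut)
  expect_equal(lab$nt_label, "c14a")
  expect_equal(lab$aa_label, "A5D")
  expect_equal(lab$kind, "missense")

  # third-position change leaving Leu: silent, lowercase nt label only
  wt2 <- paste0("ATG", "AAA", "CCC", "GGG", "CTG", "TAA")
  mut2 <- paste0("ATG", "AAA", "CCC", "GGG", "CTT", "TAA")
  lab2 <- annotate_mutations(wt2, mut2)
  expect_equal(lab2$nt_label, "g15t")
  expect_equal(lab2$kind, "silent")
  expect_equal(lab2$aa_label, "")

  # nonsense
  wt3 <- paste0("ATG", "TGG", "AAA", "TAA")
  mut3 <- paste0("ATG", "TGA", "AAA", "TAA")
  lab3 <- annotate_mutations(wt3, mut3)
  expect_equal(lab3$kind, "nonsense")
  expect_equal(lab3$aa_label, "W2*")

  expect_equal(nrow(annotate_mutations(wt, wt)), 0)
  expect_error(annotate_mutations(wt, paste0(wt, "AAA")), "length")
})
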