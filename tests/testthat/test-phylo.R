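test_that("progressive MSA reduces to pairwise alignment for two sequences", {
  p <- align_params("nt")
  a <- "ACGTACGTAA"; b <- "ACGTCGTAA"
  al <- align_global(a, b, p)
  m <- progressive_msa(c(x = a, y = b), p)
  expect_equal(m$rows[1], al$row_a)
  expect_equal(m$rows[2], al$row_b)
})

test_that("identical sequences align without gaps", {
  s <- strrep("MKVLF", 8)
  m <- progressive_msa(c(a = s, b = s, c = s), align_params("aa"))
  expect_equal(m$n_columns, nchar(s))
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
  # stripping gaps recovers inputs, in input order
  expect_equal(gsub("-", "", m$rows), rep(s, 3))
})

test_that("moderately diverged proteins keep a planted motif aligned", {
  set.seed(51)
  aas <- names(sglscan:::KD_HYDROPATHY)
  core <- paste(sample(aas, 120, replace = TRUE), collapse = "")
  motif <- "GPGAWQR"
  base <- paste0(substr(core, 1, 60), motif, substr(core, 61, 120))
  seqs <- vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(setdiff(seq_along(ch), 61:67), 10)  # spare the motif
    ch[idx] <- sample(aas, 10, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:5)
  m <- progressive_msa(seqs, align_params("aa"))
  pos <- lapply(m$rows, function(r) find_motif(r, motif))
  cols <- vapply(pos, function(x) attr(x, "columns")[1, "from"], 0L)
  expect_true(all(cols == cols[1]))    # same alignment column in every row
})

test_that("conservation profile is the modal non-gap fraction", {
  m <- msa(c("a", "b", "c", "d"),
           c("AAG-", "AAG-", "AABA", "ABBC"), "aa")
  prof <- conservation_profile(m)
  expect_equal(prof[1], 1.0)     # AAAA
  expect_equal(prof[2], 0.75)    # AAAB
  expect_equal(prof[3], 0.5)     # GGBB
  expect_equal(prof[4], 0.5)     # A vs C among 2 non-gap rows
  expect_true(all(prof >= 0 & prof <= 1))
  # row order invariance
  m2 <- msa(c("d", "c", "b", "a"), rev(m$rows), "aa")
  expect_equal(conservation_profile(m2), prof)
  # all-gap column scores 0
  m3 <- msa(c("a", "b"), c("A-A", "A-A"), "aa")
  expect_equal(conservation_profile(m3)[2], 0)
})

test_that("motif search supports wildcards, overlap and gap skipping", {
  expect_equal(as.integer(find_motif("AAGPGAKK", "GPGA")), 3L)
  expect_equal(as.integer(find_motif("MGAFRESCGL", "GXFRESCG")), 2L)
  expect_equal(as.integer(find_motif("AAAA", "AA")), 1:3)
  expect_length(find_motif("AAAA", "GPGA"), 0)
  expect_error(find_motif("AAAA", ""), "empty")
  hit <- find_motif("G-PG-A--KK", "GPGA")
  expect_equal(as.integer(hit), 1L)
  expect_equal(unname(attr(hit, "columns")[1, ]), c(1L, 6L))
})

test_that("ORF projection maps codons through the row gap pattern", {
  row <- strrep("A", 50)
  gene <- list(start = 0L, end = 153L)
  expect_equal(project_orf_to_alignment(c(30, 90), gene, row), c(10, 30))
  gapped <- paste0(strrep("A", 10), "-----", strrep("A", 40))
  expect_equal(project_orf_to_alignment(c(30, 90), gene, gapped), c(15, 35))
  expect_error(project_orf_to_alignment(c(30, 200), gene, row),
               "not inside")
  # translation check hooks in when the gene sequence is supplied
  nt <- paste0("ATG", strrep("AAA", 48), "TAA")
  aln_row <- as.character(translate_cds(nt, as_initiator = TRUE))
  expect_equal(
    project_orf_to_alignment(c(30, 90), list(start = 0, end = nchar(nt)),
                             aln_row, gene_nt = nt),
    c(10, 30))
  expect_error(
    project_orf_to_alignment(c(30, 90), list(start = 0, end = nchar(nt)),
                             strrep("W", 49), gene_nt = nt),
    "translation")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  bl <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl["a"]), 1)
  expect_equal(unname(bl["b"]), 1)
  expect_equal(unname(bl["c"]), 3)
})

test_that("NJ reconstructs additive trees exactly on 4 and 5 taxa", {
  set.seed(52)
  for (n in c(4, 5)) for (r in 1:10) {
    phy0 <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
    phy0 <- ape::unroot(phy0)
    d <- ape::cophenetic.phylo(phy0)
    d <- d[order(rownames(d)), order(colnames(d))]
    phy <- nj_tree(d)
    expect_equal(ape::dist.topo(phy, phy0), 0, ignore_attr = TRUE)
    d2 <- ape::cophenetic.phylo(phy)
    d2 <- d2[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-8)
  }
})

test_that("degenerate distance matrices are handled", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  phy <- nj_tree(d)
  expect_equal(sum(phy$edge.length), 0)
  asym <- d; asym[1, 2] <- 1
  expect_error(nj_tree(asym), "symmetric")
})

test_that("bootstrap supports a planted 2v2 split and is seed-reproducible", {
  set.seed(53)
  ncol <- 200
  block <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  other <- block
  flip <- sample(ncol, ncol / 2)      # 50% divergent columns between groups
  other[flip] <- vapply(block[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  m <- msa(c("g1a", "g1b", "g2a", "g2b"),
           c(paste(block, collapse = ""), paste(block, collapse = ""),
             paste(other, collapse = ""), paste(other, collapse = "")),
           "nt")
  tr1 <- bootstrap_support(m, n = 300, seed = 9)
  tr2 <- bootstrap_support(m, n = 300, seed = 9)
  expect_identical(tr1$node.label, tr2$node.label)
  cl <- clades_at_support(tr1, 95)
  expect_true(any(vapply(cl, function(x)
    setequal(x, c("g2a", "g2b")) || setequal(x, c("g1a", "g1b")), TRUE)))
})

test_that("clade extraction applies a strict cutoff", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  tree$node.label <- c(NA, 85, 80)
  cl <- clades_at_support(tree, 80, outgroup = "e")
  expect_length(cl, 1)
  expect_equal(sort(cl[[1]]), c("a", "b"))
  expect_equal(attr(cl[[1]], "support"), 85)
  expect_length(clades_at_support(tree, 98, outgroup = "e"), 0)
  expect_length(clades_at_support(tree, 84.9, outgroup = "e"), 1)
  expect_error(clades_at_support(tree, 150), "0..100")
})

test_that("alignment round-trips through aligned FASTA", {
  m <- msa(c("x", "y"), c("AC-GT", "ACAGT"), "nt")
  f <- withr::local_tempfile(fileext = ".afa")
  write_msa(m, f)
  m2 <- read_msa(f, "nt")
  expect_equal(m2$ids, m$ids)
  expect_equal(m2$rows, m$rows)
})
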