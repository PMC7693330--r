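test_that("find_orfs reports maximal ORFs at their 5'-most start", {
  g <- paste0("AAA", "ATG", strrep("AAA", 25), "TAA", "AAA")
  orfs <- find_orfs(g)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$end, 3L + 3L * 27L)
  expect_equal(orfs$start_codon, "ATG")
  expect_equal(nchar(orfs$protein), 26)
  expect_true(orfs$has_stop)

  # a 24-aa ORF is still reported (length screening happens later)
  g24 <- paste0("CCC", "ATG", strrep("AAA", 23), "TAA")
  expect_equal(nchar(find_orfs(g24)$protein), 24)

  expect_equal(nrow(find_orfs(strrep("CCA", 40))), 0)
})

test_that("nested same-frame starts collapse unless all_starts is set", {
  g <- paste0("ATG", "AAA", "ATG", strrep("GCA", 10), "TAA")
  expect_equal(nrow(find_orfs(g)), 1)
  expect_equal(find_orfs(g)$start, 0L)
  expanded <- find_orfs(g, all_starts = TRUE)
  expect_equal(sort(expanded$start), c(0L, 6L))
  expect_equal(unique(expanded$end), nchar(g))
})

test_that("ORFs without stop codons appear only when require_stop = FALSE", {
  g <- paste0("TTT", "ATG", strrep("GCA", 30))
  expect_equal(nrow(find_orfs(g)), 0)
  cfg <- criteria_config(require_stop = FALSE)
  orfs <- find_orfs(g, cfg)
  expect_equal(nrow(orfs), 1)
  expect_false(orfs$has_stop)
})

test_that("find_orfs matches the brute-force oracle on random sequences", {
  set.seed(101)
  cfg <- criteria_config()
  for (r in 1:12) {
    seq <- random_dna(800)
    mine <- find_orfs(seq, cfg)
    oracle <- oracle_find_orfs(seq)
    expect_equal(mine[, c("start", "end", "frame")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("SD scoring finds the best contiguous AGGAGG match over spacers", {
  cfg <- criteria_config()
  g <- paste0(strrep("C", 20), "AGGAGG", strrep("C", 7), "ATG",
              strrep("GCA", 30), "TAA")
  orf <- list(start = 20 + 6 + 7)
  sd <- score_sd(g, orf, cfg)
  expect_equal(sd$best_core_match, 6L)
  expect_equal(sd$spacer, 7L)
  expect_true(sd$passes)

  # all-pyrimidine upstream window
  g2 <- paste0(strrep("CT", 20), "ATG", strrep("GCA", 30), "TAA")
  sd2 <- score_sd(g2, list(start = 40), cfg)
  expect_equal(sd2$best_core_match, 0L)
  expect_false(sd2$passes)

  # start near the genome 5' end: truncated window, no crash
  g3 <- paste0("CC", "ATG", strrep("GCA", 30), "TAA")
  sd3 <- score_sd(g3, list(start = 2), cfg)
  expect_false(sd3$passes)

  # partial 4-mer match at some spacer
  g4 <- paste0(strrep("C", 20), "TGGAGT", strrep("C", 5), "ATG",
               strrep("GCA", 30), "TAA")
  sd4 <- score_sd(g4, list(start = 20 + 6 + 5), cfg)
  expect_equal(sd4$best_core_match, 4L)
  expect_true(sd4$passes)
})

test_that("Kyte-Doolittle window prediction matches hand computation", {
  cfg <- criteria_config()
  tm <- predict_tmd(strrep("L", 30), cfg)
  expect_equal(tm$max_window_hydropathy, 3.8)
  expect_true(tm$passes)
  expect_equal(tm$window_size, 19L)

  tm2 <- predict_tmd(strrep("D", 30), cfg)
  expect_equal(tm2$max_window_hydropathy, -3.5)
  expect_false(tm2$passes)

  tm3 <- predict_tmd(strrep("L", 10), cfg)
  expect_equal(tm3$window_size, 10L)
  expect_true(tm3$short_window)
  expect_equal(tm3$max_window_hydropathy, 3.8)

  # mixed protein: the best window is the hydrophobic block
  p <- paste0(strrep("D", 10), strrep("I", 19), strrep("D", 10))
  tm4 <- predict_tmd(p, cfg)
  expect_equal(tm4$max_window_hydropathy, 4.5)
  expect_equal(tm4$segment, c(11, 29))

  expect_error(predict_tmd("LLZ", cfg), "position 3")
})

test_that("strict and relaxed screening behave per criterion", {
  cfg <- criteria_config()
  mk <- function(protein, sd_best, kd_max) {
    df <- empty_candidate_table()
    df[1, ] <- NA
    df$genome_id <- "g"; df$start <- 0L
    df$end <- 3L * (nchar(protein) + 1L); df$frame <- 0L
    df$start_codon <- "ATG"; df$protein <- protein; df$has_stop <- TRUE
    df$sd_best <- sd_best; df$sd_spacer <- 7L; df$sd_window <- ""
    df$kd_max <- kd_max; df$kd_start <- 1L; df$kd_end <- 19L
    df$kd_window <- 19L; df$kd_short <- FALSE
    df$relaxed_fail <- ""; df$host_gene <- ""
    as_candidate_table(df)
  }
  good <- mk(strrep("L", 26), 6L, 2.5)
  expect_equal(nrow(apply_criteria(good, cfg, "strict")), 1)

  no_sd <- mk(strrep("L", 26), 0L, 2.5)
  expect_equal(nrow(apply_criteria(no_sd, cfg, "strict")), 0)
  rel <- apply_criteria(no_sd, cfg, "relaxed")
  expect_equal(rel$relaxed_fail, "no_RBS")

  no_tmd <- mk(strrep("L", 26), 6L, 0.2)
  expect_equal(nrow(apply_criteria(no_tmd, cfg, "strict")), 0)
  expect_equal(apply_criteria(no_tmd, cfg, "relaxed")$relaxed_fail, "no_TMD")

  short <- mk(strrep("L", 20), 6L, 2.5)
  expect_equal(nrow(apply_criteria(short, cfg, "strict")), 0)
  expect_equal(apply_criteria(short, cfg, "relaxed")$relaxed_fail, "short")

  # failing two criteria under the relaxed thresholds is excluded
  twofail <- mk(strrep("L", 8), 0L, 2.5)
  expect_equal(nrow(apply_criteria(twofail, cfg, "relaxed")), 0)
  # two strict failures that both clear the relaxed bar are retained,
  # with every missed strict criterion recorded in the tag
  borderline <- mk(strrep("L", 20), 3L, 2.5)
  rel2 <- apply_criteria(borderline, cfg, "relaxed")
  expect_equal(rel2$relaxed_fail, "short,no_RBS")

  # the 25-codon boundary is inclusive
  boundary <- mk(strrep("L", 25), 6L, 2.5)
  expect_true(apply_criteria(boundary, cfg, "strict")$len_pass)
})

test_that("threshold monotonicity: relaxing never removes candidates", {
  res <- generate_genome(seed = 31)
  cfg_hi <- criteria_config()
  cfg_lo <- criteria_config(min_codons = 20L, kd_threshold = 1.2,
                            sd_min_core = 3L)
  hi <- scan_genome(res$genome, cfg_hi, "strict")
  lo <- scan_genome(res$genome, cfg_lo, "strict")
  expect_true(all(candidate_key(hi) %in% candidate_key(lo)))
})

test_that("scanning is deterministic", {
  res <- generate_genome(seed = 32)
  a <- scan_genome(res$genome, mode = "relaxed")
  b <- scan_genome(res$genome, mode = "relaxed")
  expect_identical(a, b)
})
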