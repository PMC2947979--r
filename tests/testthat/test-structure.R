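test_that("constraints mirror coverage exactly, strand-aware", {
  cs <- c(chr1 = 50L)
  reads <- aligned_reads("chr1", c(11, 14), c(13, 16), c("+", "+"))
  tr <- build_coverage(reads, cs)
  expect_equal(coverage_to_constraints(tr, "chr1", 10, 14, "+"), ".||.")
  # zero coverage degenerates to unconstrained
  expect_equal(coverage_to_constraints(tr, "chr1", 30, 34, "+"), "....")
  # full coverage
  expect_equal(coverage_to_constraints(tr, "chr1", 11, 13, "+"), "||")
  # minus-strand transcripts read the genomic window reversed
  mreads <- aligned_reads("chr1", 20, 23, "-")
  tr2 <- build_coverage(mreads, cs)
  expect_equal(coverage_to_constraints(tr2, "chr1", 19, 24, "-"), ".|||.")
  expect_equal(coverage_to_constraints(tr2, "chr1", 18, 24, "-"), ".|||..")
  # plus-strand coverage is invisible on the minus strand
  expect_equal(coverage_to_constraints(tr, "chr1", 10, 14, "-"), "....")
})

test_that("the builtin engine maximizes pairs with deterministic traceback", {
  m <- nussinov_fold("GGGAAACCC")
  expect_equal(m$score, 3L)
  expect_equal(m$structure, "(((...)))")
  expect_equal(m$pairs, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_equal(nussinov_fold("AAAA")$structure, "....")
  expect_identical(nussinov_fold("GGGAAACCC"), nussinov_fold("GGGAAACCC"))
  # T input is treated as U
  expect_equal(nussinov_fold("GGGAAATTT")$score, 3L)
})

test_that("builtin pair counts equal the exhaustive enumeration oracle", {
  seqs <- dsrnatk:::local_seed(101, {
    vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
  for (s in seqs) {
    expect_equal(nussinov_fold(s)$score, bf_max_pairs(s), info = s)
  }
})

test_that("constrained folds pair every '|' or fail loudly", {
  # feasible constraint: constrained positions end up paired
  m <- nussinov_fold("GGGAAAACCC", "|........|")
  expect_true(all(m$pairs[c(1, 10)] > 0))
  # GCGC fully constrained: infeasible at min_loop 3, 2 pairs at min_loop 0
  expect_error(nussinov_fold("GCGC", "||||", min_loop = 3), "infeasible")
  m2 <- nussinov_fold("GCGC", "||||", min_loop = 0)
  expect_equal(m2$score, 2L)
  expect_true(all(m2$pairs > 0))
  # no admissible partner anywhere: error names the position
  expect_error(nussinov_fold("AAAA", "|..."), "position\\(s\\) 1")
  # interaction infeasibility (both pairable only with each other under
  # min_loop, but '|' on three bases)
  expect_error(nussinov_fold("GAAAC", "|...|", min_loop = 3), NA)
  expect_error(nussinov_fold("GAAACG", "|...||", min_loop = 3),
               "infeasible")
})

test_that("all-dot constraints reproduce the unconstrained fold bit for bit", {
  seqs <- c("GGGAAACCC", "GCAUGCAUGCAU", "AUGGCCAAUUGG")
  for (s in seqs) {
    un <- nussinov_fold(s)
    con <- nussinov_fold(s, strrep(".", nchar(s)))
    expect_equal(con$structure, un$structure)
    expect_equal(con$score, un$score)
    expect_equal(con$pairs, un$pairs)
  }
})

test_that("pair tables respect min_loop and the pairing alphabet", {
  seqs <- dsrnatk:::local_seed(202, {
    vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "U"), 15, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (s in seqs) {
    m <- nussinov_fold(s)
    idx <- which(m$pairs > seq_along(m$pairs))
    for (i in idx) {
      j <- m$pairs[i]
      expect_gt(j - i, 3)
      expect_true(paste0(substr(s, i, i), substr(s, j, j)) %in% ok)
    }
  }
})

test_that("the thermodynamic adapter parses RNAfold output and honors constraints", {
  un <- fold_rna("GGGGAAAACCCC", engine = "vienna")
  expect_equal(un$structure, "((((....))))")
  expect_lt(un$score, 0)
  # all-dot constraint reproduces the unconstrained output exactly
  free <- fold_rna("GGGGAAAACCCC", strrep(".", 12), engine = "vienna")
  expect_identical(free$structure, un$structure)
  expect_identical(free$score, un$score)
  con <- fold_rna("GGGGAAAACCCC", "||||....||||", engine = "vienna")
  expect_true(all(con$pairs[c(1:4, 9:12)] > 0))
  expect_error(fold_rna("GGGAAACCC", "...", engine = "vienna"), "length")
})

test_that("read densities are normalized by covered transcript length", {
  cs <- c(chr1 = 100L)
  reads <- aligned_reads("chr1", c(10, 10), c(20, 20), c("+", "+"))
  tr <- build_coverage(reads, cs)
  m <- nussinov_fold(strrep("A", 10))
  m <- project_reads(m, tr, "chr1", 10, 20, "+")
  expect_equal(m$density, rep(2 / 10, 10))
  m0 <- project_reads(m, tr, "chr1", 50, 60, "+")
  expect_equal(m0$density, rep(0, 10))
  # mixed coverage: depth / covered count per base
  r2 <- aligned_reads("chr1", 10, 15, "+")
  t2 <- build_coverage(r2, cs)
  m2 <- project_reads(m, t2, "chr1", 10, 20, "+")
  expect_equal(m2$density, c(rep(1 / 5, 5), rep(0, 5)))
})

test_that("CT and dot-bracket files round-trip structure models", {
  m <- nussinov_fold("GGCGAAAGCGCC")
  f <- withr::local_tempfile(fileext = ".ct")
  write_ct(m, f)
  m2 <- read_ct(f)
  expect_identical(m2$pairs, m$pairs)
  expect_equal(m2$seq, m$seq)
  f2 <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(m, f2)
  m3 <- read_dotbracket(f2)
  expect_identical(m3$pairs, m$pairs)
  expect_equal(m3$score, m$score)
  # unpaired-only model: all partners zero
  m4 <- nussinov_fold("AAAA")
  write_ct(m4, f)
  expect_true(all(read_ct(f)$pairs == 0))
  # unbalanced dot-bracket errors on read
  writeLines(c(">x 0", "GGGAAACCC", "(((...)"), f2)
  expect_error(read_dotbracket(f2), "unbalanced")
})

test_that("coverage-constrained folding works end to end on simulated data", {
  ds <- small_dataset()
  cs <- ds$config$chrom_sizes
  track <- build_coverage(ds$reads$ds_a, cs)
  hs <- ds$truth$hotspots[1, ]
  start <- hs$start
  end <- hs$start + 80L            # fold the first 80 nt of a hotspot
  seq <- as.character(Biostrings::subseq(ds$genome[[hs$chrom]],
                                         start + 1L, end))
  con <- coverage_to_constraints(track, hs$chrom, start, end, "*")
  expect_equal(nchar(con), 80L)
  # hotspots are fully covered, so every position is constrained
  expect_equal(con, strrep("|", 80))
  # per-base rule: '|' exactly where depth > 0 on the requested strand
  con_plus <- coverage_to_constraints(track, hs$chrom, start, end, "+")
  depth_plus <- dsrnatk:::region_depth(track, hs$chrom, start, end, "+")
  expect_equal(strsplit(con_plus, "")[[1]] == "|", depth_plus > 0)
})
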