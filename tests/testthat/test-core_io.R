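test_that("collapse_reads tallies non-redundant sequences and conserves copies", {
  expect_identical(collapse_reads(c("ACG", "ACG", "TTT")),
                   c(ACG = 2L, TTT = 1L))
  expect_equal(clone_abundance(collapse_reads(c("ACG", "ACG", "TTT"))), 1.5)
  expect_identical(collapse_reads("A"), c(A = 1L))
  expect_length(collapse_reads(character()), 0)
  expect_error(collapse_reads(c("ACG", "XYZ")), "alphabet")

  # 1000 draws with replacement from a 100-sequence pool
  pool <- dsrnatk:::local_seed(42, {
    vapply(1:100, function(i) {
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  drawn <- dsrnatk:::local_seed(43, sample(pool, 1000, replace = TRUE))
  nr <- collapse_reads(drawn)
  expect_equal(sum(nr), 1000L)
  expect_lte(length(nr), 100L)
  expect_identical(nr[names(table(drawn))], setNames(as.integer(table(drawn)),
                                                     names(table(drawn))))
})

test_that("trim_adapter truncates at the adapter junction and retains non-matches", {
  expect_identical(trim_adapter("ACGTGATCG", "GATCG", 5),
                   list(seq = "ACGT", found = TRUE))
  expect_identical(trim_adapter("ACGTACGT", "TTTTT", 5),
                   list(seq = "ACGTACGT", found = FALSE))
  # read that is pure adapter trims to the empty string
  expect_identical(trim_adapter("GATCG", "GATCG", 5),
                   list(seq = "", found = TRUE))
  # adapter longer than the read: unchanged
  expect_identical(trim_adapter("ACG", "GATCGAA", 5),
                   list(seq = "ACG", found = FALSE))
  # partial adapter prefix at the 3' end, above the overlap floor
  expect_identical(trim_adapter("AAAAAGATCG", "GATCGTTTTT", 5),
                   list(seq = "AAAAA", found = TRUE))
  # same suffix below the overlap floor is not recognized
  expect_identical(trim_adapter("AAAAAGAT", "GATCGTTTTT", 5)$found, FALSE)
})

test_that("preprocess_reads trims, merges collisions and drops short products", {
  res <- preprocess_reads(
    c("ACGTACGTACGTACGTAACCGATCGAA",  # trims to 19 nt
      "ACGTACGTACGTACGTAACCGATCGAA",  # same NR sequence
      "AAAAGATCGTT",                  # trims to 4 nt -> discarded
      "GGGGGGGGGGGGGGGG"),            # no adapter, retained
    adapter = "GATCG", min_overlap = 5, min_length = 15)
  expect_equal(sum(res$copies), 3)
  expect_true("ACGTACGTACGTACGTAACC" %in% names(res$copies))
  expect_equal(unname(res$copies["ACGTACGTACGTACGTAACC"]), 2L)
  expect_equal(res$n_discarded, 1L)
  expect_equal(res$n_raw, 4L)
})

test_that("BED6 round trip is lossless and field mapping is exact", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t31\tnr7/2\t4\t+", f)
  reads <- read_bed(f)
  expect_equal(reads$chrom, "chr1")
  expect_equal(reads$start, 10L)
  expect_equal(reads$end, 31L)
  expect_equal(reads$name, "nr7")
  expect_equal(reads$copies, 4)
  expect_equal(reads$n_hits, 2L)
  expect_equal(reads$weight, 2)

  r <- random_reads(200, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f2)
  again <- read_bed(f2)
  expect_equal(again, r)
  # byte-level round trip of the file
  f3 <- withr::local_tempfile(fileext = ".bed")
  write_bed(again, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("malformed BED records fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t31\tnr1/1\t1\t+",
               "chr1\t31\t10\tnr2/1\t1\t+"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t1\t5\tnr1/1\t1\tx", f)
  expect_error(read_bed(f), "strand")
  writeLines("chrZ\t1\t5\tnr1/1\t1\t+", f)
  expect_error(read_bed(f, chrom_sizes = toy_sizes), "chrZ")
  writeLines("chr1\t9990\t10020\tnr1/1\t1\t+", f)
  expect_error(read_bed(f, chrom_sizes = toy_sizes), "exceeds")
})

test_that("GFF3 reading converts coordinates and maps types", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttRNA\t101\t180\t.\t+\t.\tID=t1",
               "chr1\tsrc\tfive_prime_UTR\t201\t250\t.\t-\t.\tID=u1;Parent=g1",
               "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1"), f)
  ann <- read_gff3(f)
  expect_equal(nrow(ann), 2L)  # gene container dropped
  expect_equal(ann$start[ann$feature_id == "t1"], 100L)
  expect_equal(ann$end[ann$feature_id == "t1"], 180L)
  expect_equal(ann$category[ann$feature_id == "u1"], "UTR5")
  expect_equal(ann$parent_id[ann$feature_id == "u1"], "g1")

  writeLines("chr1\tsrc\ttRNA\t180\t101\t.\t+\t.\tID=t1", f)
  expect_error(read_gff3(f), "line 1")
  writeLines("chr1\tsrc\tweird_type\t1\t50\t.\t+\t.\tID=w1", f)
  expect_warning(ann2 <- read_gff3(f), "weird_type")
  expect_equal(ann2$category, "other_ncRNA")
})

test_that("GFF3 round trip preserves coordinates exactly", {
  ann <- nested_annotation()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  again <- read_gff3(f)
  a1 <- ann[order(ann$feature_id), ]
  a2 <- again[order(again$feature_id), names(ann)]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a2, a1)
})

test_that("build_coverage matches brute-force per-base accumulation", {
  cs <- c(chr1 = 10L)
  r1 <- aligned_reads("chr1", 2, 5, "+")
  tr <- build_coverage(r1, cs)
  expect_equal(tr$chr1$plus, c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0))
  # linearity: two half-weight copies equal one unit read
  r2 <- aligned_reads("chr1", c(2, 2), c(5, 5), c("+", "+"),
                      copies = 1, n_hits = 2)
  expect_equal(build_coverage(r2, cs)$chr1$plus, tr$chr1$plus)

  r <- random_reads(300, seed = 9)
  track <- build_coverage(r, toy_sizes)
  expect_equal(track$chr1$plus,
               bf_depth(r, "chr1", toy_sizes[["chr1"]], "+"))
  expect_equal(track$chr1$minus,
               bf_depth(r, "chr1", toy_sizes[["chr1"]], "-"))
  expect_equal(coverage_mass(track),
               sum(r$weight * (r$end - r$start)))
  expect_error(build_coverage(aligned_reads("chr1", 5, 12, "+"), cs),
               "exceeds")
})

test_that("coverage is additive over read sets", {
  a <- random_reads(100, seed = 21)
  b <- random_reads(80, seed = 22)
  ta <- build_coverage(a, toy_sizes)
  tb <- build_coverage(b, toy_sizes)
  tab <- build_coverage(rbind(a, b), toy_sizes)
  expect_equal(tab$chr1$plus, ta$chr1$plus + tb$chr1$plus)
  expect_equal(tab$chr1$minus, ta$chr1$minus + tb$chr1$minus)
})

test_that("covered_length counts bases with combined depth", {
  cs <- c(chr1 = 10L)
  empty <- build_coverage(aligned_reads(character(), integer(), integer(),
                                        character()), cs)
  expect_equal(covered_length(empty, "chr1", 0, 10), 0)
  one <- build_coverage(aligned_reads("chr1", 2, 5, "+"), cs)
  expect_equal(covered_length(one, "chr1", 0, 10), 3)
  two <- build_coverage(aligned_reads("chr1", c(2, 4), c(5, 8),
                                      c("+", "-")), cs)
  expect_equal(covered_length(two, "chr1", 0, 10), 6)

  r <- random_reads(150, seed = 13)
  track <- build_coverage(r, toy_sizes)
  expect_equal(covered_length(track, "chr1", 100, 8000),
               bf_covered_length(r, "chr1", 100, 8000, toy_sizes[["chr1"]]))
})

test_that("size_distribution bins weight by read length", {
  r <- random_reads(200, seed = 17, len_range = c(17L, 30L))
  sd <- size_distribution(r)
  expect_equal(sum(sd), sum(r$weight))
  len <- r$end - r$start
  expect_equal(unname(sd["21"]), sum(r$weight[len == 21]))
  expect_equal(unname(sd["other"]),
               sum(r$weight[len < 19 | len > 26]))
  empty <- size_distribution(r[0, ])
  expect_true(all(empty == 0))
})
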