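test_that("merge_segments equals a brute-force run scan of the depth array", {
  cs <- c(chr1 = 20L)
  reads <- aligned_reads("chr1", c(2, 4, 10), c(5, 8, 12),
                         c("+", "-", "+"))
  segs <- merge_segments(build_coverage(reads, cs), reads)
  expect_equal(segs$start, c(2, 10))
  expect_equal(segs$end, c(8, 12))
  expect_equal(segs$length, c(6, 2))
  expect_equal(segs$n_reads, c(2L, 1L))
  expect_equal(segs$plus_weight, c(1, 1))
  expect_equal(segs$minus_weight, c(1, 0))

  r <- random_reads(120, seed = 31)
  segs2 <- merge_segments(build_coverage(r, toy_sizes), r)
  d <- bf_depth(r, "chr1", toy_sizes[["chr1"]])
  runs <- rle(d > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  expect_equal(segs2$start, starts[runs$values])
  expect_equal(segs2$end, ends[runs$values])
  # segment weights partition the library mass (reads never straddle gaps)
  expect_equal(sum(segs2$weight), sum(r$weight))
})

test_that("fit_geometric is the method-of-moments estimator", {
  m <- fit_geometric(c(2, 2, 2), chrom = "chrX")
  expect_equal(m$mean_length, 2)
  expect_equal(m$p_hat, 0.5)
  degen <- fit_geometric(c(1, 1, 1, 1), chrom = "chrX")
  expect_equal(degen$p_hat, 1)
  expect_equal(geometric_tail(2, degen$p_hat), 0)
  expect_error(fit_geometric(5, chrom = "chrY"), "pooled")

  lens <- dsrnatk:::local_seed(77, rgeom(10000, 0.05) + 1)
  fit <- fit_geometric(lens, chrom = "sim")
  # moment estimator within 3 standard errors of truth
  se <- 0.05 * sqrt(1 - 0.05) / sqrt(10000)
  expect_lt(abs(fit$p_hat - 0.05), 3 * se)
})

test_that("geometric_tail has the closed form on support {1,2,...}", {
  expect_equal(geometric_tail(1, 0.3), 1)
  expect_equal(geometric_tail(5, 0.5), 0.0625)
  L <- 1:150
  expect_true(all(diff(geometric_tail(L, 0.2)) < 0))
  for (p in c(0.05, 0.5)) {
    for (l in c(1, 7, 60)) {
      expect_equal(geometric_tail(l, p), bf_geom_tail(l, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("call_hotspots applies BH genome-wide and is deterministic", {
  # 1000 background segments at the mean, one 20x outlier
  segs <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 60L, length.out = 1001L),
                     end = seq(0L, by = 60L, length.out = 1001L) + 30L,
                     stringsAsFactors = FALSE)
  segs$end[1001] <- segs$start[1001] + 600L
  segs$length <- segs$end - segs$start
  segs$n_reads <- 5L
  model <- fit_geometric(segs$length)
  hs <- call_hotspots(segs, model)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$length, 600L)
  expect_match(hs$id, "^chr1_h1$")
  # all segments exactly at the mean: nothing called
  segs0 <- segs[1:1000, ]
  expect_equal(nrow(call_hotspots(segs0, fit_geometric(segs0$length))), 0L)
  # determinism
  expect_identical(call_hotspots(segs, model), call_hotspots(segs, model))
})

test_that("hotspot calls are monotone in alpha and respect min_reads", {
  ds <- small_dataset()
  cs <- ds$config$chrom_sizes
  track <- build_coverage(ds$reads$ds_a, cs)
  segs <- merge_segments(track, ds$reads$ds_a)
  models <- fit_geometric_models(segs)
  h05 <- call_hotspots(segs, models, alpha = 0.05)
  h01 <- call_hotspots(segs, models, alpha = 0.01)
  key <- function(h) paste(h$chrom, h$start, h$end)
  expect_true(all(key(h01) %in% key(h05)))
  # hotspots are maximal covered segments: disjoint by construction
  expect_true(all(key(h05) %in% paste(segs$chrom, segs$start, segs$end)))
  ov <- dsrnatk:::overlap_pairs(h05, h05)
  expect_true(all(ov$q == ov$s))
  # single-read segments never surface
  expect_true(all(h05$n_reads >= 2))
})

test_that("planted hotspots are recovered on the small dataset", {
  ds <- small_dataset()
  hs <- hotspots_from_reads(ds$reads$ds_a, ds$config$chrom_sizes,
                            annotations = ds$annotations)
  ev <- evaluate_calls(hs, ds$truth$hotspots)
  expect_gte(ev$sensitivity, 0.9)
  # calls not explained by planted hotspots must be the dense planted
  # differential bins (long covered runs in their own right)
  diff_ds <- ds$truth$diff_bins[ds$truth$diff_bins$assay %in%
                                  c("both", "ds"), ]
  expected <- rbind(ds$truth$hotspots,
                    diff_ds[, c("chrom", "start", "end")])
  ev2 <- evaluate_calls(hs, expected)
  expect_lte(ev2$false_calls, 3)
})

test_that("hotspot/smRNA overlap percentages count bases", {
  cs <- c(chr1 = 1000L)
  hs <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 200L),
                   category = c("tRNA", "intergenic"),
                   stringsAsFactors = FALSE)
  empty <- build_coverage(aligned_reads(character(), integer(), integer(),
                                        character()), cs)
  suppressMessages(ov0 <- hotspot_smrna_overlap(hs, empty))
  expect_true(all(ov0$percent == 0))
  # exact coverage -> 100%
  sm_all <- build_coverage(aligned_reads("chr1", c(0, 100), c(50, 200),
                                         c("+", "+")), cs)
  suppressMessages(ov1 <- hotspot_smrna_overlap(hs, sm_all))
  expect_true(all(ov1$percent == 100))
  # half of the tRNA hotspot covered -> 50%
  sm_half <- build_coverage(aligned_reads("chr1", 0, 25, "+"), cs)
  suppressMessages(ov2 <- hotspot_smrna_overlap(hs, sm_half))
  expect_equal(ov2$percent[ov2$category == "tRNA"], 50)
  expect_equal(ov2$percent[ov2$category == "intergenic"], 0)
})

test_that("novel units are unannotated hotspots flagged by smRNA-hotspot overlap", {
  ann <- nested_annotation()
  hs <- data.frame(
    chrom = "chr1",
    start = c(1610L, seq(3000L, 3900L, by = 100L)),
    end = c(1660L, seq(3000L, 3900L, by = 100L) + 60L),
    id = paste0("chr1_h", 1:11),
    category = "x", stringsAsFactors = FALSE)
  # 4 of the 10 intergenic hotspots overlap smRNA hotspots (one by 1 bp)
  smhs <- data.frame(chrom = "chr1",
                     start = c(3000L, 3100L, 3200L, 3359L),
                     end = c(3040L, 3160L, 3260L, 3400L),
                     stringsAsFactors = FALSE)
  nov <- discover_novel(hs, ann, smhs)
  expect_equal(nrow(nov), 10L)           # the tRNA-overlapping one drops out
  expect_false("chr1_h1" %in% nov$id)
  expect_equal(sum(nov$smrna_overlap), 4L)
  expect_true(nov$smrna_overlap[nov$start == 3300])  # 1 bp overlap counts
  # size classes from overlapping smRNA reads
  sm_reads <- aligned_reads("chr1", c(3010, 3012, 3950), c(3031, 3036, 3974),
                            c("+", "+", "+"))
  nov2 <- discover_novel(hs, ann, smhs, smrna_reads = sm_reads)
  sc <- attr(nov2, "size_classes")
  expect_equal(unname(sc[nov2$start == 3000, "21"]), 1)
  expect_equal(unname(sc[nov2$start == 3000, "24"]), 1)
  expect_equal(unname(sc[nov2$start == 3900, "24"]), 1)
})
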