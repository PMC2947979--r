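# Shared fixtures, generated in code.

.fixture_cache <- new.env(parent = emptyenv())

# Full-size synthetic dataset (seed 7, no differential planting): the
# hotspot-recovery study conditions. Computed once per test run.
hotspot_dataset <- function() {
  if (is.null(.fixture_cache$hs)) {
    .fixture_cache$hs <- simulate_dataset(
      simulation_config(seed = 7, diff_n_both = 0L, diff_n_ds = 0L,
                        diff_n_sm = 0L, phased_n = 0L))
  }
  .fixture_cache$hs
}

# Small coherent dataset exercising every component quickly.
small_dataset <- function(seed = 11) {
  key <- paste0("small", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_dataset(simulation_config(
      seed = seed,
      chrom_sizes = c(chrA = 60000L, chrB = 40000L),
      n_segments = 1500L, hotspot_n = 8L, hotspot_length = 500L,
      diff_zone_frac = 0.2,
      diff_n_both = 4L, diff_n_ds = 2L, diff_n_sm = 2L, phased_n = 2L,
      n_sm_background = 4000L,
      features = list(tRNA = c(2L, 80L), rRNA = c(1L, 300L),
                      miRNA = c(1L, 120L),
                      transposable_element = c(2L, 500L)),
      n_mrna = 2L))
  }
  .fixture_cache[[key]]
}

# Hand-laid annotation: a plus-strand mRNA with a tRNA nested in its
# intron, on a 10 kb chromosome.
nested_annotation <- function() {
  data.frame(
    chrom = "chr1",
    start = c(1000L, 1150L, 1550L, 1850L, 2250L, 1600L, 5000L),
    end   = c(1150L, 1550L, 1850L, 2250L, 2450L, 1680L, 5500L),
    strand = c("+", "+", "+", "+", "+", "+", "-"),
    category = c("UTR5", "exon_CDS", "intron", "exon_CDS",
                 "UTR3", "tRNA", "transposable_element"),
    feature_id = c("g1.utr5", "g1.cds1", "g1.int", "g1.cds2",
                   "g1.utr3", "trna1", "te1"),
    parent_id = c("g1", "g1", "g1", "g1", "g1", "", ""),
    stringsAsFactors = FALSE)
}

toy_sizes <- c(chr1 = 10000L)

random_reads <- function(n, chrom_sizes = toy_sizes, seed = 1,
                         len_range = c(19L, 40L)) {
  dsrnatk:::local_seed(seed, {
    ch <- names(chrom_sizes)[sample.int(length(chrom_sizes), n,
                                        replace = TRUE)]
    len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    start <- floor(runif(n) * (chrom_sizes[ch] - len))
    aligned_reads(ch, start, start + len,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  copies = sample(1:4, n, replace = TRUE),
                  n_hits = sample(1:3, n, replace = TRUE))
  })
}
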