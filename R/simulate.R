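# Deterministic synthetic-data generator with truth manifests.
#
# The generator emulates the genomic footprint of a dsRNA-seq / smRNA-seq
# experiment: maximal read-covered segments whose lengths follow a
# geometric distribution (the hotspot null), planted over-long fully
# covered hotspots, paired wild-type/mutant libraries with planted
# fold-change bins, phased small-RNA loci, and a per-base conservation
# track elevated inside hotspots. One integer seed governs everything;
# deterministic sub-streams are derived per component so outputs are
# byte-identical across runs.
#
# Genome layout: the trailing `diff_zone_frac` of every chromosome is a
# differential zone holding the planted fold-change bins (and the phased
# loci nested in them); background covered segments and planted hotspots
# occupy the remainder, placed with at least 1 nt between segments so the
# observed maximal covered runs are exactly the drawn lengths.

#' Build a simulation configuration
#'
#' Defaults describe the standard synthetic study: a 1 Mb two-chromosome
#' genome carrying 20,000 background covered segments (geometric mean
#' length 40 nt) and 50 planted 400-nt fully covered hotspots; paired
#' libraries with 1 kb bins, ~50 weight per planted bin on the low side
#' and 4-fold planted differential regions (10 in both assays, 5
#' dsRNA-only, 5 smRNA-only); 3 of the double-planted bins produce phased
#' 21-nt small RNAs; conservation scores of 0.2 (background) versus 0.9
#' (hotspots) with sd 0.05.
#'
#' @param seed Integer master seed.
#' @param ... Overrides for any default (see the source for field names);
#'   unknown names raise an error.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chr1 = 600000L, chr2 = 400000L),
    # background covered-segment model
    n_segments = 20000L,
    segment_mean = 40,
    ds_read_lengths = 19:45,
    ds_read_probs = c(rep(2, 8), rep(1, 19)),  # small-RNA sizes + longer
    tile_step = 15L,
    # planted hotspots
    hotspot_n = 50L,
    hotspot_length = 400L,
    hotspot_depth = 2L,
    # differential 1 kb bins (in the trailing zone of each chromosome)
    bin_width = 1000L,
    diff_zone_frac = 0.06,
    diff_n_both = 10L,
    diff_n_ds = 5L,
    diff_n_sm = 5L,
    diff_fold = 4,
    diff_weight = 50,
    sm_read_lengths = 20:24,
    sm_read_probs = c(1, 4, 1, 1, 2),
    n_sm_background = 5000L,
    # phased loci (inside double-planted bins)
    phased_n = 3L,
    phase_cycle = 21L,
    phase_register = 7L,
    # annotation layout: category -> c(count, length)
    features = list(rRNA = c(2L, 300L), tRNA = c(4L, 80L),
                    snoRNA = c(3L, 100L), snRNA = c(2L, 150L),
                    miRNA = c(3L, 120L),
                    transposable_element = c(6L, 500L),
                    other_ncRNA = c(3L, 200L)),
    n_mrna = 6L,
    # conservation model
    cons_background = 0.2,
    cons_hotspot = 0.9,
    cons_sd = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation_config field(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

sub_seed <- function(cfg, k) (cfg$seed * 101L + k * 1009L) %% 2000000011L

# Draw m items from x (with replacement) guarding the length-1 case.
draw <- function(x, m, prob = NULL) {
  x[sample.int(length(x), m, replace = TRUE, prob = prob)]
}

# Lay out segment lengths inside [block_start, block_end) with >= 1 nt
# between consecutive segments; slack spread multinomially over the gap
# slots; order randomized. Errors when the segments cannot fit.
layout_segments <- function(block_start, block_end, lengths, labels) {
  n <- length(lengths)
  if (!n) {
    return(data.frame(start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  space <- block_end - block_start
  free <- space - sum(lengths) - (n - 1L)
  if (free < 0) {
    stop(sprintf(
      "segment layout exceeds available space (%d nt needed, %d free)",
      sum(lengths) + n - 1L, space))
  }
  ord <- sample.int(n)
  lengths <- lengths[ord]
  labels <- labels[ord]
  extra <- as.integer(rmultinom(1, free, rep(1, n + 1L)))
  gaps <- extra[seq_len(n)] + c(0L, rep(1L, n - 1L))
  starts <- block_start + cumsum(gaps) + cumsum(c(0L, lengths))[seq_len(n)]
  data.frame(start = starts, end = starts + lengths, label = labels,
             stringsAsFactors = FALSE)
}

# Tile [start, end) segments with reads so every base is covered and every
# segment of length >= 2 carries >= 2 distinct reads. One read length per
# segment, drawn from the configured distribution; consecutive reads
# advance by `step`.
tile_reads <- function(chrom, starts, ends, read_lengths, read_probs,
                       step, depth = 1L) {
  n <- length(starts)
  if (!n) {
    return(aligned_reads(character(), integer(), integer(), character()))
  }
  L <- ends - starts
  rl <- pmin(draw(read_lengths, n, read_probs), L)
  k <- pmax(1L, as.integer(ceiling((L - rl) / step)) + 1L)
  rs <- rep(starts, k) + (sequence(k) - 1L) * step
  rs <- pmin(rs, rep(ends, k) - rep(rl, k))
  re <- rs + rep(rl, k)
  ch <- rep(rep(chrom, length.out = n), k)
  single <- k == 1L & L >= 2L
  if (any(single)) {
    rs <- c(rs, starts[single])
    re <- c(re, ends[single] - 1L)
    ch <- c(ch, rep(chrom, length.out = n)[single])
  }
  if (depth > 1L) {
    rs <- rep(rs, depth)
    re <- rep(re, depth)
    ch <- rep(ch, depth)
  }
  aligned_reads(ch, rs, re,
                strand = draw(c("+", "-"), length(rs)))
}

# Uniform reads inside a bin; count drawn Poisson(lambda).
bin_reads <- function(chrom, start, end, lambda, read_lengths, read_probs) {
  n <- rpois(1, lambda)
  if (!n) {
    return(aligned_reads(character(), integer(), integer(), character()))
  }
  rl <- pmin(draw(read_lengths, n, read_probs), end - start)
  rs <- start + floor(runif(n) * (end - start - rl + 1))
  aligned_reads(rep(chrom, n), rs, rs + rl, strand = draw(c("+", "-"), n))
}

# Phased reads: 21-nt plus-strand reads whose 5' ends sit on one register
# of the 21-nt grid of the locus.
phased_reads <- function(chrom, start, end, n, D, register) {
  grid <- seq.int(start + register, end - D, by = D)
  rs <- draw(grid, n)
  aligned_reads(rep(chrom, n), rs, rs + D, strand = rep("+", n))
}

rbind_reads <- function(...) {
  parts <- Filter(nrow, list(...))
  if (!length(parts)) {
    return(aligned_reads(character(), integer(), integer(), character()))
  }
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out$name <- paste0("nr", seq_len(nrow(out)))
  out
}

#' Simulate a complete synthetic dataset
#'
#' Generates a toy genome, annotation, paired dsRNA-seq and smRNA-seq
#' libraries (A = wild-type-like, B = mutant-like), a conservation track,
#' and a truth manifest recording every planted element. Background reads
#' are identical in the A and B libraries (a paired design), so only the
#' planted fold-change bins differ between them. Planted hotspot and
#' differential intervals never overlap. The same seed reproduces every
#' output bit for bit.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `chrom.sizes`, `ds_a.bed`, `ds_b.bed`, `sm_a.bed`,
#'   `sm_b.bed`, `conservation.bedgraph` and `truth_*.tsv` files there.
#' @return List with `genome` (DNAStringSet), `annotations`, `reads` (list
#'   `ds_a`, `ds_b`, `sm_a`, `sm_b`), `conservation` (`cons_track`),
#'   `truth` (list of manifests) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  cfg <- config
  cs <- cfg$chrom_sizes
  w <- cfg$bin_width
  # zone boundary per chromosome, aligned to bins
  n_bins <- pmax(cs %/% w, 1L)
  n_zone <- pmax(as.integer(ceiling(n_bins * cfg$diff_zone_frac)), 1L)
  names(n_zone) <- names(n_bins)
  zone_start <- (n_bins - n_zone) * w
  # --- genome ----------------------------------------------------------
  genome <- local_seed(sub_seed(cfg, 1L), {
    seqs <- vapply(names(cs), function(ch) {
      paste(draw(c("A", "C", "G", "T"), cs[[ch]]), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
  # --- annotation (outside the differential zone) ----------------------
  annotations <- local_seed(sub_seed(cfg, 2L),
                            simulate_annotation(cfg, zone_start))
  # --- planted differential bins ---------------------------------------
  n_planted <- cfg$diff_n_both + cfg$diff_n_ds + cfg$diff_n_sm
  truth_diff <- local_seed(sub_seed(cfg, 3L), {
    zone_bins <- list()
    for (ch in names(cs)) {
      st <- seq.int(zone_start[[ch]], (n_bins[[ch]] - 1L) * w, by = w)
      zone_bins[[ch]] <- interval_df(ch, st, st + w, "*")
    }
    zone_bins <- do.call(rbind, c(zone_bins, list(make.row.names = FALSE)))
    if (n_planted > nrow(zone_bins)) {
      stop("differential zone too small for the planted bins; ",
           "increase diff_zone_frac or the genome size")
    }
    sel <- sort(sample.int(nrow(zone_bins), n_planted))
    assay <- sample(rep(c("both", "ds", "sm"),
                        c(cfg$diff_n_both, cfg$diff_n_ds, cfg$diff_n_sm)))
    phased <- logical(n_planted)
    both_idx <- which(assay == "both")
    if (length(both_idx)) {
      phased[both_idx[sample.int(length(both_idx),
                                 min(cfg$phased_n, length(both_idx)))]] <-
        TRUE
    }
    data.frame(zone_bins[sel, , drop = FALSE],
               assay = assay, fold = rep(cfg$diff_fold, n_planted),
               phased = phased,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  # --- covered-segment layout ------------------------------------------
  layout <- local_seed(sub_seed(cfg, 4L), {
    seg_alloc <- round(cfg$n_segments * (cs / sum(cs)))
    seg_alloc[length(seg_alloc)] <-
      cfg$n_segments - sum(seg_alloc[-length(seg_alloc)])
    hs_alloc <- round(cfg$hotspot_n * (cs / sum(cs)))
    hs_alloc[length(hs_alloc)] <-
      cfg$hotspot_n - sum(hs_alloc[-length(hs_alloc)])
    out <- list()
    for (ch in names(cs)) {
      lens <- rgeom(seg_alloc[[ch]], 1 / cfg$segment_mean) + 1L
      labs <- rep("background", length(lens))
      lens <- c(lens, rep(cfg$hotspot_length, hs_alloc[[ch]]))
      labs <- c(labs, rep("hotspot", hs_alloc[[ch]]))
      df <- layout_segments(0L, zone_start[[ch]], lens, labs)
      df$chrom <- ch
      out[[ch]] <- df
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  truth_hotspots <- layout[layout$label == "hotspot",
                           c("chrom", "start", "end"), drop = FALSE]
  truth_hotspots <- truth_hotspots[order(truth_hotspots$chrom,
                                         truth_hotspots$start), ,
                                   drop = FALSE]
  rownames(truth_hotspots) <- NULL
  bg <- layout[layout$label == "background", , drop = FALSE]
  # --- dsRNA libraries --------------------------------------------------
  ds <- local_seed(sub_seed(cfg, 5L), {
    base <- list()
    for (ch in unique(layout$chrom)) {
      sub <- layout[layout$chrom == ch, , drop = FALSE]
      hs <- sub$label == "hotspot"
      base[[ch]] <- rbind_reads(
        tile_reads(ch, sub$start[!hs], sub$end[!hs],
                   cfg$ds_read_lengths, cfg$ds_read_probs, cfg$tile_step),
        tile_reads(ch, sub$start[hs], sub$end[hs],
                   cfg$ds_read_lengths, cfg$ds_read_probs, cfg$tile_step,
                   depth = cfg$hotspot_depth))
    }
    base <- do.call(rbind_reads, base)
    extra_a <- list()
    extra_b <- list()
    for (i in seq_len(nrow(truth_diff))) {
      td <- truth_diff[i, ]
      if (!(td$assay %in% c("both", "ds"))) next
      extra_a[[length(extra_a) + 1L]] <-
        bin_reads(td$chrom, td$start, td$end,
                  cfg$diff_fold * cfg$diff_weight,
                  cfg$ds_read_lengths, cfg$ds_read_probs)
      extra_b[[length(extra_b) + 1L]] <-
        bin_reads(td$chrom, td$start, td$end, cfg$diff_weight,
                  cfg$ds_read_lengths, cfg$ds_read_probs)
    }
    list(a = do.call(rbind_reads, c(list(base), extra_a)),
         b = do.call(rbind_reads, c(list(base), extra_b)))
  })
  # --- smRNA libraries --------------------------------------------------
  sm <- local_seed(sub_seed(cfg, 6L), {
    # background scatter stays outside the differential zone so planted
    # bins carry exactly the designed fold
    n <- cfg$n_sm_background
    ch <- draw(names(cs), n, prob = zone_start)
    rl <- draw(cfg$sm_read_lengths, n, cfg$sm_read_probs)
    rs <- floor(runif(n) * (zone_start[ch] - rl))
    bgr <- aligned_reads(ch, rs, rs + rl, strand = draw(c("+", "-"), n))
    extra_a <- list()
    extra_b <- list()
    for (i in seq_len(nrow(truth_diff))) {
      td <- truth_diff[i, ]
      if (!(td$assay %in% c("both", "sm"))) next
      n_a <- rpois(1, cfg$diff_fold * cfg$diff_weight)
      extra_a[[length(extra_a) + 1L]] <- if (td$phased) {
        phased_reads(td$chrom, td$start, td$end, max(n_a, 1L),
                     cfg$phase_cycle, cfg$phase_register)
      } else {
        bin_reads(td$chrom, td$start, td$end,
                  cfg$diff_fold * cfg$diff_weight,
                  cfg$sm_read_lengths, cfg$sm_read_probs)
      }
      extra_b[[length(extra_b) + 1L]] <-
        bin_reads(td$chrom, td$start, td$end, cfg$diff_weight,
                  cfg$sm_read_lengths, cfg$sm_read_probs)
    }
    list(a = do.call(rbind_reads, c(list(bgr), extra_a)),
         b = do.call(rbind_reads, c(list(bgr), extra_b)))
  })
  # --- conservation track -----------------------------------------------
  conservation <- local_seed(sub_seed(cfg, 7L), {
    tr <- lapply(names(cs), function(ch) {
      v <- rnorm(cs[[ch]], cfg$cons_background, cfg$cons_sd)
      hs <- truth_hotspots[truth_hotspots$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(hs))) {
        idx <- (hs$start[i] + 1L):hs$end[i]
        v[idx] <- rnorm(length(idx), cfg$cons_hotspot, cfg$cons_sd)
      }
      pmin(pmax(v, 0), 1)
    })
    structure(setNames(tr, names(cs)), chrom_sizes = cs,
              class = "cons_track")
  })
  truth <- list(hotspots = truth_hotspots,
                background_segments = bg[, c("chrom", "start", "end")],
                background_lengths = bg$end - bg$start,
                diff_bins = truth_diff,
                features = annotations)
  out <- list(genome = genome, annotations = annotations,
              reads = list(ds_a = ds$a, ds_b = ds$b,
                           sm_a = sm$a, sm_b = sm$b),
              conservation = conservation, truth = truth, config = cfg)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

simulate_annotation <- function(cfg, zone_start) {
  cs <- cfg$chrom_sizes
  specs <- cfg$features
  lens <- integer()
  cats <- character()
  for (cat in names(specs)) {
    lens <- c(lens, rep(specs[[cat]][2], specs[[cat]][1]))
    cats <- c(cats, rep(cat, specs[[cat]][1]))
  }
  mrna_len <- 150L + 400L + 300L + 400L + 200L
  lens <- c(lens, rep(mrna_len, cfg$n_mrna))
  cats <- c(cats, rep("mRNA", cfg$n_mrna))
  chrom <- draw(names(cs), length(lens), prob = cs)
  feats <- list()
  for (ch in names(cs)) {
    sel <- which(chrom == ch)
    if (!length(sel)) next
    df <- layout_segments(0L, zone_start[[ch]], lens[sel], cats[sel])
    df$chrom <- ch
    feats[[ch]] <- df
  }
  feats <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    strand <- draw(c("+", "-"), 1)
    if (f$label != "mRNA") {
      out[[length(out) + 1L]] <- data.frame(
        chrom = f$chrom, start = f$start, end = f$end, strand = strand,
        category = f$label, feature_id = sprintf("f%04d", i),
        parent_id = "", stringsAsFactors = FALSE)
    } else {
      parts <- c(UTR5 = 150L, exon_CDS = 400L, intron = 300L,
                 exon_CDS2 = 400L, UTR3 = 200L)
      if (strand == "-") parts <- rev(parts)
      ends <- f$start + cumsum(parts)
      starts <- ends - parts
      out[[length(out) + 1L]] <- data.frame(
        chrom = f$chrom, start = starts, end = ends, strand = strand,
        category = sub("2$", "", names(parts)),
        feature_id = sprintf("f%04d.%d", i, seq_along(parts)),
        parent_id = sprintf("f%04d", i), stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(ds$genome, p("genome.fa"))
  write_chrom_sizes(ds$config$chrom_sizes, p("chrom.sizes"))
  write_gff3(ds$annotations, p("annotation.gff3"))
  for (lib in names(ds$reads)) {
    write_bed(ds$reads[[lib]], p(paste0(lib, ".bed")))
  }
  write_conservation(ds$conservation, p("conservation.bedgraph"))
  write.table(ds$truth$hotspots, p("truth_hotspots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$diff_bins, p("truth_diff_bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a paired two-library window experiment
#'
#' Independent Poisson read counts per bin in two libraries with matched
#' expected totals, except in `planted` bins where library A's expectation
#' is `fold` times library B's. Used for calibration (no planted bins:
#' every bin is null) and power studies of the differential window test.
#'
#' @param chrom_sizes Named integer vector.
#' @param width Bin width (default 1000).
#' @param weight Expected read weight per bin in library B (default 50).
#' @param planted Integer vector of planted bin row indices (in
#'   [bin_genome()] order).
#' @param fold Expected fold excess of library A in planted bins
#'   (default 4).
#' @param read_lengths,read_probs Read-length distribution (defaults
#'   19-26, uniform).
#' @param seed Integer seed.
#' @return List with `bins`, `reads_a`, `reads_b` and `planted`.
#' @export
simulate_window_pair <- function(chrom_sizes, width = 1000L, weight = 50,
                                 planted = integer(), fold = 4,
                                 read_lengths = 19:26, read_probs = NULL,
                                 seed = 1L) {
  bins <- bin_genome(chrom_sizes, width)
  nb <- nrow(bins)
  stopifnot(all(planted >= 1), all(planted <= nb))
  lam_a <- rep(weight, nb)
  lam_a[planted] <- weight * fold
  lam_b <- rep(weight, nb)
  gen <- function(lam) {
    n <- rpois(nb, lam)
    tot <- sum(n)
    bin_idx <- rep.int(seq_len(nb), n)
    rl <- draw(read_lengths, tot, read_probs)
    rl <- pmin(rl, bins$end[bin_idx] - bins$start[bin_idx])
    rs <- bins$start[bin_idx] +
      floor(runif(tot) * (bins$end[bin_idx] - bins$start[bin_idx] - rl + 1))
    aligned_reads(bins$chrom[bin_idx], rs, rs + rl,
                  strand = draw(c("+", "-"), tot))
  }
  local_seed(seed, {
    reads_a <- gen(lam_a)
    reads_b <- gen(lam_b)
    list(bins = bins, reads_a = reads_a, reads_b = reads_b,
         planted = planted)
  })
}

#' Match interval calls against a truth manifest
#'
#' Deterministic greedy matching at >= `min_reciprocal` reciprocal overlap
#' (each call matches at most one truth element and vice versa; candidate
#' pairs are taken in decreasing overlap order).
#'
#' @param calls,truth Interval `data.frame`s (`chrom`, `start`, `end`).
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return List with `sensitivity`, `n_truth`, `n_calls`, `n_matched`,
#'   `false_calls` (unmatched calls) and `matches` (index pairs
#'   call -> truth).
#' @export
evaluate_calls <- function(calls, truth, min_reciprocal = 0.5) {
  pairs <- overlap_pairs(calls, truth)
  if (nrow(pairs)) {
    lc <- calls$end[pairs$q] - calls$start[pairs$q]
    lt <- truth$end[pairs$s] - truth$start[pairs$s]
    pairs <- pairs[pairs$overlap >= min_reciprocal * lc &
                     pairs$overlap >= min_reciprocal * lt, , drop = FALSE]
  }
  matched_c <- logical(nrow(calls))
  matched_t <- logical(nrow(truth))
  keep <- integer()
  if (nrow(pairs)) {
    pairs <- pairs[order(-pairs$overlap, pairs$q, pairs$s), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      if (!matched_c[pairs$q[i]] && !matched_t[pairs$s[i]]) {
        matched_c[pairs$q[i]] <- TRUE
        matched_t[pairs$s[i]] <- TRUE
        keep <- c(keep, i)
      }
    }
  }
  list(sensitivity = if (nrow(truth)) sum(matched_t) / nrow(truth) else {
    NA_real_
  },
  n_truth = nrow(truth), n_calls = nrow(calls),
  n_matched = sum(matched_t), false_calls = sum(!matched_c),
  matches = pairs[keep, c("q", "s"), drop = FALSE])
}
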