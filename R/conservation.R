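# Conservation of hotspots versus flanking sequence.
#
# Per-base conservation scores (consScore, e.g. from a multi-species whole
# genome alignment) are consumed as a bedGraph; bases absent from the file
# are treated as unscored. Hotspot and flanking partitions within each
# structural moiety are compared by a Wilcoxon rank-sum test on per-region
# mean scores (per-base values are autocorrelated, so regions are the
# sampling unit).

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file (0-based half-open intervals with a score).
#' @param chrom_sizes Named integer vector.
#' @return A `cons_track`: per chromosome a numeric vector of per-base
#'   scores with `NA` at unscored bases.
#' @export
read_conservation <- function(path, chrom_sizes) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- lapply(chrom_sizes, function(n) rep(NA_real_, n))
  ch_all <- as.character(GenomicRanges::seqnames(gr))
  unk <- setdiff(unique(ch_all), names(chrom_sizes))
  if (length(unk)) {
    stop("bedGraph chromosomes absent from the size table: ",
         paste(unk, collapse = ", "))
  }
  st <- GenomicRanges::start(gr) - 1L   # to 0-based
  en <- GenomicRanges::end(gr)
  if (any(en > chrom_sizes[ch_all])) stop("bedGraph interval out of bounds")
  sc <- gr$score
  for (i in seq_along(gr)) {
    track[[ch_all[i]]][(st[i] + 1L):en[i]] <- sc[i]
  }
  structure(track, chrom_sizes = chrom_sizes, class = "cons_track")
}

#' Write a per-base conservation track to bedGraph
#'
#' @param track A `cons_track` (list of per-base vectors, `NA` = unscored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(track, path) {
  cs <- attr(track, "chrom_sizes")
  pieces <- list()
  for (ch in names(cs)) {
    v <- track[[ch]]
    scored <- !is.na(v)
    if (!any(scored)) next
    idx <- which(scored)
    pieces[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(idx, idx), score = v[idx], seqlengths = cs)
  }
  gr <- if (length(pieces)) do.call(c, unname(pieces)) else {
    GenomicRanges::GRanges(seqlengths = cs)
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Intergenic complement of an annotation
#'
#' Maximal intervals of the genome not covered by any annotated feature:
#' the `intergenic` moiety for conservation comparisons.
#'
#' @param annotations Annotation `data.frame`.
#' @param chrom_sizes Named integer vector.
#' @return Interval `data.frame` (`chrom`, `start`, `end`, `strand`).
#' @export
intergenic_complement <- function(annotations, chrom_sizes) {
  whole <- interval_df(names(chrom_sizes), 0L, unname(chrom_sizes), "*")
  subtract_intervals(whole, annotations)
}

#' Mean conservation score over a region
#'
#' Arithmetic mean over the scored bases of a region; unscored bases are
#' counted but excluded from the mean.
#'
#' @param track A `cons_track`.
#' @param chrom,start,end Region (0-based half-open).
#' @return List with `mean` (`NA` when no base is scored), `n_scored` and
#'   `n_missing`.
#' @export
mean_cons <- function(track, chrom, start, end) {
  n <- attr(track, "chrom_sizes")[[chrom]]
  if (is.null(n)) stop(sprintf("unknown chromosome '%s'", chrom))
  if (start < 0 || end > n || start >= end) {
    stop(sprintf("region [%d, %d) out of bounds for %s", start, end, chrom))
  }
  v <- track[[chrom]][(start + 1L):end]
  scored <- !is.na(v)
  list(mean = if (any(scored)) mean(v[scored]) else NA_real_,
       n_scored = sum(scored), n_missing = sum(!scored))
}

#' Partition moiety features into hotspot and flanking intervals
#'
#' For one structural moiety (e.g. all introns), splits the feature bases
#' into the part covered by hotspots and the complementary "flanking"
#' part, both emitted as maximal intervals. The two partitions are disjoint
#' and together tile the moiety exactly.
#'
#' @param hotspots Hotspot `data.frame`.
#' @param features Annotation `data.frame` rows for one moiety.
#' @return List with `hotspot` and `flanking` interval `data.frame`s.
#' @export
flanking_complement <- function(hotspots, features) {
  list(hotspot = intersect_intervals(features, hotspots),
       flanking = subtract_intervals(features, hotspots))
}

#' Compare conservation of hotspot versus flanking regions
#'
#' Two-sided Wilcoxon rank-sum test on per-region mean conservation
#' scores. Direction is the sign of (median hotspot - median flanking).
#'
#' @param hotspot_means,flanking_means Numeric vectors of per-region mean
#'   scores (at least 2 each).
#' @return List with `p_value`, `direction` (`"hotspot>flanking"`,
#'   `"hotspot<flanking"` or `"none"`), `median_hotspot`,
#'   `median_flanking`, `n_hotspot`, `n_flanking`. When either side has
#'   fewer than 2 regions the comparison is skipped (`p_value` NA, `note`
#'   explains).
#' @export
compare_category <- function(hotspot_means, flanking_means) {
  n_h <- length(hotspot_means)
  n_f <- length(flanking_means)
  if (n_h < 2 || n_f < 2) {
    return(list(p_value = NA_real_, direction = "none",
                median_hotspot = median(hotspot_means),
                median_flanking = median(flanking_means),
                n_hotspot = n_h, n_flanking = n_f,
                note = "fewer than 2 regions on one side; comparison skipped"))
  }
  p <- suppressWarnings(
    wilcox.test(hotspot_means, flanking_means, exact = NULL)$p.value)
  dm <- median(hotspot_means) - median(flanking_means)
  list(p_value = p,
       direction = if (dm > 0) "hotspot>flanking" else {
         if (dm < 0) "hotspot<flanking" else "none"
       },
       median_hotspot = median(hotspot_means),
       median_flanking = median(flanking_means),
       n_hotspot = n_h, n_flanking = n_f)
}

#' Moiety-wise conservation comparison of hotspots and flanking sequence
#'
#' For each structural moiety (coding exons, both UTRs, introns, transposons
#' and - when `intergenic_space` is supplied - intergenic regions), builds
#' the hotspot/flanking partition, computes per-region mean conservation
#' scores, drops regions with fewer than `min_scored` scored bases, and
#' runs [compare_category()].
#'
#' @param hotspots Hotspot `data.frame`.
#' @param annotations Annotation `data.frame`.
#' @param track A `cons_track`.
#' @param moieties Categories to compare (default the mRNA moieties plus
#'   transposons).
#' @param intergenic_space Optional interval `data.frame` of intergenic
#'   space to test as an additional moiety.
#' @param min_scored Minimum scored bases per region (default 10).
#' @return `data.frame` with one row per moiety: medians, region counts,
#'   `p_value`, `direction`.
#' @export
compare_conservation <- function(hotspots, annotations, track,
                                 moieties = c("exon_CDS", "UTR5", "UTR3",
                                              "intron",
                                              "transposable_element"),
                                 intergenic_space = NULL,
                                 min_scored = 10L) {
  region_means <- function(regions) {
    if (!nrow(regions)) return(numeric())
    ms <- lapply(seq_len(nrow(regions)), function(i) {
      mean_cons(track, regions$chrom[i], regions$start[i], regions$end[i])
    })
    keep <- vapply(ms, function(x) x$n_scored >= min_scored, logical(1))
    vapply(ms[keep], `[[`, numeric(1), "mean")
  }
  one <- function(moiety, features) {
    parts <- flanking_complement(hotspots, features)
    cmp <- compare_category(region_means(parts$hotspot),
                            region_means(parts$flanking))
    data.frame(moiety = moiety,
               n_hotspot = cmp$n_hotspot, n_flanking = cmp$n_flanking,
               median_hotspot = cmp$median_hotspot,
               median_flanking = cmp$median_flanking,
               p_value = cmp$p_value, direction = cmp$direction,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in moieties) {
    feats <- annotations[annotations$category == m, , drop = FALSE]
    if (!nrow(feats)) next
    out[[m]] <- one(m, feats)
  }
  if (!is.null(intergenic_space) && nrow(intergenic_space)) {
    out[["intergenic"]] <- one("intergenic", intergenic_space)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
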