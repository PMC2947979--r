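# Weighted per-base, per-strand coverage.

#' Build a weighted coverage track
#'
#' Sums read weights per base and strand. Unstranded reads (`*`) contribute
#' to the plus-strand array. The total mass invariant holds exactly:
#' `sum(track) == sum(weight * read_length)`.
#'
#' @param reads Aligned-read `data.frame` (see [aligned_reads()]).
#' @param chrom_sizes Named integer vector of chromosome lengths; reads
#'   beyond the declared bounds raise an error.
#' @return A `coverage_track`: per chromosome a list with numeric vectors
#'   `plus` and `minus`, one value per base.
#' @export
build_coverage <- function(reads, chrom_sizes) {
  validate_intervals(reads, chrom_sizes, "read")
  track <- lapply(chrom_sizes, function(n) {
    list(plus = numeric(n), minus = numeric(n))
  })
  for (ch in unique(reads$chrom)) {
    sel <- reads$chrom == ch
    for (s in c("plus", "minus")) {
      ssel <- sel & (reads$strand == if (s == "plus") "+" else "-")
      if (s == "plus") ssel <- ssel | (sel & reads$strand == "*")
      if (!any(ssel)) next
      track[[ch]][[s]] <- depth_vector(reads$start[ssel], reads$end[ssel],
                                       reads$weight[ssel],
                                       chrom_sizes[[ch]])
    }
  }
  structure(track, chrom_sizes = chrom_sizes, class = "coverage_track")
}

# Difference-array accumulation of weighted interval depth.
depth_vector <- function(start, end, weight, n) {
  d <- numeric(n + 1L)
  agg <- rowsum(c(weight, -weight), c(start + 1L, end + 1L))
  idx <- as.integer(rownames(agg))
  d[idx] <- agg[, 1]
  head(cumsum(d), n)
}

#' @export
print.coverage_track <- function(x, ...) {
  cs <- attr(x, "chrom_sizes")
  cat("coverage_track:", length(cs), "chromosome(s),",
      format(sum(cs), big.mark = ","), "bases\n")
  for (ch in names(cs)) {
    comb <- x[[ch]]$plus + x[[ch]]$minus
    cat(sprintf("  %s (%d nt): mass %.1f, covered %d nt\n", ch, cs[[ch]],
                sum(comb), sum(comb > 0)))
  }
  invisible(x)
}

#' Total coverage mass of a track
#' @param track A `coverage_track`.
#' @return Sum over all bases and strands of the depth values.
#' @export
coverage_mass <- function(track) {
  sum(vapply(track, function(ch) sum(ch$plus) + sum(ch$minus), numeric(1)))
}

region_depth <- function(track, chrom, start, end, strand = "both") {
  ch <- track[[chrom]]
  if (is.null(ch)) stop(sprintf("unknown chromosome '%s'", chrom))
  n <- attr(track, "chrom_sizes")[[chrom]]
  if (start < 0 || end > n || start >= end) {
    stop(sprintf("region [%d, %d) out of bounds for %s (%d nt)",
                 start, end, chrom, n))
  }
  idx <- (start + 1L):end
  switch(strand,
         both = ch$plus[idx] + ch$minus[idx],
         "+" = ch$plus[idx],
         "-" = ch$minus[idx],
         stop("strand must be '+', '-' or 'both'"))
}

#' Number of covered bases in a region
#'
#' Counts bases with combined-strand depth above zero, the "length of
#' covered nucleotides" used for read-density normalization.
#'
#' @param track A `coverage_track`.
#' @param chrom,start,end Region (0-based half-open).
#' @return Integer count of covered bases.
#' @export
covered_length <- function(track, chrom, start, end) {
  sum(region_depth(track, chrom, start, end) > 0)
}

#' Export a coverage track as bedGraph
#'
#' Writes the combined-strand (or single-strand) depth as a bedGraph file
#' (0-based half-open, zero runs omitted).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, path, strand = "both") {
  cs <- attr(track, "chrom_sizes")
  gr <- GenomicRanges::GRanges(seqlengths = cs)
  pieces <- list()
  for (ch in names(cs)) {
    v <- region_depth(track, ch, 0L, cs[[ch]], strand)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths       # 0-based
    keep <- r$values != 0
    if (!any(keep)) next
    pieces[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(starts[keep] + 1L, ends[keep]),
      score = r$values[keep], seqlengths = cs)
  }
  gr <- if (length(pieces)) do.call(c, unname(pieces)) else gr
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
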