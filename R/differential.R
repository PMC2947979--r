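# 1 kb differential window analysis between two libraries, and intersection
# of dsRNA and smRNA calls into RDR-substrate nominations.

#' Tile the genome into fixed-width bins
#'
#' Non-overlapping tiling; the last bin of each chromosome may be shorter.
#'
#' @param chrom_sizes Named integer vector.
#' @param width Bin width in bases (default 1000).
#' @return `data.frame` with `chrom`, `start`, `end`, `bin` (1-based index
#'   per chromosome).
#' @export
bin_genome <- function(chrom_sizes, width = 1000L) {
  stopifnot(width >= 1)
  out <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    starts <- seq.int(0L, n - 1L, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, n),
               bin = seq_along(starts), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Apportion read weight into bins
#'
#' A read's weight is split across the bins it overlaps in proportion to the
#' number of its bases in each bin, so total binned weight equals total read
#' weight exactly.
#'
#' @param reads Aligned-read `data.frame`.
#' @param bins Bin `data.frame` from [bin_genome()].
#' @param chrom_sizes Named integer vector covering all reads.
#' @return Numeric vector of per-bin weights, aligned with `bins` rows.
#' @export
count_in_bins <- function(reads, bins, chrom_sizes) {
  validate_intervals(reads, chrom_sizes, "read")
  out <- numeric(nrow(bins))
  if (!nrow(reads)) return(out)
  # Per-base weight density (weight / read length) accumulated by a
  # difference array, then summed per bin: identical to fractional
  # apportionment by overlap.
  for (ch in unique(bins$chrom)) {
    rsel <- reads$chrom == ch
    bsel <- which(bins$chrom == ch)
    if (!any(rsel) || !length(bsel)) next
    dens <- depth_vector(reads$start[rsel], reads$end[rsel],
                         reads$weight[rsel] /
                           (reads$end[rsel] - reads$start[rsel]),
                         chrom_sizes[[ch]])
    cum <- c(0, cumsum(dens))
    out[bsel] <- cum[bins$end[bsel] + 1L] - cum[bins$start[bsel] + 1L]
  }
  out
}

#' Test one bin for differential abundance between two libraries
#'
#' Fold change compares per-million-normalized bin weights with a
#' pseudocount on both counts; the p-value is a two-sided Fisher's exact
#' test on the rounded 2x2 table of bin weight versus remaining library
#' weight.
#'
#' @param count_a,count_b Bin weight in libraries A and B.
#' @param total_a,total_b Total library weights (> 0).
#' @param pseudocount Added to both counts for the fold change (default
#'   0.5).
#' @return List with `fold` (normalized A/B ratio) and `p` (Fisher p-value).
#'   Both counts zero gives fold 1, p 1.
#' @export
test_bin <- function(count_a, total_a, count_b, total_b, pseudocount = 0.5) {
  stopifnot(total_a > 0, total_b > 0)
  if (count_a == 0 && count_b == 0) return(list(fold = 1, p = 1))
  fold <- ((count_a + pseudocount) / total_a) /
    ((count_b + pseudocount) / total_b)
  a <- round(count_a)
  b <- round(count_b)
  tab <- matrix(c(a, round(total_a) - a, b, round(total_b) - b),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  list(fold = fold, p = p)
}

#' Call differential bins between two libraries
#'
#' Applies [test_bin()] to every bin in both directions: a bin is
#' significant when its fold change passes `fold_min` (in either direction)
#' and its Fisher p-value is below `p_max`. Adjacent significant bins in
#' the same direction are merged into regions (`region` column).
#'
#' @param bins Bin `data.frame` from [bin_genome()].
#' @param counts_a,counts_b Per-bin weights from [count_in_bins()].
#' @param total_a,total_b Library totals; default to `sum(counts)`.
#' @param fold_min Minimum fold change (default 2).
#' @param p_max Maximum p-value (default 0.001).
#' @param pseudocount Fold-change pseudocount (default 0.5).
#' @return `bins` with columns `count_a`, `count_b`, `norm_a`, `norm_b`
#'   (per-million), `fold`, `lods` (log10 fold), `p_value`, `direction`
#'   (`"A>B"`, `"A<B"` or `"none"`), `significant`, and `region` (id shared
#'   by merged adjacent significant bins, NA otherwise).
#' @export
call_differential <- function(bins, counts_a, counts_b,
                              total_a = sum(counts_a),
                              total_b = sum(counts_b),
                              fold_min = 2, p_max = 0.001,
                              pseudocount = 0.5) {
  stopifnot(length(counts_a) == nrow(bins),
            length(counts_b) == nrow(bins))
  res <- lapply(seq_len(nrow(bins)), function(i) {
    test_bin(counts_a[i], total_a, counts_b[i], total_b, pseudocount)
  })
  out <- bins
  out$count_a <- counts_a
  out$count_b <- counts_b
  out$norm_a <- 1e6 * counts_a / total_a
  out$norm_b <- 1e6 * counts_b / total_b
  out$fold <- vapply(res, `[[`, numeric(1), "fold")
  out$lods <- log10(out$fold)
  out$p_value <- vapply(res, `[[`, numeric(1), "p")
  out$direction <- ifelse(out$fold > 1, "A>B",
                          ifelse(out$fold < 1, "A<B", "none"))
  out$significant <- (out$fold >= fold_min | out$fold <= 1 / fold_min) &
    out$p_value < p_max
  out$direction[!out$significant & out$fold == 1] <- "none"
  out$region <- NA_character_
  sig <- which(out$significant)
  if (length(sig)) {
    # merge runs of adjacent significant bins with the same direction
    brk <- c(TRUE, diff(sig) != 1 |
               out$chrom[sig[-1]] != out$chrom[sig[-length(sig)]] |
               out$direction[sig[-1]] != out$direction[sig[-length(sig)]])
    out$region[sig] <- paste0("r", cumsum(brk))
  }
  out
}

#' Intersect dsRNA and smRNA differential calls into substrate calls
#'
#' A substrate bin is one called significant in the `A>B` direction in both
#' assays (e.g. wild-type over an RDR mutant in both the dsRNA and the
#' smRNA library): a region whose double-stranded RNA and its small-RNA
#' output both depend on the enzyme.
#'
#' @param ds_calls,sm_calls Outputs of [call_differential()] on the same
#'   binning for the dsRNA and smRNA assays.
#' @param annotations Optional annotation `data.frame` for category
#'   assignment by majority overlap.
#' @param priority Category priority for ties.
#' @return `data.frame` of substrate bins with per-assay folds and
#'   p-values, a `category` column, and a `phased` column initialized to
#'   `NA` (filled by [call_phased()]).
#' @export
intersect_substrates <- function(ds_calls, sm_calls, annotations = NULL,
                                 priority = default_priority()) {
  if (nrow(ds_calls) != nrow(sm_calls) ||
      any(ds_calls$chrom != sm_calls$chrom) ||
      any(ds_calls$start != sm_calls$start)) {
    stop("ds_calls and sm_calls must come from the same binning")
  }
  sel <- ds_calls$significant & ds_calls$direction == "A>B" &
    sm_calls$significant & sm_calls$direction == "A>B"
  out <- ds_calls[sel, c("chrom", "start", "end", "bin"), drop = FALSE]
  out$ds_fold <- ds_calls$fold[sel]
  out$ds_p <- ds_calls$p_value[sel]
  out$sm_fold <- sm_calls$fold[sel]
  out$sm_p <- sm_calls$p_value[sel]
  out$category <- assign_category(out, annotations, priority)
  out$phased <- NA
  rownames(out) <- NULL
  out
}
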