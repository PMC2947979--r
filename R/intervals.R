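# Interval plumbing. All coordinates are 0-based half-open [start, end).

CATEGORIES <- c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA",
                "transposable_element", "exon_CDS", "UTR5", "UTR3",
                "intron", "other_ncRNA", "intergenic")

#' Default category priority
#'
#' Order used to break ties when a read overlaps features of several
#' categories: structural non-coding RNAs first (they are frequently nested
#' inside mRNA introns and UTRs and dominate the base-paired signal), then
#' transposable elements, then mRNA sub-features, with `intergenic` as the
#' fallback for reads overlapping nothing.
#'
#' @return Character vector of the twelve categories, highest priority first.
#' @export
default_priority <- function() {
  CATEGORIES
}

interval_df <- function(chrom = character(), start = integer(),
                        end = integer(), strand = character()) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(df, chrom_sizes = NULL, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("%s %d: invalid coordinates [%s, %s) (need 0 <= start < end)",
                 what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if (!is.null(chrom_sizes)) {
    unk <- which(!(df$chrom %in% names(chrom_sizes)))
    if (length(unk)) {
      stop(sprintf("%s %d: unknown chromosome '%s'", what, unk[1],
                   df$chrom[unk[1]]))
    }
    over <- which(df$end > chrom_sizes[df$chrom])
    if (length(over)) {
      stop(sprintf("%s %d: interval [%d, %d) exceeds length of %s (%d)",
                   what, over[1], df$start[over[1]], df$end[over[1]],
                   df$chrom[over[1]], chrom_sizes[[df$chrom[over[1]]]]))
    }
  }
  invisible(df)
}

#' Read a two-column chromosome-size table
#'
#' @param path Path to a whitespace-delimited file with columns
#'   `chrom` and `length`.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "", as.is = TRUE,
                    col.names = c("chrom", "size"))
  if (any(duplicated(tab$chrom))) stop("duplicated chromosome in sizes file")
  if (any(tab$size < 1)) stop("non-positive chromosome length")
  setNames(as.integer(tab$size), tab$chrom)
}

#' Write a chromosome-size table
#' @param chrom_sizes Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# IRanges bridge (0-based half-open -> 1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Overlap pairs between two 0-based interval data frames, per chromosome.
# Returns data.frame(q, s, overlap) of row indices and overlap widths (nt).
overlap_pairs <- function(query, subject) {
  out <- list()
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si]))
    if (!length(hits)) next
    q <- qi[S4Vectors::queryHits(hits)]
    s <- si[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end[q], subject$end[s]) -
      pmax(query$start[q], subject$start[s])
    out[[ch]] <- data.frame(q = q, s = s, overlap = ov)
  }
  if (!length(out)) {
    return(data.frame(q = integer(), s = integer(), overlap = integer()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Per-moiety base-level set difference: intervals in `features` minus bases
# covered by `mask`, emitted as maximal intervals. Both 0-based half-open.
subtract_intervals <- function(features, mask) {
  out <- list()
  for (ch in unique(features$chrom)) {
    fi <- features[features$chrom == ch, , drop = FALSE]
    mi <- mask[mask$chrom == ch, , drop = FALSE]
    fr <- IRanges::reduce(as_iranges0(fi$start, fi$end))
    if (nrow(mi)) {
      mr <- IRanges::reduce(as_iranges0(mi$start, mi$end))
      keep <- IRanges::setdiff(fr, mr)
    } else {
      keep <- fr
    }
    if (length(keep)) {
      out[[ch]] <- interval_df(ch, IRanges::start(keep) - 1L,
                               IRanges::end(keep), "*")
    }
  }
  if (!length(out)) return(interval_df())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Base-level intersection of two interval sets, as maximal intervals.
intersect_intervals <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    ir <- IRanges::intersect(IRanges::reduce(as_iranges0(ai$start, ai$end)),
                             IRanges::reduce(as_iranges0(bi$start, bi$end)))
    if (length(ir)) {
      out[[ch]] <- interval_df(ch, IRanges::start(ir) - 1L,
                               IRanges::end(ir), "*")
    }
  }
  if (!length(out)) return(interval_df())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
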