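# Read preprocessing and BED6 interchange.
#
# Aligned reads travel as a data.frame with columns
#   chrom, start, end, name, copies, strand, n_hits, weight
# where weight = copies / n_hits apportions the clone abundance of a
# non-redundant (NR) sequence across its genomic placements.

#' Collapse raw reads to non-redundant sequences
#'
#' Reduces a vector of raw read strings to the distinct (non-redundant, NR)
#' sequences with their clone abundance. The total clone count is conserved:
#' `sum(collapse_reads(x)) == length(x)`.
#'
#' @param sequences Character vector of reads over `A,C,G,T,N`.
#' @return Named integer vector: NR sequence -> copies. Empty input gives an
#'   empty vector.
#' @examples
#' collapse_reads(c("ACG", "ACG", "TTT"))
#' @export
collapse_reads <- function(sequences) {
  if (!length(sequences)) return(setNames(integer(), character()))
  if (!is.character(sequences) || any(is.na(sequences)) ||
      any(!nzchar(sequences))) {
    stop("sequences must be non-empty strings")
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  }
  tab <- table(sequences)
  setNames(as.integer(tab), names(tab))
}

#' Average clone abundance of a read set
#'
#' Raw read count divided by the number of distinct NR sequences.
#'
#' @param copies Named integer vector as returned by [collapse_reads()].
#' @return A single number (NA for an empty set).
#' @export
clone_abundance <- function(copies) {
  if (!length(copies)) return(NA_real_)
  sum(copies) / length(copies)
}

#' Trim a 3' adapter from a read
#'
#' Searches for an exact match of a prefix of `adapter` (at least
#' `min_overlap` long) running to the 3' end of the read, taking the leftmost
#' such match, and truncates the read up to the junction. Reads without a
#' recognizable adapter are returned unchanged and flagged, not discarded.
#'
#' @param seq Read string.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum matched adapter prefix length (default 5).
#' @return List with `seq` (possibly truncated) and `found` (logical).
#' @examples
#' trim_adapter("ACGTGATCG", "GATCG")
#' @export
trim_adapter <- function(seq, adapter, min_overlap = 5L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(adapter),
            min_overlap >= 1L)
  n <- nchar(seq)
  na <- nchar(adapter)
  if (n >= min_overlap) {
    for (i in seq_len(n - min_overlap + 1L)) {
      k <- min(na, n - i + 1L)
      if (k >= min_overlap &&
          substr(seq, i, i + k - 1L) == substr(adapter, 1L, k)) {
        return(list(seq = substr(seq, 1L, i - 1L), found = TRUE))
      }
    }
  }
  list(seq = seq, found = FALSE)
}

#' Preprocess a raw read library
#'
#' NR-collapses the library, trims 3' adapters from each NR sequence, and
#' drops products shorter than `min_length` (too short to map uniquely).
#' Copies of NR sequences that collide after trimming are merged.
#'
#' @param sequences Character vector of raw reads.
#' @param adapter Adapter string, or `NULL` to skip trimming.
#' @inheritParams trim_adapter
#' @param min_length Minimum retained product length (default 15).
#' @return List with `copies` (named vector, NR sequence -> copies),
#'   `n_raw`, `n_trimmed` (NR sequences in which an adapter was found) and
#'   `n_discarded` (NR sequences dropped as too short).
#' @export
preprocess_reads <- function(sequences, adapter = NULL, min_overlap = 5L,
                             min_length = 15L) {
  copies <- collapse_reads(sequences)
  n_trimmed <- 0L
  if (!is.null(adapter) && length(copies)) {
    trimmed <- vapply(names(copies), function(s) {
      tr <- trim_adapter(s, adapter, min_overlap)
      n_trimmed <<- n_trimmed + tr$found
      tr$seq
    }, character(1))
    keep <- nchar(trimmed) >= min_length
    n_discarded <- sum(!keep)
    merged <- tapply(unname(copies)[keep], trimmed[keep], sum)
    copies <- setNames(as.integer(merged), names(merged))
  } else {
    keep <- nchar(names(copies)) >= min_length
    n_discarded <- sum(!keep)
    copies <- copies[keep]
  }
  list(copies = copies, n_raw = length(sequences),
       n_trimmed = n_trimmed, n_discarded = n_discarded)
}

#' Construct an aligned-read table
#'
#' @param chrom,start,end,strand Interval fields (0-based half-open; strand
#'   `+`, `-` or `*`).
#' @param copies Clone abundance of the NR sequence (>= 1).
#' @param n_hits Number of genomic placements of the NR sequence (>= 1).
#' @param name NR identifiers (default `nr1`, `nr2`, ...).
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return `data.frame` of aligned reads with a `weight = copies/n_hits`
#'   column.
#' @export
aligned_reads <- function(chrom, start, end, strand, copies = 1,
                          n_hits = 1L, name = NULL,
                          chrom_sizes = NULL) {
  n <- length(start)
  if (is.null(name)) {
    name <- if (n) paste0("nr", seq_len(n)) else character(0)
  }
  if (length(copies) == 1L) copies <- rep(copies, n)
  if (length(n_hits) == 1L) n_hits <- rep(n_hits, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   copies = as.numeric(copies),
                   strand = as.character(strand),
                   n_hits = as.integer(n_hits),
                   stringsAsFactors = FALSE)
  if (n) {
    validate_intervals(df, chrom_sizes, "read")
    if (any(!(df$strand %in% c("+", "-", "*")))) {
      stop("read strand must be one of '+', '-', '*'")
    }
    if (any(df$copies < 1) || any(df$n_hits < 1)) {
      stop("copies and n_hits must be >= 1")
    }
  }
  df$weight <- df$copies / df$n_hits
  df
}

#' Read aligned reads from BED6
#'
#' BED6 with the score column carrying clone copies and the name column
#' carrying `NRid/n_hits`. Coordinates are kept 0-based half-open. A name
#' without `/n_hits` implies a single placement.
#'
#' @param path BED6 file.
#' @param chrom_sizes Optional named vector; if given, reads beyond declared
#'   chromosome bounds raise an error naming the line.
#' @return Aligned-read `data.frame` (see [aligned_reads()]).
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(aligned_reads(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("BED line %d: expected 6 tab-separated fields, got %d",
                 which(nf < 6L)[1], nf[which(nf < 6L)[1]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("BED line %d: invalid coordinates '%s'..'%s'",
                 bad[1], m[bad[1], 2], m[bad[1], 3]))
  }
  bad <- which(!(m[, 6] %in% c("+", "-", ".")))
  if (length(bad)) {
    stop(sprintf("BED line %d: malformed strand '%s'", bad[1], m[bad[1], 6]))
  }
  bad <- which(is.na(score) | score < 1)
  if (length(bad)) {
    stop(sprintf("BED line %d: score (copies) must be a number >= 1, got '%s'",
                 bad[1], m[bad[1], 5]))
  }
  name_parts <- strsplit(m[, 4], "/", fixed = TRUE)
  nr_id <- vapply(name_parts, `[`, character(1), 1L)
  n_hits <- vapply(name_parts, function(p) {
    if (length(p) >= 2L) suppressWarnings(as.integer(p[2])) else 1L
  }, integer(1))
  bad <- which(is.na(n_hits) | n_hits < 1L)
  if (length(bad)) {
    stop(sprintf("BED line %d: malformed name '%s' (expected NRid/n_hits)",
                 bad[1], m[bad[1], 4]))
  }
  strand <- ifelse(m[, 6] == ".", "*", m[, 6])
  if (!is.null(chrom_sizes)) {
    bad <- which(!(m[, 1] %in% names(chrom_sizes)))
    if (length(bad)) {
      stop(sprintf("BED line %d: unknown chromosome '%s'", bad[1],
                   m[bad[1], 1]))
    }
    bad <- which(end > chrom_sizes[m[, 1]])
    if (length(bad)) {
      stop(sprintf("BED line %d: read end %d exceeds length of %s",
                   bad[1], end[bad[1]], m[bad[1], 1]))
    }
  }
  aligned_reads(m[, 1], start, end, strand, copies = score,
                n_hits = n_hits, name = nr_id)
}

#' Write aligned reads to BED6
#'
#' Inverse of [read_bed()]: name column is `NRid/n_hits`, score is copies.
#'
#' @param reads Aligned-read `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  strand <- ifelse(reads$strand == "*", ".", reads$strand)
  score <- ifelse(reads$copies == round(reads$copies),
                  format(as.integer(round(reads$copies))),
                  format(reads$copies))
  lines <- paste(reads$chrom, reads$start, reads$end,
                 paste0(reads$name, "/", reads$n_hits),
                 score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Weighted read-length distribution
#'
#' Total read weight per length class. Lengths outside
#' `[min_len, max_len]` are pooled into an `other` bin.
#'
#' @param reads Aligned-read `data.frame`.
#' @param min_len,max_len Size-class range (defaults 19 and 26 nt, the
#'   small-RNA size classes).
#' @return Named numeric vector over `min_len:max_len` plus `"other"`; sums
#'   to the total read weight.
#' @export
size_distribution <- function(reads, min_len = 19L, max_len = 26L) {
  bins <- c(as.character(min_len:max_len), "other")
  out <- setNames(numeric(length(bins)), bins)
  if (!nrow(reads)) return(out)
  len <- reads$end - reads$start
  cls <- ifelse(len >= min_len & len <= max_len, as.character(len), "other")
  agg <- tapply(reads$weight, cls, sum)
  out[names(agg)] <- agg
  out
}
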