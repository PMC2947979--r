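# GFF3 annotation input with a closed category vocabulary.

#' Default GFF3 type -> category map
#'
#' Maps common GFF3/SO feature type strings onto the closed category
#' vocabulary used throughout the package. Types not in the map are routed
#' to `other_ncRNA` with a warning at read time; `intergenic` is never
#' stored, it is the complement of the annotation.
#'
#' @return Named character vector (GFF3 type -> category).
#' @export
default_category_map <- function() {
  c(rRNA = "rRNA", tRNA = "tRNA", snoRNA = "snoRNA", snRNA = "snRNA",
    miRNA = "miRNA",
    transposable_element = "transposable_element",
    transposon_fragment = "transposable_element",
    transposable_element_gene = "transposable_element",
    CDS = "exon_CDS", exon_CDS = "exon_CDS",
    five_prime_UTR = "UTR5", UTR5 = "UTR5",
    three_prime_UTR = "UTR3", UTR3 = "UTR3",
    intron = "intron",
    ncRNA = "other_ncRNA", other_ncRNA = "other_ncRNA")
}

#' Read annotation features from GFF3
#'
#' Parses a GFF3 file into the annotation table used by [classify_reads()].
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. Feature types are mapped through `category_map`;
#' unmapped types are kept as `other_ncRNA` with one warning listing them.
#' Rows whose type maps to `NA` (e.g. `gene`, `mRNA` containers when only
#' sub-features are wanted) can be excluded via `drop_types`.
#'
#' @param path GFF3 file.
#' @param category_map Named vector mapping GFF3 type -> category
#'   (default [default_category_map()]).
#' @param drop_types GFF3 types to skip silently (default the common
#'   container types `gene`, `mRNA`, `chromosome`, `protein`, `exon`).
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `category`, `feature_id`, `parent_id`.
#' @export
read_gff3 <- function(path, category_map = default_category_map(),
                      drop_types = c("gene", "mRNA", "chromosome",
                                     "protein", "exon"),
                      chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_annotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    i <- which(nf < 9L)[1]
    stop(sprintf("GFF3 line %d: expected 9 tab-separated columns, got %d",
                 lineno[i], nf[i]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  type <- m[, 3]
  sel <- !(type %in% drop_types)
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  type <- type[sel]
  if (!nrow(m)) return(empty_annotation())
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | end1 < start1 | start1 < 1)
  if (length(bad)) {
    stop(sprintf("GFF3 line %d: invalid coordinates '%s'..'%s'",
                 lineno[bad[1]], m[bad[1], 4], m[bad[1], 5]))
  }
  attrs <- m[, 9]
  bad <- which(!grepl("=", attrs, fixed = TRUE) & attrs != ".")
  if (length(bad)) {
    stop(sprintf("GFF3 line %d: malformed attribute column '%s'",
                 lineno[bad[1]], attrs[bad[1]]))
  }
  category <- unname(category_map[type])
  unmapped <- is.na(category)
  if (any(unmapped)) {
    warning(sprintf("unmapped GFF3 types routed to other_ncRNA: %s",
                    paste(sort(unique(type[unmapped])), collapse = ", ")))
    category[unmapped] <- "other_ncRNA"
  }
  bad_cat <- setdiff(unique(category), setdiff(CATEGORIES, "intergenic"))
  if (length(bad_cat)) {
    stop(sprintf("category_map targets outside the closed vocabulary: %s",
                 paste(bad_cat, collapse = ", ")))
  }
  df <- data.frame(
    chrom = m[, 1],
    start = start1 - 1L,           # to 0-based half-open
    end = end1,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
    category = category,
    feature_id = gff3_attr(attrs, "ID"),
    parent_id = gff3_attr(attrs, "Parent"),
    stringsAsFactors = FALSE)
  miss <- !nzchar(df$feature_id)
  df$feature_id[miss] <- paste0("feat", which(miss))
  validate_intervals(df, chrom_sizes, "GFF3 feature")
  df
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) >= 3) x[3] else "", character(1))
}

empty_annotation <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), category = character(),
             feature_id = character(), parent_id = character(),
             stringsAsFactors = FALSE)
}

#' Write annotation features to GFF3
#'
#' Inverse of [read_gff3()] for the closed vocabulary: the category becomes
#' the GFF3 type column and coordinates are converted back to 1-based
#' inclusive.
#'
#' @param annotations Annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  attr_col <- paste0("ID=", annotations$feature_id,
                     ifelse(nzchar(annotations$parent_id),
                            paste0(";Parent=", annotations$parent_id), ""))
  lines <- paste(annotations$chrom, "dsrnatk", annotations$category,
                 annotations$start + 1L, annotations$end, ".",
                 ifelse(annotations$strand == "*", ".", annotations$strand),
                 ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
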