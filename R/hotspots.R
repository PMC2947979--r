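# Geometric-model hotspot calling.
#
# Covered segments are maximal runs of read-covered bases; their lengths are
# modelled per chromosome as geometric on {1, 2, ...} with p estimated by
# method of moments (p_hat = 1 / mean length). A segment of length L has
# tail probability P(X >= L) = (1 - p_hat)^(L - 1); unusually long segments
# surviving Benjamini-Hochberg correction are hotspots.

#' Extract maximal covered segments from a coverage track
#'
#' Runs of bases whose combined-strand depth reaches `min_depth` (by default
#' any positive depth). If `reads` are supplied, each segment is annotated
#' with the number, total weight and per-strand weights of the reads
#' overlapping it.
#'
#' @param track A `coverage_track`.
#' @param reads Optional aligned-read `data.frame` used to annotate segments.
#' @param min_depth Minimum combined depth (default: any depth > 0).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `length` and,
#'   when `reads` is given, `n_reads`, `weight`, `plus_weight`,
#'   `minus_weight`.
#' @export
merge_segments <- function(track, reads = NULL, min_depth = NULL) {
  cs <- attr(track, "chrom_sizes")
  segs <- list()
  for (ch in names(cs)) {
    comb <- track[[ch]]$plus + track[[ch]]$minus
    hit <- if (is.null(min_depth)) comb > 0 else comb >= min_depth
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) next
    segs[[ch]] <- interval_df(ch, starts[keep], ends[keep], "*")
  }
  segs <- if (length(segs)) {
    do.call(rbind, c(segs, list(make.row.names = FALSE)))
  } else interval_df()
  segs$length <- segs$end - segs$start
  if (!is.null(reads) && nrow(segs)) {
    segs$n_reads <- 0L
    segs$weight <- 0
    segs$plus_weight <- 0
    segs$minus_weight <- 0
    pairs <- overlap_pairs(segs, reads)
    if (nrow(pairs)) {
      add <- function(w) {
        agg <- rowsum(w, pairs$q)
        idx <- as.integer(rownames(agg))
        out <- numeric(nrow(segs))
        out[idx] <- agg[, 1]
        out
      }
      w <- reads$weight[pairs$s]
      segs$n_reads <- as.integer(add(rep(1, nrow(pairs))))
      segs$weight <- add(w)
      segs$plus_weight <- add(w * (reads$strand[pairs$s] != "-"))
      segs$minus_weight <- add(w * (reads$strand[pairs$s] == "-"))
    }
  }
  segs
}

#' Fit a geometric length model to covered segments
#'
#' Method-of-moments fit of a geometric distribution on {1, 2, ...} to the
#' segment lengths of one chromosome: `p_hat = 1 / mean(length)`.
#'
#' @param segments Segment `data.frame` from [merge_segments()] restricted
#'   to one chromosome, or a numeric vector of segment lengths.
#' @param chrom Chromosome label stored in the model (inferred from
#'   `segments` when possible).
#' @return Object of class `geom_model`: `chrom`, `mean_length`, `p_hat`,
#'   `n_segments`.
#' @export
fit_geometric <- function(segments, chrom = NA_character_) {
  if (is.data.frame(segments)) {
    ch <- unique(segments$chrom)
    if (length(ch) > 1) {
      stop("fit_geometric expects segments from a single chromosome; ",
           "use fit_geometric_models() for a genome-wide fit")
    }
    if (length(ch) == 1 && is.na(chrom)) chrom <- ch
    lengths <- segments$length
  } else {
    lengths <- segments
  }
  if (length(lengths) < 2) {
    stop("fewer than 2 segments on '", chrom,
         "': fit a pooled model across chromosomes instead")
  }
  if (any(lengths < 1)) stop("segment lengths must be >= 1")
  m <- mean(lengths)
  structure(list(chrom = chrom, mean_length = m, p_hat = 1 / m,
                 n_segments = length(lengths)),
            class = "geom_model")
}

#' @export
print.geom_model <- function(x, ...) {
  cat(sprintf(
    "geometric segment-length model [%s]: mean %.2f nt, p_hat %.4g (n = %d)\n",
    x$chrom, x$mean_length, x$p_hat, x$n_segments))
  invisible(x)
}

#' Fit per-chromosome geometric models
#'
#' One [fit_geometric()] model per chromosome; chromosomes with fewer than
#' two segments fall back to a model pooled over all segments.
#'
#' @param segments Segment `data.frame` from [merge_segments()].
#' @return Named list of `geom_model` objects, one per chromosome present.
#' @export
fit_geometric_models <- function(segments) {
  if (nrow(segments) < 2) stop("need at least 2 segments genome-wide")
  pooled <- fit_geometric(segments$length, chrom = "pooled")
  chroms <- unique(segments$chrom)
  models <- lapply(chroms, function(ch) {
    sub <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(sub) >= 2) fit_geometric(sub) else {
      m <- pooled
      m$chrom <- ch
      m
    }
  })
  setNames(models, chroms)
}

#' Geometric tail probability of a segment length
#'
#' `P(X >= L) = (1 - p_hat)^(L - 1)` for a geometric distribution on
#' {1, 2, ...}: the probability of seeing a covered segment at least `L`
#' bases long under the background model.
#'
#' @param L Segment length(s), >= 1.
#' @param p_hat Geometric success parameter in (0, 1].
#' @return Tail probability, vectorized over `L`.
#' @examples
#' geometric_tail(5, 0.5)  # 0.0625
#' @export
geometric_tail <- function(L, p_hat) {
  stopifnot(all(L >= 1), p_hat > 0, p_hat <= 1)
  (1 - p_hat)^(L - 1)
}

#' Call hotspots from covered segments
#'
#' Computes the geometric tail p-value of every segment under its
#' chromosome's model, applies Benjamini-Hochberg correction across all
#' tested segments genome-wide, and calls hotspots at `q <= alpha`.
#' Segments supported by fewer than `min_reads` distinct reads are excluded
#' from testing (when read counts are available). Hotspot ids are assigned
#' `<chrom>_h<k>` in coordinate order per chromosome.
#'
#' @param segments Segment `data.frame` from [merge_segments()].
#' @param models A `geom_model` or named per-chromosome list from
#'   [fit_geometric_models()].
#' @param alpha BH q-value threshold (default 0.05).
#' @param min_reads Minimum distinct-read support (default 2).
#' @param annotations Optional annotation `data.frame`; when given each
#'   hotspot gets the category with the largest base overlap (ties broken
#'   by `priority`), `intergenic` when none.
#' @param priority Category priority for tie-breaking.
#' @param pseudocount Pseudocount for the per-hotspot strand log-odds.
#' @return `data.frame` of called hotspots, coordinate-sorted, with
#'   `p_value`, `q_value`, `id`, `category` and `lods` columns. The full
#'   tested segment table (with p and q values) is attached as attribute
#'   `"tested"`.
#' @export
call_hotspots <- function(segments, models, alpha = 0.05, min_reads = 2L,
                          annotations = NULL,
                          priority = default_priority(), pseudocount = 1) {
  if (inherits(models, "geom_model")) {
    models <- setNames(rep(list(models), length(unique(segments$chrom))),
                       unique(segments$chrom))
  }
  tested <- segments
  if (!is.null(tested$n_reads)) {
    tested <- tested[tested$n_reads >= min_reads, , drop = FALSE]
  }
  if (!nrow(tested)) return(empty_hotspots())
  miss <- setdiff(unique(tested$chrom), names(models))
  if (length(miss)) {
    stop("no geometric model for chromosome(s): ",
         paste(miss, collapse = ", "))
  }
  p_hat <- vapply(models[tested$chrom], `[[`, numeric(1), "p_hat")
  tested$p_value <- (1 - p_hat)^(tested$length - 1)
  tested$q_value <- p.adjust(tested$p_value, method = "BH")
  hs <- tested[tested$q_value <= alpha, , drop = FALSE]
  hs <- hs[order(hs$chrom, hs$start), , drop = FALSE]
  if (nrow(hs)) {
    k <- stats::ave(seq_len(nrow(hs)), hs$chrom, FUN = seq_along)
    hs$id <- paste0(hs$chrom, "_h", k)
    hs$category <- assign_category(hs, annotations, priority)
    if (!is.null(hs$plus_weight)) {
      hs$lods <- strand_lods(hs$plus_weight, hs$minus_weight, pseudocount)
    }
  } else {
    hs <- empty_hotspots()
  }
  rownames(hs) <- NULL
  attr(hs, "tested") <- tested
  hs
}

empty_hotspots <- function() {
  df <- interval_df()
  df$length <- integer()
  df$p_value <- numeric()
  df$q_value <- numeric()
  df$id <- character()
  df$category <- character()
  df
}

# Majority-overlap category assignment with priority tie-break.
assign_category <- function(intervals, annotations, priority) {
  out <- rep("intergenic", nrow(intervals))
  if (is.null(annotations) || !nrow(annotations) || !nrow(intervals)) {
    return(out)
  }
  rank <- priority_rank(priority)
  pairs <- overlap_pairs(intervals, annotations)
  if (!nrow(pairs)) return(out)
  pairs$category <- annotations$category[pairs$s]
  agg <- stats::aggregate(overlap ~ q + category, data = pairs, FUN = sum)
  agg <- agg[order(agg$q, -agg$overlap, rank[agg$category]), , drop = FALSE]
  best <- agg[!duplicated(agg$q), , drop = FALSE]
  out[best$q] <- best$category
  out
}

#' End-to-end hotspot calling from reads
#'
#' Convenience wrapper: builds coverage, merges segments, fits the
#' per-chromosome geometric models and calls hotspots.
#'
#' @param reads Aligned-read `data.frame`.
#' @param chrom_sizes Named integer vector.
#' @inheritParams call_hotspots
#' @return As [call_hotspots()], with the fitted models attached as
#'   attribute `"models"`.
#' @export
hotspots_from_reads <- function(reads, chrom_sizes, alpha = 0.05,
                                min_reads = 2L, annotations = NULL,
                                priority = default_priority()) {
  track <- build_coverage(reads, chrom_sizes)
  segments <- merge_segments(track, reads)
  models <- fit_geometric_models(segments)
  hs <- call_hotspots(segments, models, alpha = alpha,
                      min_reads = min_reads, annotations = annotations,
                      priority = priority)
  attr(hs, "models") <- models
  hs
}

#' Percent of hotspot bases producing small RNAs
#'
#' For each hotspot category, the percentage of hotspot nucleotides with
#' non-zero coverage in a small-RNA library.
#'
#' @param hotspots Hotspot `data.frame` with a `category` column.
#' @param smrna_track `coverage_track` built from the smRNA library.
#' @return `data.frame` with `category`, `hotspot_bases`, `covered_bases`,
#'   `percent`. Categories without hotspots are omitted (with a message).
#' @export
hotspot_smrna_overlap <- function(hotspots, smrna_track) {
  if (!nrow(hotspots)) stop("no hotspots supplied")
  cov_bases <- vapply(seq_len(nrow(hotspots)), function(i) {
    sum(region_depth(smrna_track, hotspots$chrom[i], hotspots$start[i],
                     hotspots$end[i]) > 0)
  }, numeric(1))
  cats <- unique(hotspots$category)
  absent <- setdiff(CATEGORIES, cats)
  if (length(absent)) {
    message("categories without hotspots omitted: ",
            paste(absent, collapse = ", "))
  }
  tot <- tapply(hotspots$end - hotspots$start, hotspots$category, sum)
  cov <- tapply(cov_bases, hotspots$category, sum)
  data.frame(category = names(tot),
             hotspot_bases = as.integer(tot),
             covered_bases = as.integer(cov),
             percent = 100 * as.numeric(cov) / as.numeric(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discover novel transcription units among hotspots
#'
#' A novel unit is a hotspot with zero overlap to any annotated feature.
#' Each unit is flagged for overlap (>= 1 bp) with small-RNA hotspots, and,
#' when smRNA reads are supplied, annotated with the weighted small-RNA
#' size-class distribution (19-26 nt) of the reads it overlaps.
#'
#' @param hotspots Hotspot `data.frame`.
#' @param annotations Annotation `data.frame`.
#' @param smrna_hotspots Hotspot `data.frame` called on the smRNA library.
#' @param smrna_reads Optional smRNA aligned-read `data.frame`.
#' @return `data.frame` of novel units with `smrna_overlap` flag; when
#'   `smrna_reads` is given, a size-class matrix (one row per unit) is
#'   attached as attribute `"size_classes"`.
#' @export
discover_novel <- function(hotspots, annotations, smrna_hotspots,
                           smrna_reads = NULL) {
  if (!nrow(hotspots)) return(hotspots)
  ann_hits <- overlap_pairs(hotspots, annotations)
  novel <- hotspots[setdiff(seq_len(nrow(hotspots)), unique(ann_hits$q)), ,
                    drop = FALSE]
  if (!nrow(novel)) {
    novel$smrna_overlap <- logical(0)
    return(novel)
  }
  sm_hits <- overlap_pairs(novel, smrna_hotspots)
  novel$smrna_overlap <- seq_len(nrow(novel)) %in% unique(sm_hits$q)
  rownames(novel) <- NULL
  if (!is.null(smrna_reads)) {
    sc <- t(vapply(seq_len(nrow(novel)), function(i) {
      pairs <- overlap_pairs(novel[i, , drop = FALSE], smrna_reads)
      size_distribution(smrna_reads[pairs$s, , drop = FALSE])
    }, size_distribution(smrna_reads[0, , drop = FALSE])))
    rownames(sc) <- novel$id
    attr(novel, "size_classes") <- sc
  }
  novel
}
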