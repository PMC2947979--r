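# Hierarchical read classification, strand bias, duplex typing, saturation.

priority_rank <- function(priority) {
  if (!setequal(priority, CATEGORIES)) {
    stop("priority must be a permutation of the closed category vocabulary")
  }
  setNames(seq_along(priority), priority)
}

#' Classify reads against an annotation hierarchy
#'
#' Assigns exactly one category and an orientation to every read. Among the
#' features a read overlaps, the highest-priority category wins (so e.g. a
#' tRNA nested in an mRNA intron claims its reads); ties within a category
#' are resolved by largest overlap, then leftmost feature, then feature id.
#' Orientation is `sense` when read and feature strands agree, `antisense`
#' when they differ, and `none` for unstranded features. Reads overlapping
#' nothing are `intergenic` with orientation `none`.
#'
#' @param reads Aligned-read `data.frame`.
#' @param annotations Annotation `data.frame` from [read_gff3()].
#' @param priority Category order, highest first (default
#'   [default_priority()]).
#' @return `reads` with `category` and `orientation` columns appended.
#' @export
classify_reads <- function(reads, annotations, priority = default_priority()) {
  rank <- priority_rank(priority)
  reads$category <- "intergenic"
  reads$orientation <- "none"
  if (!nrow(reads) || !nrow(annotations)) return(reads)
  pairs <- overlap_pairs(reads, annotations)
  if (nrow(pairs)) {
    ord <- order(pairs$q,
                 rank[annotations$category[pairs$s]],
                 -pairs$overlap,
                 annotations$start[pairs$s],
                 annotations$feature_id[pairs$s])
    pairs <- pairs[ord, , drop = FALSE]
    best <- pairs[!duplicated(pairs$q), , drop = FALSE]
    reads$category[best$q] <- annotations$category[best$s]
    fstrand <- annotations$strand[best$s]
    rstrand <- reads$strand[best$q]
    reads$orientation[best$q] <-
      ifelse(fstrand == "*" | rstrand == "*", "none",
             ifelse(fstrand == rstrand, "sense", "antisense"))
  }
  reads
}

#' Summarize a classified library by category
#'
#' Applies [classify_reads()] and tallies, per category, the read count and
#' the sense/antisense weight, with the sense/antisense log-odds ratio.
#' Counts are conserved: `sum(count)` equals the number of reads.
#'
#' @inheritParams classify_reads
#' @param pseudocount Pseudocount for the log-odds ratio (default 1).
#' @return `data.frame` with one row per category: `category`, `count`,
#'   `sense_weight`, `antisense_weight`, `lods`.
#' @export
summarize_classes <- function(reads, annotations,
                              priority = default_priority(),
                              pseudocount = 1) {
  cls <- classify_reads(reads, annotations, priority)
  out <- data.frame(category = priority, count = 0L,
                    sense_weight = 0, antisense_weight = 0,
                    stringsAsFactors = FALSE)
  if (nrow(cls)) {
    cnt <- table(factor(cls$category, levels = priority))
    out$count <- as.integer(cnt)
    sw <- tapply(cls$weight * (cls$orientation == "sense"),
                 factor(cls$category, levels = priority), sum)
    aw <- tapply(cls$weight * (cls$orientation == "antisense"),
                 factor(cls$category, levels = priority), sum)
    out$sense_weight <- ifelse(is.na(sw), 0, sw)
    out$antisense_weight <- ifelse(is.na(aw), 0, aw)
  }
  out$lods <- strand_lods(out$sense_weight, out$antisense_weight, pseudocount)
  rownames(out) <- NULL
  out
}

#' Sense/antisense log-odds ratio
#'
#' `log10((S + c) / (A + c))`: the decade-scale strand bias of a category or
#' locus. Antisymmetric in its arguments and zero at equality.
#'
#' @param S Sense weight (>= 0).
#' @param A Antisense weight (>= 0).
#' @param pseudocount Positive pseudocount `c` (default 1) guarding against
#'   division by zero.
#' @return Numeric log-odds value(s).
#' @examples
#' strand_lods(999, 0)   # 3: a thousand-fold sense bias
#' @export
strand_lods <- function(S, A, pseudocount = 1) {
  stopifnot(all(S >= 0), all(A >= 0), pseudocount > 0)
  log10((S + pseudocount) / (A + pseudocount))
}

#' Type a duplex locus as intra- or inter-molecular
#'
#' A covered locus with reads on both genomic strands in comparable amounts
#' is evidence of an inter-molecular heteroduplex (e.g. an RDR product);
#' strongly one-sided coverage indicates an intra-molecular fold-back. The
#' call is `inter` iff both strands carry at least `min_weight` and the
#' minority strand fraction reaches `balance_threshold`.
#'
#' @param plus_weight,minus_weight Per-strand read weight (not both zero).
#' @param balance_threshold Minimum minority-strand fraction (default 0.2).
#' @param min_weight Minimum per-strand weight (default 5).
#' @return `"intra"` or `"inter"` (vectorized).
#' @export
duplex_type <- function(plus_weight, minus_weight, balance_threshold = 0.2,
                        min_weight = 5) {
  stopifnot(all(plus_weight >= 0), all(minus_weight >= 0))
  if (any(plus_weight + minus_weight == 0)) {
    stop("no duplex evidence: both strand weights are zero")
  }
  minority <- pmin(plus_weight, minus_weight)
  frac <- minority / (plus_weight + minus_weight)
  ifelse(minority >= min_weight & frac >= balance_threshold,
         "inter", "intra")
}

#' Library-saturation curves by subsampling
#'
#' Thins the library to each fraction (independent per-read Bernoulli
#' inclusion), recomputes the covered length per category, and reports it
#' relative to the full library. By construction every category reports
#' exactly 1.0 at fraction 1.
#'
#' @inheritParams classify_reads
#' @param fractions Subsample fractions in (0, 1].
#' @param n_reps Replicates per fraction (averaged).
#' @param seed Integer seed fixing the subsamples.
#' @return `data.frame` with columns `fraction`, `category` (including
#'   `"all"`), `relative_coverage`.
#' @export
subsample_saturation <- function(reads, annotations,
                                 fractions = c(0.1, 0.25, 0.5, 0.75, 1),
                                 n_reps = 3L, seed = 1L,
                                 priority = default_priority()) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  cls <- classify_reads(reads, annotations, priority)
  cats <- c("all", priority)
  cov_of <- function(idx) {
    sapply(cats, function(cat) {
      sel <- if (cat == "all") idx else idx[cls$category[idx] == cat]
      if (!length(sel)) return(0)
      by_ch <- split(sel, cls$chrom[sel])
      sum(vapply(by_ch, function(i) {
        sum(IRanges::width(IRanges::reduce(
          as_iranges0(cls$start[i], cls$end[i]))))
      }, numeric(1)))
    })
  }
  full <- cov_of(seq_len(nrow(cls)))
  out <- list()
  local_seed(seed, {
    for (f in fractions) {
      acc <- numeric(length(cats))
      for (r in seq_len(n_reps)) {
        keep <- which(runif(nrow(cls)) <= f)
        acc <- acc + cov_of(keep)
      }
      rel <- ifelse(full > 0, (acc / n_reps) / full, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, category = cats, relative_coverage = unname(rel),
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
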