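# 21-nt phasing detection.
#
# Processive dicing from a defined end concentrates small-RNA 5' ends on one
# residue class modulo the cycle length D (21 nt for plant tasiRNAs). A
# window of m cycles has m * D "slots" (one per base); a slot is occupied if
# at least one 5' end lands on it. The phasing statistic asks whether the
# occupied slots concentrate in one of the D registers: a hypergeometric
# upper tail on the best register, Bonferroni-corrected for the D registers.

# 5' end genomic coordinate of each read (0-based).
read_5p <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}

#' Register occupancy of small-RNA 5' ends in a window
#'
#' Counts, for each of the `D` registers, the number of occupied slots
#' among the `m` cycle-positions of a window starting at `locus_start`.
#' Minus-strand 5' ends are shifted by `antisense_offset` (+2 by default)
#' before taking the modulus, the register correction for the 2-nt 3'
#' overhang of siRNA duplexes.
#'
#' @param reads Aligned-read `data.frame` (small RNAs).
#' @param locus_start,locus_end Window bounds (0-based half-open); the
#'   window spans `m = floor((locus_end - locus_start) / D)` full cycles
#'   and must contain at least one.
#' @param D Cycle length in nt (default 21).
#' @param antisense_offset Register shift applied to minus-strand 5' ends
#'   (default +2).
#' @return List with `occupancy` (integer vector of length `D`: occupied
#'   slots per register), `m` (cycles) and `n` (total occupied slots).
#' @export
register_positions <- function(reads, locus_start, locus_end, D = 21L,
                               antisense_offset = 2L) {
  if (locus_end - locus_start < D) {
    stop("locus shorter than one cycle (", D, " nt)")
  }
  m <- (locus_end - locus_start) %/% D
  span <- m * D
  p5 <- read_5p(reads)
  off <- p5 - locus_start + ifelse(reads$strand == "-", antisense_offset, 0L)
  off <- off[off >= 0 & off < span]
  occ <- integer(D)
  if (length(off)) {
    slots <- unique(off)                     # occupied slots (unique bases)
    occ <- tabulate(slots %% D + 1L, nbins = D)
  }
  list(occupancy = occ, m = m, n = sum(occ))
}

#' Hypergeometric phasing p-value
#'
#' Given the register occupancy of a window (`m` cycles, `D` registers),
#' tests whether the best register holds more occupied slots than expected
#' if the `n` occupied slots were placed uniformly among the `m * D` slots:
#' upper-tail hypergeometric probability of drawing >= k of the `m` slots
#' of that register, Bonferroni-multiplied by the `D` registers examined
#' and capped at 1.
#'
#' @param occupancy Integer vector of length `D` (occupied slots per
#'   register), or the list returned by [register_positions()].
#' @param m Cycles in the window (ignored when `occupancy` is a list).
#' @param D Cycle length; defaults to `length(occupancy)`.
#' @return List with `register` (0-based best register), `k`, `n`, `p_raw`
#'   and `p` (Bonferroni-adjusted).
#' @export
phasing_pvalue <- function(occupancy, m = NULL, D = NULL) {
  if (is.list(occupancy)) {
    m <- occupancy$m
    occupancy <- occupancy$occupancy
  }
  if (is.null(D)) D <- length(occupancy)
  stopifnot(length(occupancy) == D, !is.null(m), all(occupancy >= 0),
            all(occupancy <= m))
  n <- sum(occupancy)
  if (n == 0) stop("no occupied slots: nothing to test")
  k <- max(occupancy)
  r <- which.max(occupancy) - 1L
  p_raw <- phyper(k - 1, m, m * D - m, n, lower.tail = FALSE)
  list(register = r, k = k, n = n, p_raw = p_raw, p = min(1, D * p_raw))
}

#' Flag phased small-RNA production at substrate loci
#'
#' Scans each locus with windows of `cycles * D` nt in `D`-nt steps (a
#' single truncated window when the locus is shorter), keeping small RNAs
#' in the `len_range` size classes, and records the best
#' Bonferroni-adjusted phasing p-value. Windows with fewer than
#' `min_occupied` occupied slots are not tested. A locus is phased when its
#' best p-value is at or below `p_threshold`.
#'
#' @param substrates `data.frame` with `chrom`, `start`, `end` (e.g. from
#'   [intersect_substrates()]).
#' @param smrna_reads Small-RNA aligned-read `data.frame`.
#' @param D Cycle length (default 21).
#' @param cycles Cycles per window (default 9, i.e. 189-nt windows).
#' @param p_threshold Phased-call threshold on the adjusted p (default
#'   1e-3).
#' @param len_range Read lengths contributing to phasing (default 20-22).
#' @param min_occupied Minimum occupied slots per tested window (default 4).
#' @param antisense_offset See [register_positions()].
#' @return `substrates` with `phase_p` (best adjusted p, NA when untested),
#'   `phase_register`, `phased` (logical) and `phase_status`
#'   (`"phased"`, `"non-phased"` or `"no data"`).
#' @export
call_phased <- function(substrates, smrna_reads, D = 21L, cycles = 9L,
                        p_threshold = 1e-3, len_range = c(20L, 22L),
                        min_occupied = 4L, antisense_offset = 2L) {
  len <- smrna_reads$end - smrna_reads$start
  sm <- smrna_reads[len >= len_range[1] & len <= len_range[2], ,
                    drop = FALSE]
  n_loci <- nrow(substrates)
  substrates$phase_p <- NA_real_
  substrates$phase_register <- NA_integer_
  substrates$phased <- FALSE
  substrates$phase_status <- "no data"
  W <- cycles * D
  for (i in seq_len(n_loci)) {
    loc <- substrates[i, ]
    reads_i <- sm[sm$chrom == loc$chrom & sm$start < loc$end &
                    sm$end > loc$start, , drop = FALSE]
    if (!nrow(reads_i)) next
    len_i <- loc$end - loc$start
    if (len_i < D) next
    starts <- if (len_i <= W) loc$start else {
      seq.int(loc$start, loc$end - W, by = D)
    }
    best <- NULL
    for (ws in starts) {
      we <- min(ws + W, loc$end)
      occ <- register_positions(reads_i, ws, we, D, antisense_offset)
      if (occ$n < min_occupied) next
      sc <- phasing_pvalue(occ)
      if (is.null(best) || sc$p < best$p) best <- sc
    }
    if (is.null(best)) {
      substrates$phase_status[i] <- "non-phased"
      next
    }
    substrates$phase_p[i] <- best$p
    substrates$phase_register[i] <- best$register
    substrates$phased[i] <- best$p <= p_threshold
    substrates$phase_status[i] <- if (substrates$phased[i]) "phased" else {
      "non-phased"
    }
  }
  substrates
}
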