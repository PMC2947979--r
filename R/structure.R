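# Coverage-constrained RNA secondary structure models.
#
# The constraint dialect is Vienna's: '|' = the base must pair (with
# someone), '.' = unconstrained. Two folding engines: an external
# thermodynamic adapter (RNAfold, default parameters, constraint string
# passed verbatim) and a built-in constrained Nussinov
# pair-count-maximizing dynamic program that makes the whole pipeline
# self-contained and desk-checkable.

RNA_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

as_rna <- function(seq) {
  s <- chartr("acgut", "ACGUU", seq)
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s)) stop("sequence must be over {A,C,G,U} (or T)")
  s
}

#' Convert read coverage over a transcript to a folding constraint string
#'
#' Position i is constrained paired (`'|'`) iff the corresponding genomic
#' base has depth > 0 on the transcript's strand; all other positions are
#' unconstrained (`'.'`). Minus-strand transcripts are read 5' to 3', i.e.
#' the genomic depth vector is reversed.
#'
#' @param track A `coverage_track` built from dsRNA-seq reads.
#' @param chrom,start,end Transcript location (0-based half-open).
#' @param strand Transcript strand (`"+"`, `"-"`; `"*"` uses combined
#'   depth).
#' @return Constraint string over `{|, .}` of length `end - start`.
#' @export
coverage_to_constraints <- function(track, chrom, start, end, strand = "+") {
  depth <- region_depth(track, chrom, start, end,
                        if (strand == "*") "both" else strand)
  if (strand == "-") depth <- rev(depth)
  paste(ifelse(depth > 0, "|", "."), collapse = "")
}

check_constraints <- function(constraints, n) {
  if (nchar(constraints) != n) {
    stop(sprintf("constraint length %d does not match sequence length %d",
                 nchar(constraints), n))
  }
  if (grepl("[^|.]", constraints)) {
    stop("constraint string must be over the alphabet {|, .}")
  }
  invisible(constraints)
}

#' Fold an RNA sequence, optionally under pairing constraints
#'
#' Dispatches to a folding engine. `"nussinov"` is the built-in
#' pair-count-maximizing dynamic program ([nussinov_fold()]); `"vienna"`
#' shells out to `RNAfold` (default parameters) and passes the constraint
#' string verbatim as a Vienna constraint line, returning the minimum free
#' energy structure and its free energy in kcal/mol. With all-`'.'` (or
#' absent) constraints both engines reproduce their unconstrained output
#' exactly.
#'
#' @param seq RNA sequence (`A,C,G,U`; `T` accepted).
#' @param constraints Optional constraint string (`'|'` must pair, `'.'`
#'   free).
#' @param engine `"nussinov"` or `"vienna"`.
#' @param id Transcript identifier for the model.
#' @param min_loop Minimum hairpin loop (builtin engine; default 3).
#' @return A `structure_model`: `id`, `seq`, `structure` (dot-bracket),
#'   `pairs` (integer vector, 0 = unpaired, else 1-based partner), `score`
#'   (free energy kcal/mol for vienna, pair count for nussinov), `engine`,
#'   `constrained`, `constraints`.
#' @export
fold_rna <- function(seq, constraints = NULL,
                     engine = c("nussinov", "vienna"),
                     id = "transcript", min_loop = 3L) {
  engine <- match.arg(engine)
  seq <- as_rna(seq)
  if (!is.null(constraints)) check_constraints(constraints, nchar(seq))
  if (engine == "nussinov") {
    return(nussinov_fold(seq, constraints, min_loop = min_loop, id = id))
  }
  vienna_fold(seq, constraints, id = id)
}

vienna_fold <- function(seq, constraints = NULL, id = "transcript") {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) {
    stop("thermodynamic engine unavailable: RNAfold (ViennaRNA) ",
         "not found on PATH; use engine = 'nussinov' or install ViennaRNA")
  }
  args <- c("--noPS")
  input <- seq
  if (!is.null(constraints)) {
    args <- c(args, "-C")
    input <- c(seq, constraints)
  }
  out <- suppressWarnings(system2(bin, args, input = input, stdout = TRUE,
                                  stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("RNAfold failed: ", paste(out, collapse = " "))
  }
  line <- grep("^[().]+\\s+\\(", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAfold output")
  db <- sub("\\s.*$", "", line[1])
  energy <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1",
                           line[1]))
  model <- make_structure_model(id, seq, pairs = dotbracket_to_pairs(db),
                                score = energy, engine = "vienna",
                                constraints = constraints)
  enforce_constraint_pairing(model)
  model
}

enforce_constraint_pairing <- function(model) {
  if (is.null(model$constraints)) return(invisible(model))
  must <- which(strsplit(model$constraints, "")[[1]] == "|")
  unpaired <- must[model$pairs[must] == 0]
  if (length(unpaired)) {
    stop("constrained fold left '|' position(s) unpaired: ",
         paste(unpaired, collapse = ", "))
  }
  invisible(model)
}

#' Constrained Nussinov folding
#'
#' Maximizes the number of allowed base pairs (`AU, UA, GC, CG, GU, UG`) by
#' dynamic programming subject to a minimum hairpin loop and to the
#' constraint that every `'|'` position must be paired. Constraints that
#' cannot be satisfied raise an error listing the offending positions -
#' they are never silently relaxed. Traceback is deterministic: position i
#' pairs with the smallest admissible partner achieving the optimum.
#'
#' @inheritParams fold_rna
#' @param allowed_pairs Character vector of allowed pair strings.
#' @return A `structure_model` with `score` = pair count.
#' @examples
#' nussinov_fold("GGGAAACCC")
#' @export
nussinov_fold <- function(seq, constraints = NULL, min_loop = 3L,
                          id = "transcript",
                          allowed_pairs = RNA_PAIRS) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  must <- if (is.null(constraints)) rep(FALSE, n) else {
    check_constraints(constraints, n)
    strsplit(constraints, "")[[1]] == "|"
  }
  pairable <- outer(bases, bases,
                    function(a, b) paste0(a, b) %in% allowed_pairs)
  # quick necessary check: a '|' base with no admissible partner anywhere
  if (any(must)) {
    sep_ok <- abs(outer(seq_len(n), seq_len(n), "-")) > min_loop
    no_partner <- which(must & !apply(pairable & sep_ok, 1, any))
    if (length(no_partner)) {
      stop("infeasible constraints: no admissible partner for position(s) ",
           paste(no_partner, collapse = ", "))
    }
  }
  # M is (n+2)x(n+2); M[i,j] = 0 for empty intervals (i > j).
  M <- matrix(0, n + 2L, n + 2L)
  for (i in seq_len(n)) if (must[i]) M[i, i] <- -Inf
  if (n >= 2) {
    for (span in 2:n) {
      for (i in seq_len(n - span + 1L)) {
        j <- i + span - 1L
        best <- if (must[i]) -Inf else M[i + 1L, j]
        k_min <- i + min_loop + 1L
        if (k_min <= j) {
          ks <- seq.int(k_min, j)
          ks <- ks[pairable[i, ks]]
          if (length(ks)) {
            cand <- M[i + 1L, ks - 1L] +
              M[cbind(ks + 1L, rep(j, length(ks)))] + 1
            best <- max(best, max(cand))
          }
        }
        M[i, j] <- best
      }
    }
  }
  score <- M[1L, n]
  if (!is.finite(score)) {
    stop("infeasible constraints: '|' position(s) ",
         paste(which(must), collapse = ", "),
         " cannot all be paired under min_loop = ", min_loop)
  }
  # deterministic traceback
  pairs <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]
    j <- ij[2]
    if (i > j) next
    target <- M[i, j]
    k_min <- i + min_loop + 1L
    paired <- FALSE
    if (k_min <= j) {
      for (k in seq.int(k_min, j)) {
        if (pairable[i, k] &&
            M[i + 1L, k - 1L] + M[k + 1L, j] + 1 == target) {
          pairs[i] <- k
          pairs[k] <- i
          stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          paired <- TRUE
          break
        }
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  model <- make_structure_model(id, seq, pairs, score = as.integer(score),
                                engine = "nussinov",
                                constraints = constraints)
  enforce_constraint_pairing(model)
  model
}

make_structure_model <- function(id, seq, pairs, score, engine,
                                 constraints = NULL, density = NULL) {
  n <- nchar(seq)
  stopifnot(length(pairs) == n)
  idx <- which(pairs > 0)
  if (length(idx) && any(pairs[pairs[idx]] != idx)) {
    stop("pair table is not symmetric")
  }
  structure(list(id = id, seq = seq,
                 structure = pairs_to_dotbracket(pairs),
                 pairs = pairs, score = score, engine = engine,
                 constrained = !is.null(constraints),
                 constraints = constraints, density = density),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  unit <- if (x$engine == "vienna") "kcal/mol" else "pairs"
  cat(sprintf("structure_model '%s' (%s%s): %d nt, score %s %s\n",
              x$id, x$engine, if (x$constrained) ", constrained" else "",
              nchar(x$seq), format(x$score), unit))
  cat(" ", x$seq, "\n ", x$structure, "\n")
  invisible(x)
}

pairs_to_dotbracket <- function(pairs) {
  n <- length(pairs)
  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs != 0 & pairs < seq_len(n)] <- ")"
  paste(db, collapse = "")
}

dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) {
    stop("dot-bracket string contains characters outside {(, ), .}")
  }
  pairs <- integer(length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pairs
}

#' Attach per-base normalized read density to a structure model
#'
#' `density(i) = depth(i) / covered_length(transcript)`: read counts
#' normalized by the number of covered nucleotides of the transcript, the
#' per-base rendering track accompanying each structure model.
#'
#' @param model A `structure_model`.
#' @param track A `coverage_track`.
#' @param chrom,start,end,strand Transcript location (as in
#'   [coverage_to_constraints()]).
#' @return The model with `density` filled (all zeros when the transcript
#'   has no covered base).
#' @export
project_reads <- function(model, track, chrom, start, end, strand = "+") {
  stopifnot(end - start == nchar(model$seq))
  depth <- region_depth(track, chrom, start, end,
                        if (strand == "*") "both" else strand)
  if (strand == "-") depth <- rev(depth)
  covered <- sum(depth > 0)
  model$density <- if (covered == 0) numeric(length(depth)) else {
    depth / covered
  }
  model
}

#' Write a structure model in CT format
#'
#' Connect-table format: one row per base with index, base, previous and
#' next index, partner (0 = unpaired) and index again; the header line
#' carries the length, score and id.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(model, path) {
  n <- nchar(model$seq)
  bases <- strsplit(model$seq, "")[[1]]
  header <- sprintf("%d ENERGY = %s %s", n, format(model$score), model$id)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                  model$pairs, seq_len(n))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a structure model from CT format
#'
#' @param path CT file written by [write_ct()].
#' @return A `structure_model` (engine `"ct"`).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[1])
  id <- header[length(header)]
  score <- suppressWarnings(as.numeric(header[4]))
  body <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  bases <- vapply(body, `[`, character(1), 2)
  pairs <- as.integer(vapply(body, `[`, character(1), 5))
  if (any(pairs < 0 | pairs > n)) stop("CT partner index out of range")
  make_structure_model(id, paste(bases, collapse = ""), pairs,
                       score = score, engine = "ct")
}

#' Write a structure model as FASTA-style dot-bracket
#'
#' Three lines: `>id score`, sequence, dot-bracket.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(model, path) {
  writeLines(c(sprintf(">%s %s", model$id, format(model$score)),
               model$seq, model$structure), path)
  invisible(path)
}

#' Read a structure model from a dot-bracket file
#'
#' @param path File written by [write_dotbracket()]. An unbalanced
#'   dot-bracket line raises an error.
#' @return A `structure_model` (engine `"dotbracket"`).
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], ">")) {
    stop("expected '>id score' header followed by sequence and structure")
  }
  header <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
  make_structure_model(header[1], lines[2],
                       dotbracket_to_pairs(lines[3]),
                       score = suppressWarnings(as.numeric(header[2])),
                       engine = "dotbracket")
}
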