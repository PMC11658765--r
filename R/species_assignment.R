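# Competitive species assignment: SNP-only pseudo-reference built from
# aligned candidate markers, plus a naive, fully auditable seed-and-extend
# read assigner (unique best candidate wins; ties are unassigned).

#' Build a SNP-only pseudo-reference from aligned candidate sequences
#'
#' Every alignment column containing a gap in any candidate is deleted
#' (INDEL removal), leaving equal-length gap-free sequences, one per
#' candidate. Diagnostic columns are the remaining positions at which at
#' least two candidates differ.
#'
#' @param msa Named character vector of aligned sequences (alphabet
#'   `ACGTN-`), all the same length.
#' @return A `pseudo_reference`: list with `seqs` (named character vector),
#'   `diagnostic` (integer positions in pseudo-reference coordinates), and
#'   `length`.
#' @export
build_pseudo_reference <- function(msa) {
  if (length(msa) < 2L) stop("need at least 2 candidate sequences")
  if (is.null(names(msa)) || any(!nzchar(names(msa)))) {
    stop("candidate sequences must be named")
  }
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("aligned candidate sequences must all have the same length")
  }
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  keep <- colSums(mat == "-") == 0L
  mat <- mat[, keep, drop = FALSE]
  seqs <- apply(mat, 1L, paste, collapse = "")
  diagnostic <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  if (length(diagnostic) == 0L) {
    warning("candidates are identical after gap removal: no diagnostic columns")
  }
  structure(list(seqs = stats::setNames(seqs, names(msa)),
                 diagnostic = as.integer(diagnostic),
                 length = ncol(mat)),
            class = "pseudo_reference")
}

# best ungapped full-length alignment score of `read` against `subject`:
# exact k-mer seeds at non-overlapping offsets, extension = direct
# comparison at the implied offset. Returns max(matches - mismatches) over
# valid placements, or -Inf if none within the mismatch budget.
best_ungapped_score <- function(read, subject, seed_k, max_mm) {
  L <- nchar(read)
  read_int <- utf8ToInt(read)
  subj_int <- utf8ToInt(subject)
  starts <- unique(c(seq(1L, L - seed_k + 1L, by = seed_k), L - seed_k + 1L))
  offsets <- integer(0)
  for (s in starts) {
    seed <- substr(read, s, s + seed_k - 1L)
    hits <- gregexpr(seed, subject, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    # overlapping occurrences: rescan from each hit + 1
    all_hits <- hits
    repeat {
      nxt <- regexpr(seed, substr(subject, max(all_hits) + 1L, nchar(subject)),
                     fixed = TRUE)
      if (nxt == -1L) break
      all_hits <- c(all_hits, max(all_hits) + nxt)
    }
    offsets <- c(offsets, all_hits - s + 1L)
  }
  offsets <- unique(offsets)
  offsets <- offsets[offsets >= 1L & offsets + L - 1L <= nchar(subject)]
  if (length(offsets) == 0L) return(-Inf)
  best <- -Inf
  for (o in offsets) {
    mm <- sum(read_int != subj_int[o:(o + L - 1L)])
    if (mm <= max_mm) best <- max(best, (L - mm) - mm)
  }
  best
}

#' Assign reads to candidate species by competitive ungapped mapping
#'
#' Naive seed-and-extend mapper: exact `seed_k`-mer seeds against each
#' candidate on both strands, ungapped full-length extension, per-candidate
#' best score `matches - mismatches` subject to a mismatch budget of
#' `max_mismatch_rate * read_length`. A read is assigned to the candidate
#' with the strictly best score; ties and misses are unassigned (unique
#' mappings only).
#'
#' @param reads Character vector of read sequences (optionally named).
#' @param pseudo_ref A [build_pseudo_reference()] result.
#' @param seed_k Seed length (default 25).
#' @param max_mismatch_rate Maximum mismatch fraction per read (default
#'   0.05).
#' @return An `assignment_result`: list with `counts` (per-candidate unique
#'   assignments), `unassigned`, `proportions` (over assigned reads), and
#'   `assignment` (per-read candidate or `NA`).
#' @export
assign_reads <- function(reads, pseudo_ref, seed_k = 25L,
                         max_mismatch_rate = 0.05) {
  if (!inherits(pseudo_ref, "pseudo_reference") ||
      length(pseudo_ref$seqs) == 0L) {
    stop("empty pseudo-reference")
  }
  if (any(nchar(reads) < seed_k)) stop("reads must be at least seed_k long")
  cands <- pseudo_ref$seqs
  assignment <- rep(NA_character_, length(reads))
  for (i in seq_along(reads)) {
    rd <- toupper(reads[[i]])
    rc <- revcomp(rd)
    max_mm <- floor(max_mismatch_rate * nchar(rd))
    scores <- vapply(cands, function(cs) {
      max(best_ungapped_score(rd, cs, seed_k, max_mm),
          best_ungapped_score(rc, cs, seed_k, max_mm))
    }, numeric(1))
    if (all(!is.finite(scores))) next
    top <- max(scores)
    winners <- names(scores)[scores == top]
    if (length(winners) == 1L) assignment[i] <- winners
  }
  counts <- vapply(names(cands), function(nm) sum(assignment == nm, na.rm = TRUE),
                   integer(1))
  assigned <- sum(counts)
  structure(list(
    counts = counts,
    unassigned = length(reads) - assigned,
    proportions = if (assigned > 0) counts / assigned else
      stats::setNames(rep(NA_real_, length(counts)), names(counts)),
    assignment = stats::setNames(assignment, names(reads))
  ), class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result:", sum(x$counts), "assigned,", x$unassigned,
      "unassigned\n")
  print(x$counts)
  invisible(x)
}

#' Per-candidate proportions over assigned reads
#'
#' @param counts Named non-negative numeric vector of per-candidate counts.
#' @return Named numeric vector summing to 1.
#' @export
candidate_proportions <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("no assigned reads: all counts are 0")
  counts / total
}

#' Pairwise global alignment of near-identical markers (unit-cost NW)
#'
#' A minimal built-in aligner for constructing the candidate MSA when the
#' markers are already near-identical: each sequence is globally aligned to
#' the first (Needleman-Wunsch, match +1, mismatch/gap -1) and gaps are
#' propagated column-wise. Intended for toy fixtures only; real marker MSAs
#' should come from a dedicated aligner.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @return Named character vector of aligned sequences (equal lengths).
#' @export
align_candidates <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ref <- seqs[[1]]
  pair_align <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    sc <- matrix(0L, n + 1L, m + 1L)
    sc[, 1] <- -(0:n); sc[1, ] <- -(0:m)
    for (i in seq_len(n)) {
      match_col <- ifelse(A[i] == B, 1L, -1L)
      for (j in seq_len(m)) {
        sc[i + 1L, j + 1L] <- max(sc[i, j] + match_col[j],
                                  sc[i, j + 1L] - 1L,
                                  sc[i + 1L, j] - 1L)
      }
    }
    ai <- character(0); bi <- character(0)
    i <- n; j <- m
    while (i > 0L || j > 0L) {
      if (i > 0L && j > 0L &&
          sc[i + 1L, j + 1L] == sc[i, j] + (if (A[i] == B[j]) 1L else -1L)) {
        ai <- c(A[i], ai); bi <- c(B[j], bi); i <- i - 1L; j <- j - 1L
      } else if (i > 0L && sc[i + 1L, j + 1L] == sc[i, j + 1L] - 1L) {
        ai <- c(A[i], ai); bi <- c("-", bi); i <- i - 1L
      } else {
        ai <- c("-", ai); bi <- c(B[j], bi); j <- j - 1L
      }
    }
    list(a = ai, b = bi)
  }
  # align all to the reference, then merge gap patterns on the reference
  alns <- lapply(seqs[-1], function(s) pair_align(ref, s))
  # positions in ref coordinates where any alignment inserts a gap are merged
  ref_chars <- strsplit(ref, "")[[1]]
  # simple case used here: no insertions relative to ref allowed in merge
  if (any(vapply(alns, function(al) any(al$a == "-"), logical(1)))) {
    stop("align_candidates only supports markers without insertions ",
         "relative to the first sequence; use an external aligner")
  }
  out <- c(list(ref_chars), lapply(alns, `[[`, "b"))
  names(out) <- names(seqs)
  vapply(out, paste, character(1), collapse = "")
}
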