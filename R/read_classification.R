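# Pair-level classification of reads by mapping behaviour. The pair is the
# unit throughout: exogenous pairs are selected by the "both mates unmapped"
# pair flag, and half-mapped pairs go to "other" (they are never counted as
# exogenous nor cleaned from the host alignment).

as_sam_records <- function(x) {
  if (is.character(x) && length(x) == 1L) read_sam_minimal(x) else x
}

# primary, non-supplementary records only; secondary (0x100) and
# supplementary (0x800) records are dropped and never count as mapping
# evidence (mirrors upstream multimapping exclusion)
primary_records <- function(recs) {
  recs[bitwAnd(recs$flag, 0x100L) == 0L & bitwAnd(recs$flag, 0x800L) == 0L, ,
       drop = FALSE]
}

# per pair: number of mapped mates among primary records
pair_mapped_mates <- function(recs) {
  recs <- primary_records(recs)
  mapped <- bitwAnd(recs$flag, 0x4L) == 0L
  tab <- tapply(mapped, recs$qname, sum)
  stats::setNames(as.integer(tab), names(tab))
}

#' Classify a sample's read pairs by mapping behaviour
#'
#' Partitions every read pair seen in the host alignment into
#' `target` (host-mapped, no confident pest hit), `ambiguous` (host-mapped
#' with a confident primary pest hit at `mapq >= mapq_min`), `exogenous`
#' (both mates unmapped in the host alignment), and `other` (exactly one
#' mate host-mapped, not ambiguous). Secondary and supplementary records are
#' dropped before classification.
#'
#' @param host_sam Host SAM path or record data frame.
#' @param pest_sams Named list of pest SAM paths or record data frames.
#' @param mapq_min Minimum pest mapping quality to establish ambiguity
#'   (default 20).
#' @return A `read_classification`: list with `sample` classes (`target`,
#'   `ambiguous`, `exogenous`, `other` character vectors of pair ids),
#'   `pest_hits` (named list of pair id vectors with confident pest hits),
#'   and `n_pairs`.
#' @export
classify_sample <- function(host_sam, pest_sams, mapq_min = 20L) {
  host <- as_sam_records(host_sam)
  pest_sams <- lapply(pest_sams, as_sam_records)
  if (is.null(names(pest_sams)) || any(!nzchar(names(pest_sams)))) {
    stop("pest_sams must be a named list")
  }
  host_mates <- pair_mapped_mates(host)
  universe <- names(host_mates)

  pest_hits <- lapply(pest_sams, function(recs) {
    recs <- primary_records(recs)
    extra <- setdiff(unique(recs$qname), universe)
    if (length(extra)) {
      stop("read ids present in a pest SAM but absent from host SAM: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    hit <- bitwAnd(recs$flag, 0x4L) == 0L & recs$mapq >= mapq_min
    unique(recs$qname[hit])
  })
  pest_any <- unique(unlist(pest_hits, use.names = FALSE))

  exogenous <- universe[host_mates == 0L]
  host_mapped <- universe[host_mates >= 1L]
  ambiguous <- intersect(host_mapped, pest_any)
  both_mapped <- universe[host_mates == 2L]
  target <- setdiff(both_mapped, ambiguous)
  other <- setdiff(universe[host_mates == 1L], ambiguous)

  structure(list(
    target = target, ambiguous = ambiguous, exogenous = exogenous,
    other = other, pest_hits = pest_hits, n_pairs = length(universe)
  ), class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat(sprintf("read_classification: %d pairs (target %d, ambiguous %d, exogenous %d, other %d)\n",
              x$n_pairs, length(x$target), length(x$ambiguous),
              length(x$exogenous), length(x$other)))
  invisible(x)
}

#' Count exogenous pairs per pest taxon
#'
#' Counts only exogenous pairs with a primary pest alignment at
#' `mapq >= mapq_min`. With `dedupe = TRUE`, pairs with an identical
#' (reference, position, flag) signature over both mates are collapsed to
#' one, approximating upstream duplicate marking. A pair hitting two pest
#' references counts once per reference; such pairs are reported in the
#' `multi_hit` attribute.
#'
#' @param classification A [classify_sample()] result.
#' @param pest_sams Named list of pest SAM paths or record data frames.
#' @param mapq_min Minimum mapping quality (default 20).
#' @param dedupe Collapse position duplicates (default `TRUE`).
#' @return Named integer vector of per-taxon exogenous pair counts, with a
#'   `multi_hit` attribute (pair ids counted in more than one taxon).
#' @export
count_exogenous_by_taxon <- function(classification, pest_sams,
                                     mapq_min = 20L, dedupe = TRUE) {
  pest_sams <- lapply(pest_sams, as_sam_records)
  exo <- classification$exogenous
  counted <- lapply(names(pest_sams), function(pn) {
    recs <- primary_records(pest_sams[[pn]])
    recs <- recs[recs$qname %in% exo &
                   bitwAnd(recs$flag, 0x4L) == 0L &
                   recs$mapq >= mapq_min, , drop = FALSE]
    if (nrow(recs) == 0L) return(character(0))
    sig <- tapply(sprintf("%s:%d:%d", recs$rname, recs$pos, recs$flag),
                  recs$qname, function(v) paste(sort(v), collapse = "|"))
    ids <- names(sig)
    if (dedupe) ids <- ids[!duplicated(as.character(sig))]
    ids
  })
  names(counted) <- names(pest_sams)
  counts <- vapply(counted, length, integer(1))
  hits_per_pair <- table(unlist(counted, use.names = FALSE))
  attr(counts, "multi_hit") <- names(hits_per_pair)[hits_per_pair > 1L]
  counts
}

#' Remove ambiguous pairs from a host alignment
#'
#' Drops every record whose read id is in the classification's ambiguous
#' set; all other records pass through unchanged. This is the cleanup step
#' applied before variant calling so that contaminant reads mapping to
#' conserved host regions cannot create false variants.
#'
#' @param host_sam Host SAM path or record data frame.
#' @param classification A [classify_sample()] result.
#' @return Filtered record data frame (same columns as the input records).
#' @export
blacklist_ambiguous <- function(host_sam, classification) {
  host <- as_sam_records(host_sam)
  host[!(host$qname %in% classification$ambiguous), , drop = FALSE]
}
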