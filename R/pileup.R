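# Naive pileup genotyper used to demonstrate the consequence of ambiguous
# reads: contaminant reads mapped into conserved host regions deposit
# non-reference bases there, and a pileup caller run before blacklisting
# manufactures variants that track pest load.

#' Naive per-sample pileup genotypes at given host positions
#'
#' For each sample and 1-based host position, counts reference and
#' non-reference bases over mapped primary records (ungapped layout: base at
#' `pos - record_pos + 1` of the stored sequence) and codes a dosage from
#' the alternate-allele fraction: 0 if < 0.25, 1 if in [0.25, 0.75), 2
#' otherwise; `NA` when no read covers the position.
#'
#' @param host_records_by_sample Named list of host SAM record data frames
#'   (one per sample).
#' @param host_seq Host reference sequence (single string).
#' @param positions Integer vector of 1-based host positions.
#' @return List with `dosage` (samples x positions matrix), `alt_frac`, and
#'   `depth` matrices.
#' @export
naive_pileup_genotypes <- function(host_records_by_sample, host_seq,
                                   positions) {
  samples <- names(host_records_by_sample)
  np <- length(positions)
  ref_base <- substring(host_seq, positions, positions)
  alt <- matrix(0L, length(samples), np, dimnames = list(samples, positions))
  depth <- matrix(0L, length(samples), np, dimnames = list(samples, positions))
  for (si in seq_along(samples)) {
    recs <- primary_records(as_sam_records(host_records_by_sample[[si]]))
    recs <- recs[bitwAnd(recs$flag, 0x4L) == 0L, , drop = FALSE]
    if (nrow(recs) == 0L) next
    rlen <- nchar(recs$seq)
    for (pi in seq_len(np)) {
      p <- positions[pi]
      cov <- which(recs$pos <= p & recs$pos + rlen - 1L >= p)
      if (length(cov) == 0L) next
      bases <- substring(recs$seq[cov], p - recs$pos[cov] + 1L,
                         p - recs$pos[cov] + 1L)
      depth[si, pi] <- length(cov)
      alt[si, pi] <- sum(bases != ref_base[pi])
    }
  }
  af <- ifelse(depth > 0, alt / depth, NA_real_)
  dosage <- matrix(NA_real_, length(samples), np,
                   dimnames = list(samples, positions))
  dosage[!is.na(af) & af < 0.25] <- 0
  dosage[!is.na(af) & af >= 0.25 & af < 0.75] <- 1
  dosage[!is.na(af) & af >= 0.75] <- 2
  list(dosage = dosage, alt_frac = af, depth = depth)
}
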