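# Alignment-level read-pair simulator. Reads are simulated as SAM records
# directly (no aligner re-implementation): the classification logic under
# test operates on mapping behaviour, not on alignment internals.
#
# Three pair classes are emitted per sample:
#   host-only  - mapped in the host SAM, both mates unmapped in every pest SAM
#   pest-only  - both mates unmapped in the host SAM (pair flag 12),
#                mapped with high MAPQ in the originating pest SAM
#   ambiguous  - pest-derived pairs from the conserved block, mapped in BOTH
#                the host SAM (at the homologous host coordinates, carrying
#                the pest alleles) and the pest SAM
# Ambiguous pairs scale with the pest count, mirroring load-correlated
# contamination: their number is round(ambiguous_fraction * pest_count).

FLAG_PAIR_M1 <- 65L    # paired, first in pair, both mates mapped
FLAG_PAIR_M2 <- 129L
FLAG_UNM_M1 <- 77L     # paired, first in pair, both mates unmapped
FLAG_UNM_M2 <- 141L

pair_records <- function(qnames, rname, pos1, pos2, seq1, seq2, mapq,
                         mapped = TRUE) {
  n <- length(qnames)
  if (n == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  if (mapped) {
    data.frame(
      qname = rep(qnames, each = 2L),
      flag = rep(c(FLAG_PAIR_M1, FLAG_PAIR_M2), n),
      rname = rname,
      pos = as.integer(rbind(pos1, pos2)),
      mapq = as.integer(mapq),
      seq = as.character(rbind(seq1, seq2)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      qname = rep(qnames, each = 2L),
      flag = rep(c(FLAG_UNM_M1, FLAG_UNM_M2), n),
      rname = "*",
      pos = 0L,
      mapq = 0L,
      seq = as.character(rbind(seq1, seq2)),
      stringsAsFactors = FALSE)
  }
}

draw_pairs <- function(genome, lo, hi, n, read_len, gap) {
  # mate1 start uniform in [lo, hi - (2*read_len + gap)] (1-based);
  # returns starts and sequences for both mates
  span <- 2L * read_len + gap
  if (hi - lo + 1L < span) stop("region too short for read pairs")
  s1 <- sample(seq.int(lo, hi - span + 1L), n, replace = TRUE)
  s2 <- s1 + read_len + gap
  list(s1 = s1, s2 = s2,
       q1 = substring(genome, s1, s1 + read_len - 1L),
       q2 = substring(genome, s2, s2 + read_len - 1L))
}

#' Simulate per-sample host and pest alignments with truth labels
#'
#' @param genomes Output of [make_genomes()].
#' @param loads Output of [simulate_loads()]; `counts` gives the per-sample
#'   pest-only pair counts assigned to the first pest taxon.
#' @param ambiguous_fraction Ambiguous pairs per pest-only pair, in [0, 1].
#' @param n_host_pairs Host-only pairs per sample.
#' @param read_len Read length (bp).
#' @param gap Inner mate gap (bp).
#' @param seed Integer seed.
#' @return A list of per-sample records: each element has `host` (SAM record
#'   data frame), `pests` (named list of SAM record data frames), and
#'   `truth` (data frame `qname`, `class`, `origin`). Attribute `pest_names`
#'   lists the pest taxa.
#' @export
simulate_alignments <- function(genomes, loads, ambiguous_fraction = 0.1,
                                n_host_pairs = 100L, read_len = 50L,
                                gap = 20L, seed = 1L) {
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("ambiguous_fraction must be in [0, 1]")
  }
  host <- genomes$host[[1]]
  pest_names <- names(genomes$pests)
  hb <- genomes$truth$host_block
  with_seed(seed, {
    samples <- names(loads$counts)
    out <- lapply(samples, function(sid) {
      c_i <- loads$counts[[sid]]
      n_amb <- as.integer(round(ambiguous_fraction * c_i))
      qn_host <- sprintf("%s_h%05d", sid, seq_len(n_host_pairs))
      qn_pest <- if (c_i > 0) sprintf("%s_p%05d", sid, seq_len(c_i)) else character(0)
      qn_amb <- if (n_amb > 0) sprintf("%s_a%05d", sid, seq_len(n_amb)) else character(0)

      # host-only pairs: left of the conserved block (both mates outside it)
      hp <- draw_pairs(host, 1L, hb[["start"]], n_host_pairs, read_len, gap)
      host_recs <- pair_records(qn_host, "host", hp$s1, hp$s2, hp$q1, hp$q2, 60L)

      pest_recs <- stats::setNames(vector("list", length(pest_names)), pest_names)
      for (pn in pest_names) {
        pest_recs[[pn]] <- pair_records(qn_host, NA, NA, NA, hp$q1, hp$q2,
                                        0L, mapped = FALSE)
      }

      # pest-only pairs: from the first pest, outside its conserved block
      if (c_i > 0) {
        p1 <- pest_names[[1]]
        pg <- genomes$pests[[p1]]
        pb <- genomes$truth$pest_blocks[[p1]]
        pp <- draw_pairs(pg, 1L, pb$block_start, c_i, read_len, gap)
        host_recs <- rbind(host_recs,
                           pair_records(qn_pest, NA, NA, NA, pp$q1, pp$q2, 0L,
                                        mapped = FALSE))
        pest_recs[[p1]] <- rbind(pest_recs[[p1]],
                                 pair_records(qn_pest, p1, pp$s1, pp$s2,
                                              pp$q1, pp$q2, 40L))
        for (pn in setdiff(pest_names, p1)) {
          pest_recs[[pn]] <- rbind(pest_recs[[pn]],
                                   pair_records(qn_pest, NA, NA, NA, pp$q1,
                                                pp$q2, 0L, mapped = FALSE))
        }
      }

      # ambiguous pairs: pest-derived from the conserved block, mapped in both
      if (n_amb > 0) {
        p1 <- pest_names[[1]]
        pg <- genomes$pests[[p1]]
        pb <- genomes$truth$pest_blocks[[p1]]
        ap <- draw_pairs(pg, pb$block_start + 1L, pb$block_end, n_amb,
                         read_len, gap)
        shift <- hb[["start"]] - pb$block_start
        host_recs <- rbind(host_recs,
                           pair_records(qn_amb, "host", ap$s1 + shift,
                                        ap$s2 + shift, ap$q1, ap$q2, 60L))
        pest_recs[[p1]] <- rbind(pest_recs[[p1]],
                                 pair_records(qn_amb, p1, ap$s1, ap$s2,
                                              ap$q1, ap$q2, 40L))
        for (pn in setdiff(pest_names, p1)) {
          pest_recs[[pn]] <- rbind(pest_recs[[pn]],
                                   pair_records(qn_amb, NA, NA, NA, ap$q1,
                                                ap$q2, 0L, mapped = FALSE))
        }
      }

      truth <- data.frame(
        qname = c(qn_host, qn_pest, qn_amb),
        class = c(rep("target", length(qn_host)),
                  rep("exogenous", length(qn_pest)),
                  rep("ambiguous", length(qn_amb))),
        origin = c(rep("host", length(qn_host)),
                   rep(pest_names[[1]], length(qn_pest) + length(qn_amb))),
        stringsAsFactors = FALSE)
      list(host = host_recs, pests = pest_recs, truth = truth)
    })
    names(out) <- samples
    attr(out, "pest_names") <- pest_names
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Write a simulated sample's alignments to SAM files
#'
#' @param sim One element of the [simulate_alignments()] output.
#' @param dir Output directory.
#' @param sample_id Sample id used in file names.
#' @param genomes The [make_genomes()] output (for `@SQ` lengths).
#' @return Named list with `host` path and `pests` paths.
#' @export
write_sample_sams <- function(sim, dir, sample_id, genomes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host_path <- file.path(dir, paste0(sample_id, ".host.sam"))
  write_sam(sim$host, host_path,
            ref_lengths = c(host = nchar(genomes$host[[1]])))
  pest_paths <- vapply(names(sim$pests), function(pn) {
    p <- file.path(dir, paste0(sample_id, ".", pn, ".sam"))
    write_sam(sim$pests[[pn]], p,
              ref_lengths = stats::setNames(nchar(genomes$pests[[pn]]), pn))
    p
  }, character(1))
  list(host = host_path, pests = as.list(pest_paths))
}
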