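# Toy genome generator: a random host contig plus pest contigs that each
# carry a mutated copy of one host block. The shared block is the source of
# ambiguous reads downstream (cross-taxa sequence similarity).

#' Simulate a host genome and pest genomes sharing a conserved block
#'
#' The host is a single random contig. Each pest contig is random sequence
#' with a copy of one fixed host block inserted, mutated at per-base rate
#' `divergence`. Block coordinates (0-based half-open) and the divergent
#' positions are recorded as ground truth.
#'
#' @param host_len Host contig length (bp).
#' @param pest_specs Named integer vector of pest contig lengths; names are
#'   pest taxon names.
#' @param conserved_len Length of the shared block; must be `< host_len` and
#'   no longer than any pest contig.
#' @param divergence Per-base substitution rate of the pest block copies,
#'   in [0, 0.2].
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A list with `host` (named character vector of length 1), `pests`
#'   (named character vector), and `truth`: block coordinates in host and in
#'   each pest, the divergent positions (1-based offsets within the block)
#'   per pest, and the seed.
#' @export
make_genomes <- function(host_len = 20000L, pest_specs = c(pestA = 12000L),
                         conserved_len = 2000L, divergence = 0.05,
                         seed = 1L) {
  if (conserved_len >= host_len) stop("conserved_len must be < host_len")
  if (divergence < 0 || divergence > 0.2) stop("divergence must be in [0, 0.2]")
  if (any(pest_specs < conserved_len)) {
    stop("every pest contig must be at least conserved_len long")
  }
  if (is.null(names(pest_specs)) || any(!nzchar(names(pest_specs)))) {
    stop("pest_specs must be named")
  }
  with_seed(seed, {
    host <- random_dna(host_len)
    # block placed centrally so host-only reads can avoid it at both ends
    block_start <- as.integer((host_len - conserved_len) %/% 2)
    block <- substr(host, block_start + 1L, block_start + conserved_len)
    pests <- character(0)
    pest_truth <- list()
    for (nm in names(pest_specs)) {
      plen <- as.integer(pest_specs[[nm]])
      mut <- mutate_seq(block, divergence)
      p_start <- as.integer((plen - conserved_len) %/% 2)
      left <- random_dna(p_start)
      right <- random_dna(plen - p_start - conserved_len)
      pests[nm] <- paste0(left, mut$seq, right)
      pest_truth[[nm]] <- list(block_start = p_start,
                               block_end = p_start + conserved_len,
                               divergent_offsets = mut$positions)
    }
    list(
      host = stats::setNames(host, "host"),
      pests = pests,
      truth = list(
        host_block = c(start = block_start, end = block_start + conserved_len),
        pest_blocks = pest_truth,
        conserved_len = as.integer(conserved_len),
        divergence = divergence,
        seed = as.integer(seed)
      )
    )
  })
}
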