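# Shared fixtures, all built in code at test time.

# minimal SAM body lines (11 mandatory fields)
sam_line <- function(qname, flag, rname = "*", pos = 0L, mapq = 0L,
                     seq = "ACGT") {
  cigar <- if (bitwAnd(flag, 4L) != 0L) "*" else paste0(nchar(seq), "M")
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, "*",
        sep = "\t")
}

write_sam_fixture <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6", lines), path)
  path
}

# a full paired record set: both mates, with given mapping status
pair_lines <- function(qname, mapped, rname = "host", pos = 100L,
                       mapq = 60L, seq = "ACGTACGT") {
  if (mapped) {
    c(sam_line(qname, 65L, rname, pos, mapq, seq),
      sam_line(qname, 129L, rname, pos + 50L, mapq, seq))
  } else {
    c(sam_line(qname, 77L), sam_line(qname, 141L))
  }
}

# small classification fixture shared across tests
tiny_alignment_world <- function(seed = 3L, n_samples = 20L,
                                 ambiguous_fraction = 0.2) {
  genomes <- make_genomes(host_len = 20000L, pest_specs = c(pestA = 12000L),
                          conserved_len = 2000L, divergence = 0.05,
                          seed = seed)
  pop <- make_population(n_samples = n_samples, n_pops = 2L, fst = 0.1,
                         n_variants = 200L, seed = seed)
  loads <- simulate_loads(pop, n_causal = 20L, h2 = 0.4, seed = seed,
                          f_max = 0.002, depth_meanlog = log(5e4))
  sims <- simulate_alignments(genomes, loads,
                              ambiguous_fraction = ambiguous_fraction,
                              n_host_pairs = 50L, seed = seed)
  list(genomes = genomes, pop = pop, loads = loads, sims = sims)
}

# a VCF text fixture
vcf_fixture <- function(records, samples = c("s1", "s2", "s3"),
                        path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# an AR(1) kinship with an identified variance ratio, plus a matched
# phenotype at lambda_true = 1
ar1_lmm_fixture <- function(n = 400L, rho = 0.5, seed = 10L) {
  K <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  y <- withr::with_seed(seed, {
    drop(t(chol(K)) %*% stats::rnorm(n)) + stats::rnorm(n)
  })
  list(K = K, y = y)
}
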