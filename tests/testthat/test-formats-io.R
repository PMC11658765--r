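test_that("read_sam_minimal parses flags, positions and mapq", {
  path <- write_sam_fixture(c(
    sam_line("r1", 12L),
    sam_line("r2", 0L, "Chr1", 100L, 60L),
    sam_line("r3", 16L, "Chr1", 500L, 30L)
  ))
  recs <- read_sam_minimal(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$flag, c(12L, 0L, 16L))
  expect_true(bitwAnd(recs$flag[1], 4L) != 0L)   # unmapped
  expect_equal(recs$mapq[2], 60L)
  expect_equal(recs$rname[1], "*")
})

test_that("read_sam_minimal rejects malformed lines with a line number", {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tChr1"), path)
  expect_error(read_sam_minimal(path), "line 2")
  writeLines(c("@HD\tVN:1.6", sam_line("r1", 0L, "Chr1", 1L),
               "r2\tnotaflag\tChr1\t1\t60\t4M\t*\t0\t0\tACGT\t*"), path)
  expect_error(read_sam_minimal(path), "flag")
})

test_that("SAM write/read round-trips the minimal fields", {
  recs <- data.frame(qname = c("a", "a", "b"), flag = c(65L, 129L, 12L),
                     rname = c("host", "host", "*"), pos = c(10L, 80L, 0L),
                     mapq = c(60L, 60L, 0L), seq = c("ACGT", "GGGT", "TTTT"),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".sam")
  write_sam(recs, path, ref_lengths = c(host = 1000L))
  back <- read_sam_minimal(path)
  expect_equal(back, recs)
})

test_that("read_vcf_biallelic applies the biallelic, missingness and dosage rules", {
  path <- vcf_fixture(c(
    vcf_rec("Chr1", 100, "A", "T", c("0/0", "0/1", "1/1")),
    vcf_rec("Chr1", 200, "A", "T,G", c("0/0", "0/1", "1/1")),  # multiallelic
    vcf_rec("Chr1", 300, "C", "G", c("./.", "0/1", "1/1")),    # 33% missing
    vcf_rec("Chr1", 400, "G", "A", c("1|1", "0|1", "0|0"))     # phased
  ))
  vt <- read_vcf_biallelic(path, max_missing = 0.10)
  expect_equal(vt$sites$pos, c(100L, 400L))
  expect_equal(unname(vt$dosage[, 1]), c(0, 1, 2))
  expect_equal(unname(vt$dosage[, 2]), c(2, 1, 0))
  # missing tolerated when under the threshold
  vt2 <- read_vcf_biallelic(path, max_missing = 0.5)
  expect_equal(vt2$sites$pos, c(100L, 300L, 400L))
  expect_true(is.na(vt2$dosage["s1", 2]))
  expect_equal(vt2$sites$missing_frac[2], 1 / 3)
})

test_that("read_vcf_biallelic errors without a GT field", {
  path <- vcf_fixture(paste(c("Chr1", 100, ".", "A", "T", ".", "PASS", ".",
                              "DP", "10", "12", "9"), collapse = "\t"))
  expect_error(read_vcf_biallelic(path), "GT")
})

test_that("VCF write/read round-trips dosages", {
  dos <- matrix(c(0, 1, 2, NA, 2, 0), nrow = 3,
                dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  sites <- data.frame(chrom = "Chr1", pos = c(10L, 20L), id = c("v1", "v2"),
                      ref = "A", alt = "T", missing_frac = c(0, 1 / 3),
                      stringsAsFactors = FALSE)
  vt <- exoload:::new_variant_table(sites, dos)
  path <- tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  back <- read_vcf_biallelic(path, max_missing = 0.5)
  expect_equal(back$dosage, dos)
  expect_equal(back$sites$pos, sites$pos)
})

test_that("unionbed reader enforces invariants and round-trips exactly", {
  sites <- data.frame(chrom = "Chr1", pos = c(10L, 25L, 40L),
                      context = c("CG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  fraction <- matrix(c(0.5, NA, 1 / 3, 0.25, 0.8, 0), nrow = 3,
                     dimnames = list(NULL, c("s1", "s2")))
  coverage <- matrix(c(4L, 0L, 9L, 8L, 5L, 7L), nrow = 3,
                     dimnames = list(NULL, c("s1", "s2")))
  ub <- new_unionbed(sites, fraction, coverage)
  expect_equal(dim(ub$fraction), c(3L, 2L))
  path <- tempfile(fileext = ".unionbed")
  write_unionbed(ub, path)
  back <- read_unionbed(path)
  expect_equal(back$fraction, ub$fraction)
  expect_equal(back$coverage, ub$coverage)
  expect_equal(back$sites, ub$sites, ignore_attr = TRUE)
})

test_that("unionbed construction rejects invalid fractions and inconsistent missingness", {
  sites <- data.frame(chrom = "Chr1", pos = 1L, context = "CG",
                      stringsAsFactors = FALSE)
  expect_error(new_unionbed(sites, matrix(1.02), matrix(5L)), "\\[0, 1\\]")
  expect_error(new_unionbed(sites, matrix(0.5), matrix(0L)), "missing")
  expect_silent(new_unionbed(sites, matrix(NA_real_), matrix(0L)))
})

test_that("BED and GFF3 encodings of the same gene read identically", {
  bed <- tempfile(fileext = ".bed")
  writeLines("Chr1\t10\t20\tgeneX\t0\t.\tgene", bed)
  gff <- tempfile(fileext = ".gff3")
  writeLines("Chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=geneX", gff)
  iv_bed <- read_intervals(bed, "bed")
  iv_gff <- read_intervals(gff, "gff3")
  expect_equal(iv_bed$start, 10L)
  expect_equal(iv_bed$end, 20L)
  expect_equal(as.data.frame(iv_bed)[c("chrom", "start", "end", "name")],
               as.data.frame(iv_gff)[c("chrom", "start", "end", "name")])
})

test_that("intervals round-trip through both dialects and reject empty spans", {
  iv <- new_interval_set(chrom = c("Chr1", "Chr2"), start = c(0L, 100L),
                         end = c(50L, 220L), feature_class = c("gene", "TE"),
                         name = c("g1", "te1"))
  for (dialect in c("bed", "gff3")) {
    path <- tempfile()
    write_intervals(iv, path, dialect)
    back <- read_intervals(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(iv), ignore_attr = TRUE)
  }
  gff <- tempfile()
  writeLines("Chr1\tsrc\tgene\t21\t20\t.\t+\t.\tID=bad", gff)
  expect_error(read_intervals(gff, "gff3"), "end <= start")
})

test_that("FASTA writer/reader round-trips named sequences", {
  seqs <- c(a = "ACGTACGT", b = "GGGCCC")
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
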