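# Minimal, strict readers/writers for the standard text formats used by the
# pipeline. One internal coordinate convention everywhere: intervals are
# 0-based half-open; SAM/VCF positions stay 1-based and are converted only at
# the parse/serialise boundary.

# ---------------------------------------------------------------------------
# SAM

#' Read the minimal alignment fields from a SAM text file
#'
#' Parses read id, bitwise flag, reference name, 1-based position, mapping
#' quality and sequence from each alignment line. No CIGAR arithmetic, no
#' tags: every consumer in this package operates on mapping behaviour only.
#'
#' @param path Path to a SAM text file (header lines start with `@`).
#' @return A data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `seq`. Unmapped records carry `rname = "*"`.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (length(body) == 0L) {
    return(data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- body[which(nf < 11L)[1]]
    stop("malformed SAM line ", bad, ": fewer than 11 fields")
  }
  flag <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(flag)) {
    bad <- body[which(is.na(flag))[1]]
    stop("malformed SAM line ", bad, ": flag is not an integer")
  }
  data.frame(
    qname = vapply(parts, `[[`, "", 1L),
    flag = flag,
    rname = vapply(parts, `[[`, "", 3L),
    pos = as.integer(vapply(parts, `[[`, "", 4L)),
    mapq = as.integer(vapply(parts, `[[`, "", 5L)),
    seq = vapply(parts, `[[`, "", 10L),
    stringsAsFactors = FALSE
  )
}

#' Write alignment records as SAM text
#'
#' @param records Data frame as returned by [read_sam_minimal()].
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference lengths for `@SQ`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, ref_lengths = NULL) {
  header <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(ref_lengths)) {
    header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                                as.integer(ref_lengths)))
  }
  unmapped <- bitwAnd(records$flag, 4L) != 0L
  cigar <- ifelse(unmapped | records$seq == "*", "*",
                  paste0(nchar(records$seq), "M"))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$rname,
                  as.integer(records$pos), as.integer(records$mapq), cigar,
                  records$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

sam_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# ---------------------------------------------------------------------------
# VCF

#' Read biallelic variants with genotype dosages from a VCF
#'
#' Multi-allelic sites are dropped. Genotypes are recoded as alternate-allele
#' dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA` (phased
#' separators accepted). Variants whose missing-call fraction exceeds
#' `max_missing` are dropped.
#'
#' @param path Path to a VCF v4.x text file with a GT field.
#' @param max_missing Maximum tolerated fraction of missing genotype calls
#'   per variant (default 0.1).
#' @return A `variant_table`: list with `sites` (data frame `chrom`, `pos`,
#'   `id`, `ref`, `alt`, `missing_frac`) and `dosage` (samples x variants
#'   matrix).
#' @export
read_vcf_biallelic <- function(path, max_missing = 0.1) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(new_variant_table(
      data.frame(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), missing_frac = numeric(),
                 stringsAsFactors = FALSE),
      matrix(numeric(), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  keep <- !grepl(",", vapply(parts, `[[`, "", 5L), fixed = TRUE)
  parts <- parts[keep]
  n_s <- length(samples)
  site_list <- list()
  dosage_cols <- list()
  for (p in parts) {
    fmt <- strsplit(p[[9]], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("VCF record without GT in FORMAT at ",
                            p[[1]], ":", p[[2]])
    gts <- vapply(strsplit(p[10:(9 + n_s)], ":", fixed = TRUE),
                  `[[`, "", gt_idx)
    gts <- gsub("|", "/", gts, fixed = TRUE)
    dos <- rep(NA_real_, n_s)
    dos[gts == "0/0"] <- 0
    dos[gts %in% c("0/1", "1/0")] <- 1
    dos[gts == "1/1"] <- 2
    miss <- mean(is.na(dos))
    if (miss > max_missing) next
    id <- if (p[[3]] == ".") paste0(p[[1]], "_", p[[2]]) else p[[3]]
    site_list[[length(site_list) + 1L]] <- data.frame(
      chrom = p[[1]], pos = as.integer(p[[2]]), id = id,
      ref = p[[4]], alt = p[[5]], missing_frac = miss,
      stringsAsFactors = FALSE)
    dosage_cols[[length(dosage_cols) + 1L]] <- dos
  }
  sites <- if (length(site_list)) do.call(rbind, site_list) else
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), missing_frac = numeric(),
               stringsAsFactors = FALSE)
  dosage <- if (length(dosage_cols))
    matrix(unlist(dosage_cols), nrow = n_s,
           dimnames = list(samples, sites$id))
  else matrix(numeric(), nrow = n_s, ncol = 0, dimnames = list(samples, NULL))
  new_variant_table(sites, dosage)
}

new_variant_table <- function(sites, dosage) {
  stopifnot(nrow(sites) == ncol(dosage))
  structure(list(sites = sites, dosage = dosage), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", ncol(x$dosage), "variants x", nrow(x$dosage),
      "samples\n")
  invisible(x)
}

#' Write a variant table as a minimal VCF v4.2
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(vt$dosage)), collapse = "\t"))
  rows <- vapply(seq_len(nrow(vt$sites)), function(i) {
    paste(c(vt$sites$chrom[i], vt$sites$pos[i], vt$sites$id[i],
            vt$sites$ref[i], vt$sites$alt[i], ".", "PASS", ".", "GT",
            gt_code(vt$dosage[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# unionbed (multi-sample methylation table)

#' Construct a unionbed methylation object
#'
#' @param sites Data frame with `chrom`, `pos` (1-based cytosine position)
#'   and `context` (one of CG, CHG, CHH).
#' @param fraction Sites x samples matrix of methylation fractions in [0, 1];
#'   `NA` exactly where coverage is 0.
#' @param coverage Sites x samples integer matrix of read coverage.
#' @return A `unionbed` object.
#' @export
new_unionbed <- function(sites, fraction, coverage) {
  stopifnot(nrow(sites) == nrow(fraction), all(dim(fraction) == dim(coverage)))
  if (!all(sites$context %in% c("CG", "CHG", "CHH"))) {
    stop("context must be one of CG, CHG, CHH")
  }
  bad <- !is.na(fraction) & (fraction < 0 | fraction > 1)
  if (any(bad)) stop("methylation fraction outside [0, 1]")
  if (any(coverage < 0)) stop("negative coverage")
  if (any(is.na(fraction) != (coverage == 0))) {
    stop("fraction must be missing exactly where coverage is 0")
  }
  structure(list(sites = sites, fraction = fraction, coverage = coverage),
            class = "unionbed")
}

#' @export
print.unionbed <- function(x, ...) {
  cat("unionbed:", nrow(x$sites), "sites x", ncol(x$fraction), "samples (",
      paste(names(table(x$sites$context)), collapse = "/"), ")\n")
  invisible(x)
}

#' Read a unionbed multi-sample methylation table
#'
#' Layout (this package's documented dialect): a header row
#' `chrom pos context <s>.frac <s>.cov ...` with one fraction/coverage column
#' pair per sample; tab-separated; fraction written as `NA` when coverage is
#' 0.
#'
#' @param path Path to the table.
#' @return A `unionbed` object.
#' @export
read_unionbed <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cn <- colnames(tab)
  if (length(cn) < 5L || any(cn[1:3] != c("chrom", "pos", "context"))) {
    stop("unionbed must start with columns chrom, pos, context")
  }
  rest <- cn[-(1:3)]
  frac_cols <- grep("\\.frac$", rest, value = TRUE)
  cov_cols <- grep("\\.cov$", rest, value = TRUE)
  samples <- sub("\\.frac$", "", frac_cols)
  if (!identical(samples, sub("\\.cov$", "", cov_cols))) {
    stop("unionbed fraction/coverage column pairs do not match")
  }
  fraction <- as.matrix(tab[frac_cols])
  coverage <- as.matrix(tab[cov_cols])
  colnames(fraction) <- samples
  colnames(coverage) <- samples
  fraction[coverage == 0] <- NA_real_
  new_unionbed(tab[1:3], fraction, coverage)
}

#' Write a unionbed object in the package dialect
#'
#' @param ub A `unionbed` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unionbed <- function(ub, path) {
  samples <- colnames(ub$fraction)
  out <- ub$sites
  for (s in samples) {
    out[[paste0(s, ".frac")]] <- sprintf("%.17g", ub$fraction[, s])
    out[[paste0(s, ".cov")]] <- ub$coverage[, s]
  }
  for (s in samples) {
    col <- paste0(s, ".frac")
    out[[col]][is.na(ub$fraction[, s])] <- "NA"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# intervals (BED / GFF3)

#' Construct an interval set (internal coordinates 0-based half-open)
#'
#' @param chrom Character vector.
#' @param start,end Integer vectors, `start < end`, 0-based half-open.
#' @param feature_class Character vector (gene/CDS/promoter/TE/intergenic or
#'   free-form labels).
#' @param name Character vector of feature names.
#' @return Data frame of class `interval_set`.
#' @export
new_interval_set <- function(chrom, start, end, feature_class = NA_character_,
                             name = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) {
    stop("interval with end <= start after normalisation: ",
         paste(which(end <= start), collapse = ", "))
  }
  structure(data.frame(chrom = chrom, start = start, end = end,
                       feature_class = feature_class, name = name,
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

#' Read genomic intervals from BED or GFF3
#'
#' BED input is 0-based half-open and used as-is; GFF3 (1-based closed) is
#' normalised to 0-based half-open (`start - 1`, `end`). The optional 7th BED
#' column carries the feature class, mirroring [write_intervals()].
#'
#' @param path Path to the file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return An `interval_set`.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bed") {
    nf <- lengths(parts)
    if (any(nf < 3L)) stop("BED line with fewer than 3 fields")
    get <- function(i, default = NA_character_) {
      vapply(parts, function(p) if (length(p) >= i) p[[i]] else default,
             character(1))
    }
    new_interval_set(
      chrom = get(1L),
      start = as.integer(get(2L)),
      end = as.integer(get(3L)),
      feature_class = get(7L),
      name = get(4L)
    )
  } else {
    nf <- lengths(parts)
    if (any(nf < 9L)) stop("GFF3 line with fewer than 9 fields")
    attrs <- vapply(parts, `[[`, "", 9L)
    name <- vapply(strsplit(attrs, ";", fixed = TRUE), function(a) {
      hit <- grep("^(ID|Name)=", a, value = TRUE)
      if (length(hit)) sub("^(ID|Name)=", "", hit[[1]]) else NA_character_
    }, character(1))
    new_interval_set(
      chrom = vapply(parts, `[[`, "", 1L),
      start = as.integer(vapply(parts, `[[`, "", 4L)) - 1L,
      end = as.integer(vapply(parts, `[[`, "", 5L)),
      feature_class = vapply(parts, `[[`, "", 3L),
      name = name
    )
  }
}

#' Write an interval set as BED or GFF3
#'
#' @param iv An `interval_set`.
#' @param path Output path.
#' @param dialect `"bed"` (feature class in column 7) or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s", iv$chrom, iv$start, iv$end,
                     ifelse(is.na(iv$name), ".", iv$name),
                     ifelse(is.na(iv$feature_class), ".", iv$feature_class))
  } else {
    lines <- sprintf("%s\texoload\t%s\t%d\t%d\t.\t.\t.\tID=%s",
                     iv$chrom,
                     ifelse(is.na(iv$feature_class), "region", iv$feature_class),
                     iv$start + 1L, iv$end,
                     ifelse(is.na(iv$name), ".", iv$name))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA (via Biostrings)

#' Read a FASTA file as a named character vector
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
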