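# A priori candidate enrichment over -log10(p) threshold sweeps, a
# conservative FDR upper bound, a chromosome-local rotation permutation null,
# and genomic-feature enrichment for methylation scans.

#' Flag variants within a window of a priori candidate genes
#'
#' A variant is a candidate iff it lies within
#' `[start - window, end + window)` of any candidate gene interval
#' (intervals 0-based half-open; variant positions 1-based).
#'
#' @param variant_chrom,variant_pos Variant coordinates (1-based positions).
#' @param candidate_genes An `interval_set` of candidate genes.
#' @param window Flanking window in bp (default 20000).
#' @return Logical vector, one flag per variant.
#' @export
mark_candidates <- function(variant_chrom, variant_pos, candidate_genes,
                            window = 20000L) {
  missing_chr <- setdiff(unique(candidate_genes$chrom), unique(variant_chrom))
  extra_chr <- setdiff(unique(variant_chrom), unique(candidate_genes$chrom))
  # genes on chromosomes with no variants are legitimate; variants on
  # chromosomes absent from the annotation are an input mismatch only when
  # the annotation names none of the variant chromosomes
  if (length(intersect(unique(variant_chrom), unique(candidate_genes$chrom))) == 0L) {
    stop("chromosome names do not overlap; variants: ",
         paste(utils::head(extra_chr, 5), collapse = ","), " vs genes: ",
         paste(utils::head(missing_chr, 5), collapse = ","))
  }
  pos0 <- variant_pos - 1L
  flags <- rep(FALSE, length(variant_pos))
  for (chr in unique(candidate_genes$chrom)) {
    gi <- candidate_genes[candidate_genes$chrom == chr, , drop = FALSE]
    vi <- which(variant_chrom == chr)
    if (length(vi) == 0L) next
    for (r in seq_len(nrow(gi))) {
      flags[vi] <- flags[vi] |
        (pos0[vi] >= gi$start[r] - window & pos0[vi] < gi$end[r] + window)
    }
  }
  flags
}

#' Candidate enrichment across -log10(p) thresholds with FDR upper bound
#'
#' At each threshold `t` (0.5 increments), with `s(t)` significant variants
#' of which `a(t)` are candidates, total `S` variants and `A` candidates:
#' `E(t) = [a/s] / [A/S]`, and the conservative FDR upper bound among
#' significant candidates is
#' `min(1, [(s - a) * A / (S - A)] / a)` (non-candidate hits presumed null,
#' candidate null rate equal to the non-candidate rate).
#'
#' @param p_values Numeric p-values.
#' @param flags Logical candidate flags, same length.
#' @param t_step Threshold increment on the -log10 scale (default 0.5).
#' @return An `enrichment_result` data frame: `t`, `s`, `a`, `enrichment`,
#'   `fdr_ub`, with totals `S` and `A` as attributes.
#' @export
enrichment_curve <- function(p_values, flags, t_step = 0.5) {
  if (length(p_values) != length(flags) || length(p_values) == 0L) {
    stop("p_values and flags must be non-empty and the same length")
  }
  S <- length(p_values)
  A <- sum(flags)
  if (A == 0L || A == S) stop("degenerate background: A must satisfy 0 < A < S")
  lp <- -log10(p_values)
  tmax <- max(0, floor(max(lp[is.finite(lp)]) / t_step) * t_step)
  t <- seq(0, tmax, by = t_step)
  s <- vapply(t, function(th) sum(lp >= th), integer(1))
  a <- vapply(t, function(th) sum(lp >= th & flags), integer(1))
  enr <- ifelse(s > 0, (a / s) / (A / S), NA_real_)
  fdr <- ifelse(a > 0, pmin(1, ((s - a) * A / (S - A)) / a), NA_real_)
  structure(data.frame(t = t, s = s, a = a, enrichment = enr, fdr_ub = fdr),
            class = c("enrichment_result", "data.frame"),
            S = S, A = A)
}

enrichment_at <- function(lp, flags, threshold) {
  s <- sum(lp >= threshold)
  if (s == 0L) return(NA_real_)
  a <- sum(lp >= threshold & flags)
  (a / s) / (sum(flags) / length(flags))
}

#' Rotation permutation test of candidate enrichment
#'
#' Null distribution by circularly shifting the candidate flag vector within
#' each chromosome by an independent uniform offset, keeping the p-values
#' fixed in genomic order (relative rotation preserves the local correlation
#' structure of both tracks). The statistic is the enrichment at
#' `test_threshold`; the empirical p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param p_values Numeric p-values, position-sorted within chromosomes.
#' @param flags Logical candidate flags.
#' @param chrom_of_variant Chromosome of each variant.
#' @param test_threshold Threshold on the -log10(p) scale (typically the
#'   Bonferroni threshold from the association scan).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A `rotation_null`: list with `observed`, `null` (numeric vector),
#'   `p`, `n_perm`, `seed`.
#' @export
rotation_test <- function(p_values, flags, chrom_of_variant, test_threshold,
                          n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: empirical p will be coarse")
  lp <- -log10(p_values)
  observed <- enrichment_at(lp, flags, test_threshold)
  if (is.na(observed)) {
    warning("no variants pass the test threshold; empirical p undefined")
    return(structure(list(observed = NA_real_, null = numeric(0), p = NA_real_,
                          n_perm = n_perm, seed = seed),
                     class = "rotation_null"))
  }
  chrom_idx <- split(seq_along(flags), chrom_of_variant)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      fl <- flags
      for (ix in chrom_idx) {
        k <- sample.int(length(ix), 1L) - 1L  # offset 0 .. n-1
        if (k > 0L) fl[ix] <- fl[ix][c((k + 1L):length(ix), 1L:k)]
      }
      enrichment_at(lp, fl, test_threshold)
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p,
                 n_perm = n_perm, seed = seed),
            class = "rotation_null")
}

#' @export
print.rotation_null <- function(x, ...) {
  cat(sprintf("rotation_null: observed %.3f, empirical p %.4g (%d perms)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Genomic-feature enrichment of low p-values
#'
#' For each feature `f` and threshold `t`:
#' `enrichment_f(t) = [fraction of sites with -log10(p) >= t in f] /
#' [fraction of all sites in f]`. Features with zero background sites give
#' `NA`. The background-weighted mean of defined enrichments is 1 at every
#' threshold.
#'
#' @param p_values Numeric p-values.
#' @param feature_label_per_site Character feature label per site (exactly
#'   one, precedence-resolved upstream).
#' @param t_step Threshold increment (default 0.5).
#' @return Long-format data frame: `feature`, `t`, `enrichment`,
#'   `background_fraction`.
#' @export
feature_enrichment <- function(p_values, feature_label_per_site, t_step = 0.5) {
  if (length(p_values) != length(feature_label_per_site)) {
    stop("p_values and labels must have the same length")
  }
  lp <- -log10(p_values)
  feats <- sort(unique(feature_label_per_site))
  bg <- vapply(feats, function(f) mean(feature_label_per_site == f), numeric(1))
  tmax <- max(0, floor(max(lp[is.finite(lp)]) / t_step) * t_step)
  t <- seq(0, tmax, by = t_step)
  out <- do.call(rbind, lapply(t, function(th) {
    sig <- lp >= th
    n_sig <- sum(sig)
    enr <- vapply(feats, function(f) {
      if (bg[f] == 0) return(NA_real_)
      if (n_sig == 0L) return(NA_real_)
      mean(feature_label_per_site[sig] == f) / bg[f]
    }, numeric(1))
    data.frame(feature = feats, t = th, enrichment = enr,
               background_fraction = unname(bg), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Resolve overlapping feature annotations to one label per site
#'
#' Assigns each site the highest-precedence feature class whose interval
#' contains it; sites in no interval are `"intergenic"`.
#'
#' @param site_chrom,site_pos Site coordinates (1-based positions).
#' @param features An `interval_set` with `feature_class` labels.
#' @param precedence Class precedence, highest first.
#' @return Character vector of labels.
#' @export
feature_labels <- function(site_chrom, site_pos, features,
                           precedence = c("CDS", "promoter", "gene", "TE",
                                          "intergenic")) {
  pos0 <- site_pos - 1L
  labels <- rep("intergenic", length(site_pos))
  rank <- stats::setNames(seq_along(precedence), precedence)
  current <- rep(Inf, length(site_pos))
  for (chr in unique(features$chrom)) {
    fi <- features[features$chrom == chr, , drop = FALSE]
    vi <- which(site_chrom == chr)
    if (length(vi) == 0L) next
    for (r in seq_len(nrow(fi))) {
      cls <- fi$feature_class[r]
      rk <- rank[cls]
      if (is.na(rk)) rk <- length(precedence) + 1
      inside <- vi[pos0[vi] >= fi$start[r] & pos0[vi] < fi$end[r]]
      upd <- inside[rk < current[inside]]
      labels[upd] <- cls
      current[upd] <- rk
    }
  }
  labels
}
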