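# Methylation-side operations: site filtering for EWA, extreme-group
# selection, a transparent seed-merge-test DMR caller (substituting the
# external WGBS DMR pipeline with the same printed constraints: 4x coverage,
# per-context processing, 20 vs 20 design, FDR < 20%), DMR feature
# densities, and EWA input preparation.

#' Select the highest- and lowest-load samples
#'
#' @param loads Named numeric vector of residual loads.
#' @param n Group size (default 20).
#' @return List with `high` and `low` sample id vectors (ties broken by
#'   sample id, deterministically).
#' @export
select_extreme_samples <- function(loads, n = 20L) {
  if (2L * n > length(loads)) stop("2n exceeds the number of samples")
  ids <- names(loads)
  if (is.null(ids)) stop("loads must be named by sample id")
  ord <- order(loads, ids)  # ascending load, id-lexicographic ties
  list(high = sort(ids[utils::tail(ord, n)]),
       low = sort(ids[utils::head(ord, n)]))
}

#' Filter a unionbed to informative, well-covered sites
#'
#' A site is kept iff it has coverage >= `min_cov` in at least `presence` of
#' the samples AND at least `min_diff_samples` samples differ from the site
#' median methylation by at least `min_diff`.
#'
#' @param ub A `unionbed`.
#' @param min_cov Minimum per-sample coverage (default 4, i.e. coverage > 3).
#' @param presence Minimum fraction of samples covered (default 0.95).
#' @param min_diff Minimum absolute deviation from the site median
#'   (default 0.05).
#' @param min_diff_samples Minimum number of deviating samples (default 2).
#' @return Filtered `unionbed`.
#' @export
filter_union <- function(ub, min_cov = 4L, presence = 0.95, min_diff = 0.05,
                         min_diff_samples = 2L) {
  n <- ncol(ub$coverage)
  covered <- rowSums(ub$coverage >= min_cov) / n >= presence
  med <- apply(ub$fraction, 1L, stats::median, na.rm = TRUE)
  dev <- abs(ub$fraction - med)
  informative <- rowSums(dev >= min_diff, na.rm = TRUE) >= min_diff_samples
  keep <- which(covered & informative)
  new_unionbed(ub$sites[keep, , drop = FALSE],
               ub$fraction[keep, , drop = FALSE],
               ub$coverage[keep, , drop = FALSE])
}

#' Call differentially methylated regions between two sample groups
#'
#' Per context: seed sites are those where both groups have at least 80% of
#' their samples covered at `min_cov` and the group mean difference is at
#' least `seed_diff`; seeds closer than `max_gap` bp are merged; merged
#' regions with at least `min_sites` seed sites are tested by Mann-Whitney U
#' on per-sample region mean methylation (samples with no covered site in
#' the region are dropped); Benjamini-Hochberg correction is applied across
#' regions within the context and regions with `q < fdr` are reported.
#'
#' @param ub A `unionbed`.
#' @param high,low Sample id vectors (disjoint).
#' @param min_cov Minimum coverage for a sample to contribute to a site
#'   (default 4).
#' @param seed_diff Minimum absolute group mean difference at seed sites
#'   (default 0.1).
#' @param max_gap Maximum merge gap in bp (default 300).
#' @param min_sites Minimum seed sites per region (default 5).
#' @param fdr BH q-value cutoff (default 0.2).
#' @param group_presence Minimum fraction of each group covered for a site
#'   to be usable (default 0.8).
#' @return A `dmr_set` data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `n_sites`, `delta` (high - low), `p`, `q`,
#'   `direction` (`hyper`/`hypo` w.r.t. the high group). The pre-test
#'   candidate regions are kept in the `candidates` attribute.
#' @export
call_dmrs <- function(ub, high, low, min_cov = 4L, seed_diff = 0.1,
                      max_gap = 300L, min_sites = 5L, fdr = 0.2,
                      group_presence = 0.8) {
  if (length(intersect(high, low))) stop("high and low groups overlap")
  stopifnot(all(c(high, low) %in% colnames(ub$fraction)))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), n_sites = integer(),
                      delta = numeric(), p = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  fh <- ub$fraction[, high, drop = FALSE]
  fl <- ub$fraction[, low, drop = FALSE]
  ch <- ub$coverage[, high, drop = FALSE]
  cl <- ub$coverage[, low, drop = FALSE]
  okh <- ch >= min_cov
  okl <- cl >= min_cov
  usable <- rowMeans(okh) >= group_presence & rowMeans(okl) >= group_presence
  mh <- rowSums(fh * okh, na.rm = TRUE) / rowSums(okh)
  ml <- rowSums(fl * okl, na.rm = TRUE) / rowSums(okl)
  seed <- usable & !is.na(mh) & !is.na(ml) & abs(mh - ml) >= seed_diff

  all_regions <- list()
  skipped <- 0L
  for (ctx in unique(ub$sites$context)) {
    for (chr in unique(ub$sites$chrom)) {
      si <- which(ub$sites$context == ctx & ub$sites$chrom == chr & seed)
      if (length(si) == 0L) next
      si <- si[order(ub$sites$pos[si])]
      pos <- ub$sites$pos[si]
      brk <- c(0L, cumsum(diff(pos) > max_gap))
      for (grp in split(si, brk)) {
        if (length(grp) < min_sites) next
        region_h <- fh[grp, , drop = FALSE]; region_h[!okh[grp, , drop = FALSE]] <- NA
        region_l <- fl[grp, , drop = FALSE]; region_l[!okl[grp, , drop = FALSE]] <- NA
        vh <- colMeans(region_h, na.rm = TRUE)
        vl <- colMeans(region_l, na.rm = TRUE)
        vh <- vh[is.finite(vh)]; vl <- vl[is.finite(vl)]
        if (length(vh) < 2L || length(vl) < 2L) { skipped <- skipped + 1L; next }
        p <- suppressWarnings(
          stats::wilcox.test(vh, vl, exact = FALSE)$p.value)
        if (!is.finite(p)) p <- 1
        delta <- mean(vh) - mean(vl)
        all_regions[[length(all_regions) + 1L]] <- data.frame(
          chrom = chr, start = min(ub$sites$pos[grp]) - 1L,
          end = max(ub$sites$pos[grp]), context = ctx,
          n_sites = length(grp), delta = delta, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(all_regions) == 0L) {
    out <- empty
  } else {
    cand <- do.call(rbind, all_regions)
    cand$q <- NA_real_
    for (ctx in unique(cand$context)) {
      sel <- cand$context == ctx
      cand$q[sel] <- stats::p.adjust(cand$p[sel], method = "BH")
    }
    cand$direction <- ifelse(cand$delta >= 0, "hyper", "hypo")
    out <- cand[cand$q < fdr, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "candidates") <- cand
  }
  attr(out, "skipped_regions") <- skipped
  structure(out, class = c("dmr_set", "data.frame"))
}

#' DMR density per genomic feature class
#'
#' `density_f = #DMRs overlapping feature class f / Mb covered by f`. A DMR
#' overlapping two feature classes counts in both.
#'
#' @param dmrs A `dmr_set`.
#' @param features An `interval_set` with `feature_class`.
#' @param genome_feature_mb Named vector: Mb covered by each feature class.
#' @return Named numeric vector of densities (per Mb); `NA` for zero-Mb
#'   features.
#' @export
dmr_feature_density <- function(dmrs, features, genome_feature_mb) {
  classes <- names(genome_feature_mb)
  counts <- stats::setNames(integer(length(classes)), classes)
  for (cls in classes) {
    fi <- features[features$feature_class == cls, , drop = FALSE]
    if (nrow(fi) == 0L || nrow(dmrs) == 0L) next
    hit <- vapply(seq_len(nrow(dmrs)), function(i) {
      any(fi$chrom == dmrs$chrom[i] & fi$start < dmrs$end[i] &
            fi$end > dmrs$start[i])
    }, logical(1))
    counts[cls] <- sum(hit)
  }
  ifelse(genome_feature_mb > 0, counts / genome_feature_mb, NA_real_)
}

#' Restrict a filtered unionbed to DMR intervals and set the EWA threshold
#'
#' Retains sites lying within any DMR of matching context and returns the
#' per-contrast Bonferroni threshold `0.05 / n_DMRs` (cytosines within one
#' DMR are treated as mutually correlated, so the DMR is the testing unit).
#'
#' @param ub A filtered `unionbed`.
#' @param dmrs A `dmr_set`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `unionbed` (possibly 0-row), `bonferroni_p`, `n_dmrs`,
#'   and `status` (`"ok"` or `"no_dmrs"`).
#' @export
ewa_sites <- function(ub, dmrs, alpha = 0.05) {
  n_dmrs <- nrow(dmrs)
  if (n_dmrs == 0L) {
    return(list(unionbed = new_unionbed(ub$sites[0, , drop = FALSE],
                                        ub$fraction[0, , drop = FALSE],
                                        ub$coverage[0, , drop = FALSE]),
                bonferroni_p = NA_real_, n_dmrs = 0L, status = "no_dmrs"))
  }
  pos0 <- ub$sites$pos - 1L
  keep <- rep(FALSE, nrow(ub$sites))
  for (i in seq_len(n_dmrs)) {
    keep <- keep | (ub$sites$chrom == dmrs$chrom[i] &
                      ub$sites$context == dmrs$context[i] &
                      pos0 >= dmrs$start[i] & pos0 < dmrs$end[i])
  }
  list(unionbed = new_unionbed(ub$sites[keep, , drop = FALSE],
                               ub$fraction[keep, , drop = FALSE],
                               ub$coverage[keep, , drop = FALSE]),
       bonferroni_p = alpha / n_dmrs, n_dmrs = n_dmrs, status = "ok")
}

#' Write DMRs as BED6+ (score = -log10 q; extra columns delta, n_sites,
#' direction)
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4g\t.\t%.6g\t%d\t%s",
                   dmrs$chrom, dmrs$start, dmrs$end, dmrs$context,
                   -log10(pmax(dmrs$q, 1e-300)), dmrs$delta, dmrs$n_sites,
                   dmrs$direction)
  writeLines(lines, path)
  invisible(path)
}
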