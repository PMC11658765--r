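# Methylation matrix simulator: context-specific Beta baselines, negative
# binomial coverage, binomial sampling of observed fractions, and spiked
# load-linked differentially methylated intervals.

#' Simulate a multi-sample methylation matrix with spiked DMRs
#'
#' Baseline per-site methylation is Beta-distributed with context-specific
#' means (CG high, CHG intermediate, CHH low). Within `n_dmr` spiked
#' intervals, per-sample methylation is shifted by
#' `dmr_effect * standardised(load)` (negative effect = hypomethylation in
#' high-load samples). Coverage is negative binomial; observed fractions are
#' binomial draws at the true methylation level, missing where coverage is 0.
#'
#' @param n_sites_per_context Sites per context; scalar or named vector over
#'   `c("CG", "CHG", "CHH")`. Use 0 to skip a context.
#' @param loads Named numeric vector of per-sample loads (names = sample ids).
#' @param n_dmr Number of spiked intervals.
#' @param dmr_effect Methylation shift per standard deviation of load, in
#'   [-1, 1].
#' @param dmr_sites Number of consecutive sites per spiked interval.
#' @param spike_context Context carrying the spiked intervals.
#' @param coverage_mu,coverage_size Negative binomial coverage parameters.
#' @param baseline_conc Concentration of the Beta baseline around the context
#'   mean.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return List with `unionbed` and `truth` (spiked intervals as an
#'   `interval_set`, effect, seed).
#' @export
simulate_methylation <- function(n_sites_per_context = 2000L, loads,
                                 n_dmr = 5L, dmr_effect = -0.3,
                                 dmr_sites = 10L, spike_context = "CG",
                                 coverage_mu = 15, coverage_size = 5,
                                 baseline_conc = 8, chrom = "Chr1",
                                 seed = 1L) {
  if (dmr_effect < -1 || dmr_effect > 1) stop("dmr_effect must be in [-1, 1]")
  contexts <- c("CG", "CHG", "CHH")
  if (length(n_sites_per_context) == 1L && is.null(names(n_sites_per_context))) {
    n_sites_per_context <- stats::setNames(rep(n_sites_per_context, 3), contexts)
  }
  ctx_mean <- c(CG = 0.70, CHG = 0.30, CHH = 0.08)
  samples <- names(loads)
  n <- length(loads)
  z <- if (stats::sd(loads) > 0) (loads - mean(loads)) / stats::sd(loads) else
    rep(0, n)
  with_seed(seed, {
    site_list <- list()
    for (ctx in contexts) {
      m <- as.integer(n_sites_per_context[[ctx]] %||% 0L)
      if (m == 0L) next
      pos <- cumsum(sample(20:60, m, replace = TRUE))
      site_list[[ctx]] <- data.frame(chrom = chrom, pos = pos, context = ctx,
                                     stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    ns <- nrow(sites)
    mu_site <- ctx_mean[sites$context]
    base <- stats::rbeta(ns, mu_site * baseline_conc,
                         (1 - mu_site) * baseline_conc)

    # spiked intervals: runs of consecutive sites within spike_context
    in_spike <- rep(FALSE, ns)
    spike_iv <- NULL
    ctx_idx <- which(sites$context == spike_context)
    if (n_dmr > 0) {
      if (length(ctx_idx) < n_dmr * dmr_sites * 2L) {
        stop("not enough ", spike_context, " sites for the requested spikes")
      }
      n_slots <- length(ctx_idx) %/% (2L * dmr_sites)
      slots <- sort(sample.int(n_slots, n_dmr))
      starts <- (slots - 1L) * 2L * dmr_sites + 1L
      iv <- lapply(starts, function(s) ctx_idx[s:(s + dmr_sites - 1L)])
      for (v in iv) in_spike[v] <- TRUE
      spike_iv <- new_interval_set(
        chrom = rep(chrom, n_dmr),
        start = vapply(iv, function(v) sites$pos[v[1]] - 1L, numeric(1)),
        end = vapply(iv, function(v) sites$pos[v[length(v)]], numeric(1)),
        feature_class = "spiked_dmr",
        name = sprintf("spike%02d", seq_len(n_dmr)))
    }

    truth_meth <- matrix(rep(base, n), nrow = ns)
    if (any(in_spike)) {
      truth_meth[in_spike, ] <- truth_meth[in_spike, ] +
        matrix(rep(dmr_effect * z, each = sum(in_spike)), nrow = sum(in_spike))
    }
    truth_meth <- clip01(truth_meth)

    coverage <- matrix(stats::rnbinom(ns * n, mu = coverage_mu,
                                      size = coverage_size), nrow = ns)
    meth_reads <- matrix(stats::rbinom(ns * n, as.vector(coverage),
                                       as.vector(truth_meth)), nrow = ns)
    fraction <- ifelse(coverage > 0, meth_reads / coverage, NA_real_)
    colnames(fraction) <- samples
    colnames(coverage) <- samples
    list(
      unionbed = new_unionbed(sites, fraction, coverage),
      truth = list(spiked = spike_iv, dmr_effect = dmr_effect,
                   spike_context = spike_context, loads_z = z,
                   seed = as.integer(seed))
    )
  })
}
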