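# Population-structured genotypes (Balding-Nichols model) and pest-load
# liabilities with configurable SNP heritability and population effects.

#' Simulate population-structured biallelic genotypes
#'
#' Ancestral allele frequencies are uniform on `maf_range`; per-population
#' frequencies are Beta-distributed around them with concentration set by
#' `fst` (Balding-Nichols). Genotypes are binomial(2, p_pop) dosages.
#' `fst = 0` collapses to a panmictic population.
#'
#' @param n_samples Number of samples (split as evenly as possible across
#'   populations).
#' @param n_pops Number of populations (>= 1).
#' @param fst Differentiation parameter in [0, 1).
#' @param n_variants Number of variants (>= 1).
#' @param maf_range Range of ancestral allele frequencies.
#' @param seed Integer seed.
#' @param chrom_names Chromosome names; variants are split evenly across them
#'   with sorted random positions.
#' @param n_founders_per_pop If finite, each population consists of
#'   lineages descending from this many founder genotypes: every sample
#'   copies a founder at a fraction `founder_copy_rate` of variants and
#'   redraws the rest from the population frequencies. This emulates the
#'   within-population relatedness of selfing-species collections (repeated
#'   near-identical accessions), which is what makes kinship-based variance
#'   estimation well identified. Default `Inf` = all samples independent.
#' @param founder_copy_rate Fraction of the genome copied from the founder
#'   (ignored when `n_founders_per_pop = Inf`).
#' @return List with `variants` (a `variant_table`) and `populations`
#'   (character vector of population labels per sample).
#' @export
make_population <- function(n_samples = 200L, n_pops = 2L, fst = 0.1,
                            n_variants = 2000L, maf_range = c(0.05, 0.5),
                            seed = 1L, chrom_names = c("Chr1", "Chr2"),
                            n_founders_per_pop = Inf,
                            founder_copy_rate = 0.9) {
  if (n_variants < 1L) stop("n_variants must be >= 1")
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  with_seed(seed, {
    pops <- rep(paste0("pop", seq_len(n_pops)), length.out = n_samples)
    pops <- sort(pops)
    p_anc <- stats::runif(n_variants, maf_range[1], maf_range[2])
    dosage <- matrix(0L, nrow = n_samples, ncol = n_variants)
    for (k in seq_len(n_pops)) {
      idx <- which(pops == paste0("pop", k))
      if (fst == 0) {
        p_pop <- p_anc
      } else {
        c0 <- (1 - fst) / fst
        p_pop <- stats::rbeta(n_variants, p_anc * c0, (1 - p_anc) * c0)
      }
      draw <- function(rows) matrix(
        stats::rbinom(rows * n_variants, 2L, rep(p_pop, each = rows)),
        nrow = rows)
      if (is.finite(n_founders_per_pop)) {
        founders <- draw(as.integer(n_founders_per_pop))
        pick <- sample.int(nrow(founders), length(idx), replace = TRUE)
        block <- founders[pick, , drop = FALSE]
        redraw <- matrix(stats::runif(length(idx) * n_variants) >
                           founder_copy_rate, nrow = length(idx))
        fresh <- draw(length(idx))
        block[redraw] <- fresh[redraw]
        dosage[idx, ] <- block
      } else {
        dosage[idx, ] <- draw(length(idx))
      }
    }
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    rownames(dosage) <- sample_ids
    chrom <- rep(chrom_names, length.out = n_variants)
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(n_variants), chrom), function(ix) {
      sort(sample.int(1e7, length(ix)))
    }), use.names = FALSE)
    ids <- paste0(chrom, "_", pos)
    colnames(dosage) <- ids
    sites <- data.frame(chrom = chrom, pos = pos, id = ids,
                        ref = "A", alt = "T", missing_frac = 0,
                        stringsAsFactors = FALSE)
    list(variants = new_variant_table(sites, dosage),
         populations = stats::setNames(pops, sample_ids))
  })
}

#' Simulate pest loads, sequencing depths and exogenous read counts
#'
#' A liability \eqn{l_i = g_i + u_{pop(i)} + e_i} is built with
#' \eqn{Var(g) = h^2}, \eqn{Var(u) = pop\_effect\_sd^2} and residual variance
#' topping the total up to 1. The genetic value comes either from `n_causal`
#' sampled variants with standardised effects (`genetic_model = "causal"`) or
#' directly from the IBS kinship (`genetic_model = "kinship"`, an exactly
#' h2-calibrated polygenic background). The liability maps to a pest genome
#' fraction through a monotone positive link; depths are log-normal and read
#' counts Poisson(f_i * d_i) (negative binomial when `nb_size` is finite).
#'
#' @param population Output of [make_population()].
#' @param n_causal Number of causal variants (`genetic_model = "causal"`).
#' @param h2 True SNP heritability of the liability, in [0, 1].
#' @param pop_effect_sd Standard deviation of per-population effects on the
#'   liability scale.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of per-sample
#'   deduplicated read totals.
#' @param f_max Maximum pest genome fraction (exp link uses
#'   `f_max * exp(0.5 * l) / exp(2)` capped at `f_max`).
#' @param link Liability-to-fraction link: `"softplus"` (default; bounded
#'   scaled softplus) or `"exp"` (log-linear, preserves liability-scale
#'   variance ratios on the log-count scale).
#' @param genetic_model `"causal"` or `"kinship"` (see above).
#' @param nb_size If finite, counts are negative binomial with this size
#'   (overdispersion toggle); default `Inf` = Poisson.
#' @param seed Integer seed.
#' @return List with `counts`, `depths`, `fractions`, `liability`, and
#'   `truth` (causal ids/effects, `h2_true`, population effects, seed).
#' @export
simulate_loads <- function(population, n_causal = 100L, h2 = 0.3,
                           pop_effect_sd = 0, depth_meanlog = log(2e5),
                           depth_sdlog = 0.3, f_max = 0.02,
                           link = c("softplus", "exp"),
                           genetic_model = c("causal", "kinship"),
                           nb_size = Inf, seed = 1L) {
  link <- match.arg(link)
  genetic_model <- match.arg(genetic_model)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  dosage <- population$variants$dosage
  n <- nrow(dosage)
  if (genetic_model == "causal" && n_causal > ncol(dosage)) {
    stop("n_causal exceeds the number of variants")
  }
  if (h2 + pop_effect_sd^2 > 1) stop("h2 + pop_effect_sd^2 must be <= 1")
  with_seed(seed, {
    causal_ids <- character(0)
    beta <- numeric(0)
    if (h2 == 0) {
      g <- rep(0, n)
    } else if (genetic_model == "causal") {
      causal_idx <- sort(sample.int(ncol(dosage), n_causal))
      causal_ids <- colnames(dosage)[causal_idx]
      beta <- stats::rnorm(n_causal)
      gmat <- scale(dosage[, causal_idx, drop = FALSE])
      gmat[is.na(gmat)] <- 0  # monomorphic columns contribute nothing
      g <- drop(gmat %*% beta)
      g <- (g - mean(g)) / stats::sd(g) * sqrt(h2)
    } else {
      K <- ibs_kinship(population$variants)$K
      K <- K * (n / sum(diag(K)))
      eg <- eigen(K, symmetric = TRUE)
      d <- pmax(eg$values, 0)
      # theoretical scaling (marginal Var(g_i) = h2 * K_ii, mean diag 1):
      # an empirical rescale by sd(g) would inflate the genetic variance
      # whenever K carries strong shared structure
      g <- sqrt(h2) * drop(eg$vectors %*% (sqrt(d) * stats::rnorm(n)))
    }
    pops <- population$populations
    pop_levels <- unique(pops)
    u <- stats::setNames(stats::rnorm(length(pop_levels), 0, 1), pop_levels)
    if (pop_effect_sd > 0 && stats::sd(u[pops]) > 0) {
      u_smp <- u[pops] / stats::sd(u[pops]) * pop_effect_sd
    } else {
      u_smp <- rep(0, n)
    }
    e_sd <- sqrt(max(0, 1 - h2 - pop_effect_sd^2))
    l <- g + u_smp + stats::rnorm(n, 0, e_sd)
    f <- switch(link,
      softplus = f_max * pmin(1, log1p(exp(l)) / log1p(exp(3))),
      exp = pmin(f_max, f_max * exp(0.5 * l) / exp(2))
    )
    d_i <- pmax(1, round(stats::rlnorm(n, depth_meanlog, depth_sdlog)))
    mu <- f * d_i
    counts <- if (is.finite(nb_size)) {
      stats::rnbinom(n, mu = mu, size = nb_size)
    } else {
      stats::rpois(n, mu)
    }
    ids <- rownames(dosage)
    list(
      counts = stats::setNames(counts, ids),
      depths = stats::setNames(d_i, ids),
      fractions = stats::setNames(f, ids),
      liability = stats::setNames(l, ids),
      truth = list(h2_true = h2, causal_ids = causal_ids, beta = beta,
                   pop_effect_sd = pop_effect_sd, link = link,
                   genetic_model = genetic_model, f_max = f_max,
                   seed = as.integer(seed))
    )
  })
}
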