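test_that("make_genomes places a conserved block with the requested divergence", {
  g0 <- make_genomes(host_len = 5000L, pest_specs = c(p = 3000L),
                     conserved_len = 1000L, divergence = 0, seed = 2L)
  hb <- g0$truth$host_block
  host_block <- substr(g0$host[[1]], hb["start"] + 1L, hb["end"])
  pb <- g0$truth$pest_blocks$p
  pest_block <- substr(g0$pests[["p"]], pb$block_start + 1L, pb$block_end)
  expect_identical(host_block, pest_block)

  g5 <- make_genomes(host_len = 5000L, pest_specs = c(p = 3000L),
                     conserved_len = 1000L, divergence = 0.05, seed = 2L)
  hb <- g5$truth$host_block
  pb <- g5$truth$pest_blocks$p
  a <- strsplit(substr(g5$host[[1]], hb["start"] + 1L, hb["end"]), "")[[1]]
  b <- strsplit(substr(g5$pests[["p"]], pb$block_start + 1L, pb$block_end),
                "")[[1]]
  # direct mismatch count equals the recorded divergent positions
  expect_equal(which(a != b), pb$divergent_offsets)
  expect_gt(length(pb$divergent_offsets), 20L)
  expect_lt(length(pb$divergent_offsets), 90L)
})

test_that("make_genomes is seed-deterministic and validates lengths", {
  a <- make_genomes(seed = 9L)
  b <- make_genomes(seed = 9L)
  expect_identical(a, b)
  expect_error(make_genomes(host_len = 1000L, conserved_len = 1000L),
               "conserved_len")
  expect_error(make_genomes(divergence = 0.5), "divergence")
})

test_that("make_population: fst = 0 gives undifferentiated populations", {
  pop <- make_population(n_samples = 200L, n_pops = 2L, fst = 0,
                         n_variants = 200L, seed = 5L)
  pvals <- vapply(seq_len(200L), function(j) {
    tab <- table(pop$populations, pop$variants$dosage[, j])
    if (ncol(tab) < 2L) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05, na.rm = TRUE), 0.9)
})

test_that("make_population labels, determinism and validation", {
  pop <- make_population(n_samples = 10L, n_pops = 1L, n_variants = 20L,
                         seed = 1L)
  expect_true(all(pop$populations == "pop1"))
  expect_identical(make_population(seed = 4L, n_samples = 30L,
                                   n_variants = 50L)$variants$dosage,
                   make_population(seed = 4L, n_samples = 30L,
                                   n_variants = 50L)$variants$dosage)
  expect_error(make_population(n_variants = 0L), "n_variants")
  expect_error(make_population(fst = 1), "fst")
  # positions sorted within chromosomes
  s <- pop$variants$sites
  expect_true(all(tapply(s$pos, s$chrom, function(p) all(diff(p) > 0))))
})

test_that("simulate_loads counts track depth and respect the seed", {
  pop <- make_population(n_samples = 150L, n_pops = 1L, fst = 0,
                         n_variants = 100L, seed = 6L)
  ld <- simulate_loads(pop, h2 = 0, pop_effect_sd = 0, depth_sdlog = 1.5,
                       seed = 6L)
  fit <- stats::lm(log(ld$counts + 1) ~ log(ld$depths))
  expect_gt(stats::coef(fit)[2], 0.9)
  expect_lt(stats::coef(fit)[2], 1.1)
  expect_identical(simulate_loads(pop, seed = 7L)$counts,
                   simulate_loads(pop, seed = 7L)$counts)
  expect_error(simulate_loads(pop, h2 = 1.2), "h2")
})

test_that("simulate_alignments: truth labels, zero-ambiguity and zero-count edges", {
  w <- tiny_alignment_world(seed = 13L, n_samples = 6L,
                            ambiguous_fraction = 0)
  for (sid in names(w$sims)) {
    s <- w$sims[[sid]]
    cl <- classify_sample(s$host, s$pests)
    expect_length(cl$ambiguous, 0L)
  }
  # a sample with zero pest count has zero exogenous pest-assigned pairs
  w2 <- tiny_alignment_world(seed = 14L, n_samples = 8L)
  w2$loads$counts[] <- c(0L, w2$loads$counts[-1])  # force one zero sample
  sims <- simulate_alignments(w2$genomes, w2$loads, ambiguous_fraction = 0.2,
                              n_host_pairs = 30L, seed = 14L)
  s <- sims[[1]]
  cl <- classify_sample(s$host, s$pests)
  expect_length(cl$exogenous, 0L)
  cnt <- count_exogenous_by_taxon(cl, s$pests)
  expect_equal(unname(cnt["pestA"]), 0L)
})

test_that("simulate_methylation spikes shift the high-load group and obey the seed", {
  loads <- stats::setNames(stats::rnorm(30), sprintf("s%02d", 1:30))
  sim <- simulate_methylation(n_sites_per_context = c(CG = 400L, CHG = 0L,
                                                      CHH = 0L),
                              loads = loads, n_dmr = 3L, dmr_effect = -0.3,
                              seed = 8L)
  ub <- sim$unionbed
  expect_true(all(is.na(ub$fraction) == (ub$coverage == 0)))
  grp <- select_extreme_samples(loads, n = 10L)
  sp <- sim$truth$spiked
  pos0 <- ub$sites$pos - 1L
  for (i in seq_len(nrow(sp))) {
    inside <- pos0 >= sp$start[i] & pos0 < sp$end[i] &
      ub$sites$context == "CG"
    mh <- mean(ub$fraction[inside, grp$high], na.rm = TRUE)
    ml <- mean(ub$fraction[inside, grp$low], na.rm = TRUE)
    expect_lt(mh, ml)  # hypomethylated in the high-load group
  }
  expect_identical(
    simulate_methylation(100L, loads = loads, n_dmr = 0L, seed = 3L)$unionbed,
    simulate_methylation(100L, loads = loads, n_dmr = 0L, seed = 3L)$unionbed)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(make_genomes(seed = 1L))
  invisible(make_population(n_samples = 10L, n_variants = 10L, seed = 1L))
  expect_identical(.Random.seed, before)
})
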