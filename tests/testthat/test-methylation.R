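test_that("select_extreme_samples picks ranks deterministically", {
  loads <- stats::setNames(1:40, sprintf("s%02d", 1:40))
  grp <- select_extreme_samples(loads, n = 20L)
  expect_setequal(grp$high, sprintf("s%02d", 21:40))
  expect_setequal(grp$low, sprintf("s%02d", 1:20))
  rev_grp <- select_extreme_samples(rev(loads), n = 20L)
  expect_equal(rev_grp, grp)  # input order does not matter
  # boundary tie: resolved id-lexicographically
  tied <- stats::setNames(c(1, 2, 2, 3), c("a", "b", "c", "d"))
  g2 <- select_extreme_samples(tied, n = 2L)
  expect_equal(g2$low, c("a", "b"))
  expect_equal(g2$high, c("c", "d"))
  expect_error(select_extreme_samples(loads, n = 21L), "2n")
})

test_that("filter_union applies presence and difference rules (hand-counted)", {
  n <- 20L
  samples <- sprintf("s%02d", 1:n)
  sites <- data.frame(chrom = "Chr1", pos = c(10L, 20L, 30L, 40L),
                      context = "CG", stringsAsFactors = FALSE)
  cov <- matrix(10L, 4, n, dimnames = list(NULL, samples))
  frac <- matrix(0.5, 4, n, dimnames = list(NULL, samples))
  # site 1: passes (two deviating samples)
  frac[1, 1:2] <- c(0.4, 0.6)
  # site 2: covered in only 18/20 = 90% < 95% -> dropped
  cov[2, 1:2] <- 3L
  frac[2, 3:4] <- c(0.3, 0.7)
  # site 3: identical fractions everywhere -> dropped
  # site 4: only one deviating sample -> dropped
  frac[4, 1] <- 0.9
  ub <- new_unionbed(sites, frac, cov)
  kept <- filter_union(ub, min_cov = 4L, presence = 0.95, min_diff = 0.05,
                       min_diff_samples = 2L)
  expect_equal(kept$sites$pos, 10L)
})

test_that("call_dmrs finds nothing when groups are identical", {
  loads <- stats::setNames(rnorm(20), sprintf("s%02d", 1:20))
  sim <- simulate_methylation(300L, loads = loads, n_dmr = 0L, seed = 2L)
  ub <- sim$unionbed
  # duplicate the matrix so both groups carry the same columns
  both <- new_unionbed(ub$sites,
                       cbind(ub$fraction, `colnames<-`(ub$fraction, paste0("d", 1:20))),
                       cbind(ub$coverage, `colnames<-`(ub$coverage, paste0("d", 1:20))))
  dmrs <- call_dmrs(both, high = colnames(ub$fraction), low = paste0("d", 1:20))
  expect_equal(nrow(dmrs), 0L)
  expect_error(call_dmrs(ub, high = names(loads)[1:10],
                         low = names(loads)[5:15]), "overlap")
})

test_that("call_dmrs recovers a spiked region with the right direction", {
  loads <- stats::setNames(rnorm(40), sprintf("s%02d", 1:40))
  sim <- simulate_methylation(n_sites_per_context = c(CG = 800L, CHG = 0L,
                                                      CHH = 0L),
                              loads = loads, n_dmr = 1L, dmr_effect = -0.4,
                              seed = 5L)
  grp <- select_extreme_samples(loads, n = 20L)
  dmrs <- call_dmrs(sim$unionbed, grp$high, grp$low)
  sp <- sim$truth$spiked
  overlap <- dmrs$chrom == sp$chrom & dmrs$start < sp$end & dmrs$end > sp$start
  expect_true(any(overlap))
  expect_true(all(dmrs$direction[overlap] == "hypo"))
  expect_true(all(dmrs$q >= dmrs$p, na.rm = TRUE))
  expect_true(all(dmrs$n_sites >= 5L))
})

test_that("seeds separated by more than max_gap form distinct regions", {
  samples <- sprintf("s%02d", 1:20)
  high <- samples[1:10]; low <- samples[11:20]
  # two blocks of 5 CG sites; block gap 301 bp; strong group contrast
  pos <- c(seq(100L, by = 50L, length.out = 5L),
           seq(100L + 4L * 50L + 301L, by = 50L, length.out = 5L))
  sites <- data.frame(chrom = "Chr1", pos = pos, context = "CG",
                      stringsAsFactors = FALSE)
  frac <- matrix(0.2, 10, 20, dimnames = list(NULL, samples))
  frac[, 1:10] <- 0.8
  cov <- matrix(10L, 10, 20, dimnames = list(NULL, samples))
  ub <- new_unionbed(sites, frac, cov)
  dmrs <- call_dmrs(ub, high, low, min_sites = 5L)
  expect_equal(nrow(dmrs), 2L)
  expect_true(all(dmrs$direction == "hyper"))
  # same layout with a 300 bp gap merges into one region
  pos2 <- pos; pos2[6:10] <- pos2[6:10] - 1L
  ub2 <- new_unionbed(transform(sites, pos = pos2), frac, cov)
  expect_equal(nrow(call_dmrs(ub2, high, low, min_sites = 5L)), 1L)
})

test_that("lowering seed_diff never shrinks the candidate region set", {
  loads <- stats::setNames(rnorm(30), sprintf("s%02d", 1:30))
  sim <- simulate_methylation(400L, loads = loads, n_dmr = 2L,
                              dmr_effect = -0.3, seed = 9L)
  grp <- select_extreme_samples(loads, n = 15L)
  n_cand <- vapply(c(0.3, 0.2, 0.1, 0.05), function(sd0) {
    d <- call_dmrs(sim$unionbed, grp$high, grp$low, seed_diff = sd0)
    cand <- attr(d, "candidates")
    if (is.null(cand)) 0L else nrow(cand)
  }, integer(1))
  expect_true(all(diff(n_cand) >= 0))
})

test_that("dmr_feature_density divides overlap counts by feature Mb", {
  dmrs <- structure(data.frame(
    chrom = "Chr1", start = seq(0L, 900L, by = 100L),
    end = seq(50L, 950L, by = 100L), context = "CG", n_sites = 5L,
    delta = -0.2, p = 0.001, q = 0.01, direction = "hypo",
    stringsAsFactors = FALSE), class = c("dmr_set", "data.frame"))
  features <- new_interval_set("Chr1", 0L, 1000L, "TE", "te1")
  dens <- dmr_feature_density(dmrs, features, c(TE = 2, gene = 1, empty = 0))
  expect_equal(unname(dens["TE"]), 5)     # 10 DMRs / 2 Mb
  expect_equal(unname(dens["gene"]), 0)
  expect_true(is.na(dens["empty"]))
  none <- dmrs[0, ]
  expect_equal(unname(dmr_feature_density(none, features,
                                          c(TE = 2, gene = 1))["TE"]), 0)
})

test_that("ewa_sites restricts to matching-context DMR intervals and sets the threshold", {
  samples <- c("a", "b")
  sites <- data.frame(chrom = "Chr1", pos = c(100L, 200L, 300L),
                      context = c("CG", "CG", "CHH"),
                      stringsAsFactors = FALSE)
  frac <- matrix(0.5, 3, 2, dimnames = list(NULL, samples))
  cov <- matrix(5L, 3, 2, dimnames = list(NULL, samples))
  ub <- new_unionbed(sites, frac, cov)
  dmrs <- structure(data.frame(chrom = "Chr1", start = 150L, end = 350L,
                               context = "CG", n_sites = 5L, delta = 0.1,
                               p = 0.01, q = 0.05, direction = "hyper",
                               stringsAsFactors = FALSE),
                    class = c("dmr_set", "data.frame"))
  out <- ewa_sites(ub, dmrs)
  expect_equal(out$unionbed$sites$pos, 200L)  # pos 300 is CHH, wrong context
  expect_equal(out$bonferroni_p, 0.05)
  # the study-scale arithmetic: 162 DMRs -> 0.05 / 162
  many <- dmrs[rep(1, 162), ]
  expect_equal(ewa_sites(ub, many)$bonferroni_p, 0.05 / 162,
               tolerance = 1e-12)
  none <- dmrs[0, ]
  out0 <- ewa_sites(ub, none)
  expect_equal(out0$status, "no_dmrs")
  expect_equal(nrow(out0$unionbed$sites), 0L)
})

test_that("DMR intervals within a context are pairwise disjoint", {
  loads <- stats::setNames(rnorm(40), sprintf("s%02d", 1:40))
  sim <- simulate_methylation(c(CG = 600L, CHG = 200L, CHH = 200L),
                              loads = loads, n_dmr = 4L, dmr_effect = -0.4,
                              seed = 12L)
  grp <- select_extreme_samples(loads, n = 20L)
  dmrs <- call_dmrs(sim$unionbed, grp$high, grp$low)
  for (ctx in unique(dmrs$context)) {
    d <- dmrs[dmrs$context == ctx, ]
    d <- d[order(d$chrom, d$start), ]
    if (nrow(d) < 2L) next
    same <- d$chrom[-1] == d$chrom[-nrow(d)]
    expect_true(all(d$start[-1][same] >= d$end[-nrow(d)][same]))
  }
})
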