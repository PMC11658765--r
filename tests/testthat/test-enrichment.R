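test_that("mark_candidates applies the 20 kb window with half-open boundaries", {
  genes <- new_interval_set("Chr1", 50000L, 60000L, "gene", "g1")
  # gene start 50000 (0-based): window reaches 0-based 30000 = 1-based 30001
  flags <- mark_candidates(rep("Chr1", 4),
                           c(30001L, 30000L, 80000L, 80001L), genes,
                           window = 20000L)
  expect_equal(flags, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(mark_candidates("Chr9", 100L, genes), "chromosome")
})

test_that("mark_candidates agrees with a brute-force distance scan", {
  set.seed(6)
  genes <- new_interval_set(
    chrom = sample(c("Chr1", "Chr2"), 15, replace = TRUE),
    start = st <- sample.int(9e5, 15), end = st + sample.int(5000, 15),
    feature_class = "gene", name = paste0("g", 1:15))
  chrom <- sample(c("Chr1", "Chr2"), 3000, replace = TRUE)
  pos <- sample.int(1e6, 3000)
  fast <- mark_candidates(chrom, pos, genes, window = 20000L)
  brute <- vapply(seq_along(pos), function(i) {
    any(genes$chrom == chrom[i] &
          pos[i] - 1L >= genes$start - 20000L &
          pos[i] - 1L < genes$end + 20000L)
  }, logical(1))
  expect_identical(fast, brute)
})

test_that("enrichment_curve reproduces the hand-worked example exactly", {
  # S = 100, A = 10; at threshold 1.0: s = 10 of which a = 5 candidates
  p <- c(rep(0.05, 5), rep(0.05, 5), rep(0.5, 5), rep(0.5, 85))
  flags <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 85))
  res <- enrichment_curve(p, flags)
  row <- res[res$t == 1.0, ]
  expect_equal(row$s, 10L)
  expect_equal(row$a, 5L)
  expect_equal(row$enrichment, 5.0)
  expect_equal(row$fdr_ub, ((10 - 5) * 10 / 90) / 5)
  expect_equal(attr(res, "S"), 100L)
  expect_equal(attr(res, "A"), 10L)
  expect_error(enrichment_curve(p, rep(FALSE, 100)), "degenerate")
  expect_error(enrichment_curve(p, rep(TRUE, 100)), "degenerate")
})

test_that("enrichment_curve matches a naive per-threshold recount and is monotone", {
  set.seed(7)
  p <- runif(500)^2
  flags <- runif(500) < 0.15
  res <- enrichment_curve(p, flags)
  lp <- -log10(p)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$s[i], sum(lp >= res$t[i]))
    expect_equal(res$a[i], sum(lp >= res$t[i] & flags))
  }
  expect_true(all(diff(res$s) <= 0))
  expect_true(all(diff(res$a) <= 0))
  expect_true(all(res$a <= res$s))
  # null expectation: E(t) near 1 at low thresholds
  expect_lt(abs(res$enrichment[res$t == 0.5] - 1), 0.35)
})

test_that("rotation_test: identity rotation, all-true flags, determinism", {
  set.seed(8)
  p <- runif(300)
  chrom <- rep(c("Chr1", "Chr2"), each = 150)
  flags <- runif(300) < 0.2
  lp <- -log10(p)
  obs <- exoload:::enrichment_at(lp, flags, 0.5)
  rot <- rotation_test(p, flags, chrom, test_threshold = 0.5, n_perm = 200L,
                       seed = 4L)
  expect_equal(rot$observed, obs)
  rot2 <- rotation_test(p, flags, chrom, test_threshold = 0.5, n_perm = 200L,
                        seed = 4L)
  expect_identical(rot$null, rot2$null)
  expect_gte(rot$p, 1 / 201)
  # flags all true: enrichment identically 1 under any rotation
  rot_all <- rotation_test(p, rep(TRUE, 300), chrom, test_threshold = 0.5,
                           n_perm = 100L, seed = 1L)
  expect_equal(rot_all$observed, 1)
  expect_equal(rot_all$p, 1)
  expect_warning(rotation_test(p, flags, chrom, 0.5, n_perm = 50L, seed = 1L),
                 "coarse")
})

test_that("feature_enrichment conserves mass and degenerates correctly", {
  set.seed(9)
  p <- runif(400)
  single <- feature_enrichment(p, rep("TE", 400))
  expect_true(all(single$enrichment[!is.na(single$enrichment)] == 1))
  labels <- sample(c("gene", "TE", "intergenic"), 400, replace = TRUE,
                   prob = c(0.2, 0.3, 0.5))
  fe <- feature_enrichment(p, labels)
  for (th in unique(fe$t)) {
    sl <- fe[fe$t == th & !is.na(fe$enrichment), ]
    if (nrow(sl) < 3L) next  # a feature with no significant sites drops out
    expect_equal(sum(sl$enrichment * sl$background_fraction), 1,
                 tolerance = 1e-12)
  }
  # concentrating the small p-values in one feature drives its curve up
  p2 <- ifelse(labels == "TE", p / 1000, p)
  fe2 <- feature_enrichment(p2, labels)
  te <- fe2[fe2$feature == "TE", ]
  expect_gt(te$enrichment[te$t == 3], te$enrichment[te$t == 0])
})

test_that("feature_labels resolves overlaps by precedence", {
  features <- new_interval_set(
    chrom = rep("Chr1", 3), start = c(100L, 150L, 0L),
    end = c(300L, 250L, 1000L),
    feature_class = c("gene", "CDS", "TE"),
    name = c("g", "c", "t"))
  labs <- feature_labels(rep("Chr1", 4), c(120L, 200L, 500L, 2000L), features)
  expect_equal(labs, c("gene", "CDS", "TE", "intergenic"))
})
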