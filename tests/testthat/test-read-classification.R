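test_that("classify_sample applies the partition rules on a hand fixture", {
  # r1 host-mapped only; r2 host+pest mapped; r3 host-unmapped, pest-mapped;
  # r4 unmapped everywhere; r5 pest hit below the mapq threshold
  host <- write_sam_fixture(c(
    pair_lines("r1", TRUE), pair_lines("r2", TRUE),
    pair_lines("r3", FALSE), pair_lines("r4", FALSE),
    pair_lines("r5", TRUE)
  ))
  pest <- write_sam_fixture(c(
    pair_lines("r1", FALSE), pair_lines("r2", TRUE, rname = "pest"),
    pair_lines("r3", TRUE, rname = "pest"), pair_lines("r4", FALSE),
    pair_lines("r5", TRUE, rname = "pest", mapq = 10L)
  ))
  cl <- classify_sample(host, list(pestA = pest), mapq_min = 20L)
  expect_setequal(cl$target, c("r1", "r5"))
  expect_setequal(cl$ambiguous, "r2")
  expect_setequal(cl$exogenous, c("r3", "r4"))
  expect_length(cl$other, 0L)
  expect_equal(cl$n_pairs, 5L)
})

test_that("half-mapped pairs land in 'other' and secondary records are ignored", {
  host <- write_sam_fixture(c(
    sam_line("h1", 73L, "host", 10L, 60L),   # mate1 mapped, mate2 unmapped
    sam_line("h1", 133L),
    pair_lines("h2", FALSE),
    sam_line("h2", 321L, "host", 99L, 60L)   # secondary: not mapping evidence
  ))
  pest <- write_sam_fixture(c(pair_lines("h1", FALSE),
                              pair_lines("h2", FALSE)))
  cl <- classify_sample(host, list(p = pest))
  expect_setequal(cl$other, "h1")
  expect_setequal(cl$exogenous, "h2")
})

test_that("classification equals generator truth and partition is exact", {
  w <- tiny_alignment_world(seed = 31L, n_samples = 10L,
                            ambiguous_fraction = 0.25)
  for (sid in names(w$sims)) {
    s <- w$sims[[sid]]
    cl <- classify_sample(s$host, s$pests)
    expect_setequal(cl$target, s$truth$qname[s$truth$class == "target"])
    expect_setequal(cl$ambiguous, s$truth$qname[s$truth$class == "ambiguous"])
    expect_setequal(cl$exogenous, s$truth$qname[s$truth$class == "exogenous"])
    expect_equal(length(cl$target) + length(cl$ambiguous) +
                   length(cl$exogenous) + length(cl$other), cl$n_pairs)
  }
})

test_that("raising mapq_min never increases the ambiguous set", {
  w <- tiny_alignment_world(seed = 32L, n_samples = 5L,
                            ambiguous_fraction = 0.3)
  s <- w$sims[[1]]
  sizes <- vapply(c(0L, 20L, 41L, 100L), function(mq) {
    length(classify_sample(s$host, s$pests, mapq_min = mq)$ambiguous)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[4], 0L)  # pest mapq is 40 in the simulator
})

test_that("pest-only read ids missing from the host SAM raise an error", {
  host <- write_sam_fixture(pair_lines("a", TRUE))
  pest <- write_sam_fixture(c(pair_lines("a", FALSE),
                              pair_lines("ghost", TRUE, rname = "pest")))
  expect_error(classify_sample(host, list(p = pest)), "ghost")
})

test_that("count_exogenous_by_taxon counts, dedupes and matches truth", {
  w <- tiny_alignment_world(seed = 33L, n_samples = 8L)
  for (sid in names(w$sims)[1:4]) {
    s <- w$sims[[sid]]
    cl <- classify_sample(s$host, s$pests)
    cnt <- count_exogenous_by_taxon(cl, s$pests)
    expect_equal(unname(cnt["pestA"]),
                 sum(s$truth$class == "exogenous"))
  }
  # duplicate pair (same positions) collapses under dedupe
  host <- write_sam_fixture(c(pair_lines("d1", FALSE), pair_lines("d2", FALSE),
                              pair_lines("u1", FALSE)))
  pest <- write_sam_fixture(c(
    pair_lines("d1", TRUE, rname = "pest", pos = 500L, mapq = 40L),
    pair_lines("d2", TRUE, rname = "pest", pos = 500L, mapq = 40L),
    pair_lines("u1", TRUE, rname = "pest", pos = 900L, mapq = 40L)
  ))
  cl <- classify_sample(host, list(p = pest))
  expect_equal(unname(count_exogenous_by_taxon(cl, list(p = pest))["p"]), 2L)
  expect_equal(unname(count_exogenous_by_taxon(cl, list(p = pest),
                                               dedupe = FALSE)["p"]), 3L)
})

test_that("blacklist_ambiguous removes exactly the ambiguous records, idempotently", {
  w <- tiny_alignment_world(seed = 34L, n_samples = 5L,
                            ambiguous_fraction = 0.4)
  s <- w$sims[[which.max(w$loads$counts[1:5])]]
  cl <- classify_sample(s$host, s$pests)
  expect_gt(length(cl$ambiguous), 0L)
  clean <- blacklist_ambiguous(s$host, cl)
  expect_equal(nrow(s$host) - nrow(clean), 2L * length(cl$ambiguous))
  pests_clean <- lapply(s$pests, function(p)
    p[p$qname %in% clean$qname, , drop = FALSE])
  cl2 <- classify_sample(clean, pests_clean)
  expect_length(cl2$ambiguous, 0L)
  # empty ambiguous set: output identical to input
  w0 <- tiny_alignment_world(seed = 35L, n_samples = 3L,
                             ambiguous_fraction = 0)
  s0 <- w0$sims[[1]]
  cl0 <- classify_sample(s0$host, s0$pests)
  expect_identical(blacklist_ambiguous(s0$host, cl0), s0$host)
})
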