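test_that("overlap_degree follows the reciprocal-overlap formula", {
  p <- overlap_params(w = 1)
  expect_equal(overlap_degree(100, 100, 100, 100, p), 1.0)
  expect_equal(overlap_degree(50, 100, 100, 50, p), 0.25)
  expect_equal(overlap_degree(0, 100, 100, 0, p), 0.0)
  expect_equal(overlap_degree(50, 100, 100, 50, overlap_params(w = 2)), 0.5)
  expect_error(overlap_degree(50, 0, 100, 50, p), "positive")
  expect_error(overlap_degree(50, 100, -1, 50, p), "positive")
  expect_error(overlap_degree(50, 100, 100, 60, p), "m <= al")
})

test_that("overlap_degree is monotone in matches and bounded by w", {
  p <- overlap_params(w = 1)
  withr::with_seed(7, {
    for (i in 1:50) {
      ql <- sample(1000:20000, 1); rl <- sample(1000:20000, 1)
      al <- sample.int(min(ql, rl), 1)
      m <- sort(sample.int(al, 2))
      expect_lte(overlap_degree(al, ql, rl, m[1], p),
                 overlap_degree(al, ql, rl, m[2], p))
      expect_lte(overlap_degree(al, ql, rl, m[2], p), p$w)
    }
  })
})

make_paf <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qname = r[[1]], qlen = as.integer(r[[2]]),
               qstart = as.integer(r[[3]]), qend = as.integer(r[[4]]),
               strand = r[[5]], tname = r[[6]], tlen = as.integer(r[[7]]),
               tstart = as.integer(r[[8]]), tend = as.integer(r[[9]]),
               matches = as.integer(r[[10]]), block_len = as.integer(r[[11]]),
               mapq = 60L, is_primary = TRUE, stringsAsFactors = FALSE)
  }))
}

test_that("initial_classes aggregates chromosomes and defaults to None", {
  ref <- make_paf(
    list("r1", 1000, 0, 900, "+", "chr1", 5000, 0, 900, 900, 900),
    list("r1", 1000, 0, 900, "+", "chr1", 5000, 2000, 2900, 880, 900),
    list("r2", 1000, 0, 900, "+", "chr1", 5000, 0, 900, 900, 900),
    list("r2", 1000, 0, 900, "+", "chr7", 5000, 0, 900, 850, 900),
    list("r4", 1000, 0, 300, "+", "chr2", 5000, 0, 300, 300, 300)
  )
  cls <- initial_classes(ref, read_ids = c("r1", "r2", "r3", "r4"),
                         min_block_len = 500)
  expect_equal(cls$r1, "chr1")
  expect_equal(cls$r2, c("chr1", "chr7"))
  expect_equal(cls$r3, "None")
  # r4's only alignment fails min_block_len
  expect_equal(cls$r4, "None")
})

test_that("detect_containment covers both directions and the length tie", {
  aln <- make_paf(list("q", 100, 0, 100, "+", "t", 500, 0, 100, 100, 100))
  expect_equal(detect_containment(aln, 0.95), "query_contained")
  aln <- make_paf(list("q", 100, 0, 50, "+", "t", 500, 0, 50, 50, 50))
  expect_equal(detect_containment(aln, 0.95), "none")
  aln <- make_paf(list("q", 500, 0, 100, "+", "t", 100, 0, 100, 100, 100))
  expect_equal(detect_containment(aln, 0.95), "target_contained")
  # equal lengths, full mutual coverage: smaller id collapses
  aln <- make_paf(list("a", 100, 0, 100, "+", "b", 100, 0, 100, 100, 100))
  expect_equal(detect_containment(aln, 0.95), "query_contained")
  aln <- make_paf(list("b", 100, 0, 100, "+", "a", 100, 0, 100, 100, 100))
  expect_equal(detect_containment(aln, 0.95), "target_contained")
})

test_that("build_alg pairs every forward edge with an equal reverse edge", {
  ava <- make_paf(
    list("r1", 1000, 600, 1000, "+", "r2", 1000, 0, 400, 400, 400)
  )
  alg <- build_alg(ava, list(r1 = "chr1", r2 = "chr1"),
                   overlap_params(min_block_len = 100))
  expect_setequal(alg$nodes, c("r1", "r2"))
  expect_equal(nrow(alg$edges), 2)
  expect_equal(sort(alg$edges$direction), c("forward", "reverse"))
  expect_equal(alg$edges$weight[1], alg$edges$weight[2])
  expect_equal(alg$edges$weight[1], 400 * 400 / (1000 * 1000))
})

test_that("build_alg collapses containments and re-points edges", {
  # r2 fully contained in r1; r2 also overlaps r3
  ava <- make_paf(
    list("r2", 500, 0, 500, "+", "r1", 2000, 700, 1200, 500, 500),
    list("r2", 500, 200, 500, "+", "r3", 1000, 0, 300, 300, 300)
  )
  alg <- build_alg(ava, list(r1 = "chr1", r2 = "chr2", r3 = "None"),
                   overlap_params(min_block_len = 100))
  expect_setequal(alg$nodes, c("r1", "r3"))
  expect_equal(alg$contained_in[["r2"]], "r1")
  # the r2~r3 alignment now connects r1 and r3
  expect_setequal(alg$adj[["r1"]]$to, "r3")
  # r2's class joined r1's label set
  expect_setequal(alg$labels[["r1"]], c("chr1", "chr2"))
  # "None" disappeared from nowhere: r3 keeps it as its only label
  expect_equal(alg$labels[["r3"]], "None")
})

test_that("parallel edges keep only the maximum weight", {
  ava <- make_paf(
    list("r1", 1000, 500, 1000, "+", "r2", 1000, 0, 500, 500, 500),
    list("r1", 1000, 300, 1000, "-", "r2", 1000, 0, 700, 700, 700)
  )
  alg <- build_alg(ava, list(), overlap_params(min_block_len = 100))
  expect_equal(nrow(alg$edges), 2)
  expect_equal(alg$edges$weight[1], 700 * 700 / (1000 * 1000))
})

test_that("graph construction is idempotent and edge-paired on real data", {
  fx <- basic_fixture()
  cls <- initial_classes(fx$ref, read_ids = fx$reads$read_id)
  alg1 <- build_alg(fx$ava, cls)
  alg2 <- build_alg(fx$ava, cls)
  expect_identical(alg1$nodes, alg2$nodes)
  expect_identical(alg1$edges, alg2$edges)
  expect_identical(alg1$labels, alg2$labels)
  # every (from, to, weight) has its (to, from, weight) partner
  key <- paste(alg1$edges$from, alg1$edges$to, alg1$edges$weight)
  rev_key <- paste(alg1$edges$to, alg1$edges$from, alg1$edges$weight)
  expect_setequal(key, rev_key)
  # weights stay within the w bound (plus indel slack)
  expect_true(all(alg1$edges$weight <= alg1$params$w * 1.05))
})
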