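seg <- function(chrom, strand, ref_s, ref_e, read_s = 0, read_e = 100,
                read_id = "r") {
  list(read_s = read_s, read_e = read_e, ref_s = ref_s, ref_e = ref_e,
       chrom = chrom, strand = strand, read_id = read_id)
}

test_that("canonicalize_bnd implements all eight order/strand cases", {
  A <- function(strand, s, e) seg("chrA", strand, s, e)
  B <- function(strand, s, e) seg("chrB", strand, s, e)
  check <- function(first, second, exp) {
    got <- canonicalize_bnd(first, second)
    expect_equal(unlist(got[1, c("chrom1", "pos1", "chrom2", "pos2")],
                        use.names = FALSE),
                 exp)
  }
  # first on the smaller chromosome
  check(A("+", 100, 200), B("+", 5000, 5100), c("chrA", 200, "chrB", 5000))
  check(A("+", 100, 200), B("-", 5000, 5100), c("chrA", 200, "chrB", 5100))
  check(A("-", 100, 200), B("+", 5000, 5100), c("chrA", 100, "chrB", 5000))
  check(A("-", 100, 200), B("-", 5000, 5100), c("chrA", 100, "chrB", 5100))
  # first on the larger chromosome
  check(B("+", 5000, 5100), A("+", 100, 200), c("chrA", 100, "chrB", 5100))
  check(B("+", 5000, 5100), A("-", 100, 200), c("chrA", 200, "chrB", 5100))
  check(B("-", 5000, 5100), A("+", 100, 200), c("chrA", 100, "chrB", 5000))
  check(B("-", 5000, 5100), A("-", 100, 200), c("chrA", 200, "chrB", 5000))

  expect_error(canonicalize_bnd(A("+", 1, 2), A("+", 3, 4)),
               "single chromosome")
})

test_that("canonical signals are always chromosome-ordered", {
  withr::with_seed(5, {
    for (i in 1:1000) {
      chroms <- sample(paste0("chr", 1:9), 2)
      f <- seg(chroms[1], sample(c("+", "-"), 1),
               sample.int(1e6, 1), sample.int(1e6, 1) + 1e6)
      s <- seg(chroms[2], sample(c("+", "-"), 1),
               sample.int(1e6, 1), sample.int(1e6, 1) + 1e6)
      out <- canonicalize_bnd(f, s)
      expect_true(out$chrom1 < out$chrom2)
    }
  })
})

split_paf <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qname = r$id, qlen = 10000L, qstart = as.integer(r$qs),
               qend = as.integer(r$qe), strand = r$strand, tname = r$chrom,
               tlen = 200000L, tstart = as.integer(r$ts),
               tend = as.integer(r$te),
               matches = as.integer(r$qe - r$qs),
               block_len = as.integer(r$qe - r$qs), mapq = 60L,
               is_primary = TRUE, stringsAsFactors = FALSE)
  }))
}

test_that("extract_split_signals keeps only tight inter-chromosomal splits", {
  # one alignment: no split
  one <- split_paf(list(id = "r1", qs = 0, qe = 9000, strand = "+",
                        chrom = "chr1", ts = 1000, te = 10000))
  expect_equal(nrow(extract_split_signals(one)), 0)

  # genuine split: different chromosomes, 20 bp read gap
  sp <- split_paf(
    list(id = "r2", qs = 0, qe = 5000, strand = "+", chrom = "chr1",
         ts = 95000, te = 100000),
    list(id = "r2", qs = 5020, qe = 9000, strand = "+", chrom = "chr2",
         ts = 50000, te = 53980)
  )
  sig <- extract_split_signals(sp)
  expect_equal(nrow(sig), 1)
  expect_equal(sig$chrom1, "chr1")
  expect_equal(sig$pos1, 100000)
  expect_equal(sig$pos2, 50000)

  # same chromosome: excluded
  same <- split_paf(
    list(id = "r3", qs = 0, qe = 5000, strand = "+", chrom = "chr1",
         ts = 0, te = 5000),
    list(id = "r3", qs = 5000, qe = 9000, strand = "+", chrom = "chr1",
         ts = 90000, te = 94000)
  )
  expect_equal(nrow(extract_split_signals(same)), 0)

  # near-complete multi-mapping of the same stretch: not a split
  mm <- split_paf(
    list(id = "r4", qs = 0, qe = 9000, strand = "+", chrom = "chr1",
         ts = 0, te = 9000),
    list(id = "r4", qs = 100, qe = 9100, strand = "+", chrom = "chr2",
         ts = 0, te = 9000)
  )
  expect_equal(nrow(extract_split_signals(mm)), 0)
})

bnd <- function(c1, p1, c2, p2, id) {
  data.frame(chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2, read_id = id,
             bases1 = 5000L, bases2 = 5000L, stringsAsFactors = FALSE)
}

test_that("cluster_signals groups within the radius and enforces support", {
  p <- translocation_params(th_bnd = 100, min_support = 2)
  sig <- rbind(bnd("chr1", 1000, "chr2", 5000, "rA"),
               bnd("chr1", 1050, "chr2", 5040, "rB"))
  bp <- cluster_signals(sig, p)
  expect_true(nrow(bp) >= 1)
  expect_true(all(bp$n_support == 2))

  # two distant signals: two singleton clusters, both discarded
  sig2 <- rbind(bnd("chr1", 1000, "chr2", 5000, "rA"),
                bnd("chr1", 5000, "chr2", 9000, "rB"))
  expect_equal(nrow(cluster_signals(sig2, p)), 0)

  # a lone signal never reaches min_support = 2
  expect_equal(nrow(cluster_signals(bnd("chr1", 1, "chr2", 2, "rA"), p)), 0)
})

test_that("shared acceptor coordinates across clusters become the insertion", {
  p <- translocation_params(th_bnd = 1000, min_support = 2)
  # two junction clusters sharing the chr3 position, distinct chr2 positions
  sig <- rbind(
    bnd("chr2", 100000, "chr3", 100000, "r1"),
    bnd("chr2", 100010, "chr3", 100005, "r2"),
    bnd("chr2", 150000, "chr3", 100002, "r3"),
    bnd("chr2", 150020, "chr3", 99990, "r4")
  )
  bp <- cluster_signals(sig, p)
  ins <- bp[bp$kind == "insertion", ]
  del <- bp[bp$kind == "deletion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$chrom, "chr3")
  expect_lt(abs(ins$pos - 100000), 100)
  expect_setequal(ins$support_reads[[1]], c("r1", "r2", "r3", "r4"))
  expect_equal(nrow(del), 2)
  expect_setequal(del$chrom, c("chr2", "chr2"))
})

test_that("mark_enhanced_nodes overrides labels, following containment", {
  alg <- alg_from_edges(data.frame(from = "r1", to = "r9", weight = 1),
                        list(r1 = "chr1", r9 = "chr1"))
  alg$contained_in <- c(rC = "r9")
  bp <- data.frame(kind = "insertion", chrom = "chr2", pos = 100L,
                   n_support = 2L, stringsAsFactors = FALSE)
  bp$support_reads <- list(c("r1", "rC"))
  out <- mark_enhanced_nodes(alg, bp)
  expect_equal(unname(out$enhanced["r1"]), "chr2")
  expect_equal(unname(out$enhanced["r9"]), "chr2")  # rC's representative
  expect_equal(out$labels[["r1"]], "chr2")

  # no breakpoints: graph untouched
  empty <- cluster_signals(data.frame(chrom1 = character(),
                                      pos1 = integer(),
                                      chrom2 = character(),
                                      pos2 = integer(),
                                      read_id = character(),
                                      bases1 = integer(),
                                      bases2 = integer()))
  expect_identical(mark_enhanced_nodes(alg, empty), alg)
})
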