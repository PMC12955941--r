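test_that("truncation_check is boundary-inclusive", {
  p <- correction_params(theta = 0.3, epsilon = 1)
  expect_true(truncation_check(10, 3, p))   # 3 <= 4
  expect_false(truncation_check(10, 5, p))  # 5 > 4
  expect_true(truncation_check(10, 4, p))   # boundary
})

chain_alg <- function(weights, labels = list()) {
  n <- length(weights) + 1
  nodes <- letters[seq_len(n)]
  alg_from_edges(
    data.frame(from = nodes[-n], to = nodes[-1], weight = weights,
               stringsAsFactors = FALSE),
    labels, nodes = nodes)
}

test_that("grow_path truncates a chain at the weight drop", {
  alg <- chain_alg(c(10, 9, 2))
  p <- grow_path(alg, "a", params = correction_params(theta = 0.5,
                                                      epsilon = 0))
  expect_s3_class(p, "read_path")
  expect_equal(p$node_ids, c("a", "b", "c"))  # 2 <= 0.5 * 9 stops before d
})

test_that("grow_path extends bidirectionally from a star center", {
  alg <- alg_from_edges(data.frame(
    from = c("center", "center", "center"),
    to = c("n5", "n4", "n3"),
    weight = c(5, 4, 3), stringsAsFactors = FALSE))
  p <- grow_path(alg, "center",
                 params = correction_params(theta = 0, epsilon = 0))
  # forward takes the weight-5 leaf, reverse the weight-4 leaf
  expect_equal(p$node_ids, c("n4", "center", "n5"))
})

test_that("grow_path handles isolated nodes and rejects unknown starts", {
  alg <- alg_from_edges(data.frame(from = "a", to = "b", weight = 1),
                        nodes = c("a", "b", "lonely"))
  expect_equal(grow_path(alg, "lonely")$node_ids, "lonely")
  expect_error(grow_path(alg, "ghost"), "unknown start")
})

test_that("grow_path skips visited nodes via the next priority level", {
  alg <- alg_from_edges(data.frame(
    from = c("a", "a", "b"), to = c("b", "c", "d"),
    weight = c(10, 6, 9), stringsAsFactors = FALSE))
  p <- grow_path(alg, "a", visited = c("b"),
                 params = correction_params(theta = 0, epsilon = 0))
  # best edge (a-b, 10) is blocked, so the search drops to (a-c, 6)
  expect_true("c" %in% p$node_ids)
  expect_false("b" %in% p$node_ids)
})

test_that("grow_path matches the independent oracle on random graphs", {
  withr::with_seed(11, {
    for (i in 1:150) {
      n <- sample(2:30, 1)
      g <- random_labeled_graph(n, p_edge = stats::runif(1, 0.05, 0.4))
      start <- sample(g$nodes, 1)
      visited <- sample(setdiff(g$nodes, start),
                        size = sample(0:(n - 1), 1))
      theta <- stats::runif(1, 0, 0.9)
      eps <- stats::runif(1, 0, 0.2)
      p <- correction_params(theta = theta, epsilon = eps)
      mine <- grow_path(g$alg, start, visited, p)$node_ids
      # both edge directions for the oracle's flat scan
      ed <- rbind(g$edges,
                  data.frame(from = g$edges$to, to = g$edges$from,
                             weight = g$edges$weight))
      ref <- oracle_grow_path(ed, start, visited, theta, eps)
      expect_identical(mine, ref)
      # path legality: distinct nodes, consecutive adjacency
      expect_false(anyDuplicated(mine) > 0)
      if (length(mine) > 1) {
        for (j in seq_len(length(mine) - 1)) {
          expect_true(mine[j + 1] %in% g$alg$adj[[mine[j]]]$to)
        }
      }
    }
  })
})

test_that("vote_path_class counts set membership and breaks ties low", {
  labels <- list(a = "chr1", b = "chr1", c = "chr2")
  expect_equal(vote_path_class(c("a", "b", "c"), labels), "chr1")
  labels <- list(a = c("chr1", "chr2"), b = "chr1", c = "chr3")
  expect_equal(vote_path_class(c("a", "b", "c"), labels), "chr1")
  labels <- list(a = "None", b = "None")
  expect_equal(vote_path_class(c("a", "b"), labels), "None")
  labels <- list(a = "chr2", b = "chr1")
  expect_equal(vote_path_class(c("a", "b"), labels), "chr1")
})

test_that("run_iteration propagates path majorities above the support floor", {
  lab <- stats::setNames(replicate(5, "chr2", simplify = FALSE),
                         letters[1:5])
  alg <- chain_alg(c(10, 10, 10, 10), lab)
  nh <- run_iteration(alg, correction_params(sn_min = 3, theta = 0),
                      order = letters[1:5])
  expect_true(all(nh == "chr2"))

  # path too small for SN_min: nodes keep their own single-class reading
  lab2 <- lab; lab2$c <- c("chr3", "chr5"); lab2$e <- "None"
  alg2 <- chain_alg(c(10, 10, 10, 10), lab2)
  nh2 <- run_iteration(alg2, correction_params(sn_min = 10, theta = 0),
                       order = letters[1:5])
  expect_equal(unname(nh2["c"]), "chr3")  # lexicographically smallest member
  expect_equal(unname(nh2["e"]), "None")
  expect_equal(unname(nh2["a"]), "chr2")
})

test_that("enhanced nodes override the path majority", {
  lab <- list(a = "chr1", b = "chr1", c = "chr1")
  alg <- chain_alg(c(10, 10), lab)
  alg$enhanced[["c"]] <- "chr4"
  nh <- run_iteration(alg, correction_params(sn_min = 1, theta = 0),
                      order = c("a", "b", "c"))
  expect_true(all(nh == "chr4"))
})

test_that("consensus_vote excludes None unless unanimous and breaks ties low", {
  expect_equal(consensus_vote(c("chr1", "chr1", "chr2")), "chr1")
  expect_equal(consensus_vote(c("chr1", "chr2")), "chr1")
  expect_equal(consensus_vote(c("None", "None", "chr7")), "chr7")
  expect_equal(consensus_vote(c("None", "None")), "None")
})

test_that("correct_classes is deterministic under a fixed seed", {
  withr::with_seed(3, g <- random_labeled_graph(25, 0.2))
  s1 <- correct_classes(g$alg, correction_params(seed = 7))
  s2 <- correct_classes(g$alg, correction_params(seed = 7))
  expect_identical(s1$class_hash, s2$class_hash)
  expect_identical(s1$final_class, s2$final_class)
  expect_equal(ncol(s1$class_hash), 5)
  expect_true(all(g$alg$nodes %in% names(s1$final_class)))
})

test_that("bin_reads inherits classes through containment", {
  final <- c(r1 = "chr1", r2 = "chr2", r4 = "None")
  asn <- bin_reads(final, contained_in = c(r3 = "r1"))
  expect_equal(asn$class[asn$read_id == "r3"], "chr1")
  expect_equal(asn$class[asn$read_id == "r4"], "unassigned")
  expect_setequal(asn$read_id, c("r1", "r2", "r3", "r4"))
})
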