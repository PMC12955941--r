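# Shared fixtures (built once per session) and an independent path-search
# oracle used to cross-check the greedy implementation.

fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
}

write_fixture <- function(key, genome, reads) {
  dir <- file.path(tempdir(), paste0("fixture_", key))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads_fa <- file.path(dir, "reads.fa")
  write_fasta(stats::setNames(reads$sequence, reads$read_id), reads_fa)
  ref_paf <- file.path(dir, "ref.paf")
  ava_paf <- file.path(dir, "ava.paf")
  ref <- naive_align(reads, genome)
  ava <- naive_align(reads)
  write_paf(ref, ref_paf)
  write_paf(ava, ava_paf)
  list(dir = dir, genome = genome, reads = reads,
       truth = stats::setNames(reads$truth_chrom, reads$read_id),
       reads_fa = reads_fa, ref_paf = ref_paf, ava_paf = ava_paf,
       ref = ref, ava = ava)
}

# 3 chromosomes x 200 kb, 5x error-free 10 kb reads, no repeats
basic_fixture <- function() {
  if (is.null(fixture_cache$basic)) {
    g <- simulate_genome(n_chrom = 3, chrom_len = 200000, seed = 101)
    rd <- simulate_reads(g, coverage = 5, mean_len = 10000, len_sd = 1000,
                         subst_rate = 0, seed = 102)
    fixture_cache$basic <- write_fixture("basic", g, rd)
  }
  fixture_cache$basic
}

# same scale plus a 15 kb repeat family, one copy per chromosome
repeat_fixture <- function() {
  if (is.null(fixture_cache$rpt)) {
    g <- simulate_genome(n_chrom = 3, chrom_len = 200000,
                         shared_repeat_len = 15000, n_repeat_copies = 1,
                         seed = 201)
    rd <- simulate_reads(g, coverage = 5, mean_len = 10000, len_sd = 1000,
                         subst_rate = 0, seed = 202)
    fixture_cache$rpt <- write_fixture("repeat", g, rd)
  }
  fixture_cache$rpt
}

# planted 50 kb translocation chr2[100k,150k) -> chr3 @ 100k; reads come
# from the rearranged genome, alignments go to the unmodified reference
transloc_fixture <- function() {
  if (is.null(fixture_cache$tr)) {
    g0 <- simulate_genome(n_chrom = 3, chrom_len = 200000, seed = 301)
    g1 <- plant_translocation(g0, donor = "chr2", donor_start = 100000,
                              donor_end = 150000, acceptor = "chr3",
                              acceptor_pos = 100000)
    rd <- simulate_reads(g1, coverage = 5, mean_len = 10000, len_sd = 1000,
                         subst_rate = 0, seed = 302)
    fx <- write_fixture("transloc", g1, rd)
    fx$ref <- naive_align(rd, g0)
    write_paf(fx$ref, fx$ref_paf)
    fx$reference_genome <- g0
    fixture_cache$tr <- fx
  }
  fixture_cache$tr
}

# fraction of each read covered by a repeat copy of its own chromosome
repeat_overlap_fraction <- function(reads, annotations) {
  vapply(seq_len(nrow(reads)), function(i) {
    a <- annotations[annotations$chrom == reads$truth_chrom[i], ,
                     drop = FALSE]
    if (!nrow(a)) return(0)
    rs <- reads$truth_start[i]
    re <- rs + reads$length[i]
    max(pmax(0, pmin(re, a$end) - pmax(rs, a$start))) / reads$length[i]
  }, numeric(1))
}

# Independent reference implementation of the greedy bidirectional path
# growth: works off the raw edge table with repeated full scans, no
# precomputed adjacency, so it shares no code with grow_path().
oracle_grow_path <- function(edges, start, visited, theta, eps) {
  best_candidate <- function(cur, excluded) {
    cand <- edges[edges$from == cur & !(edges$to %in% excluded), ,
                  drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(-cand$weight, cand$to), , drop = FALSE]
    cand[1, ]
  }
  walk <- function(cur, excluded) {
    out <- character(0)
    prev_w <- NA_real_
    repeat {
      cand <- best_candidate(cur, excluded)
      if (is.null(cand)) break
      if (!is.na(prev_w) && cand$weight <= theta * prev_w + eps) break
      out <- c(out, cand$to)
      excluded <- c(excluded, cand$to)
      prev_w <- cand$weight
      cur <- cand$to
    }
    list(nodes = out, excluded = excluded)
  }
  fwd <- walk(start, c(visited, start))
  bwd <- walk(start, fwd$excluded)
  c(rev(bwd$nodes), start, fwd$nodes)
}

# random labeled graph for property tests (undirected pair list + alg)
random_labeled_graph <- function(n_nodes, p_edge = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      weight = round(stats::runif(sum(keep), 0.01, 1), 4),
                      stringsAsFactors = FALSE)
  classes <- c("chr1", "chr2", "chr3", "None")
  labels <- lapply(stats::setNames(nodes, nodes), function(n) {
    k <- sample(1:2, 1)
    sample(classes, k)
  })
  list(alg = alg_from_edges(edges, labels, nodes = nodes), edges = edges,
       nodes = nodes)
}
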