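#' Overlap-graph parameters
#'
#' @param w positive scale constant of the overlap-degree score. The greedy
#'   path search and the drop rule are scale-covariant when `epsilon` is
#'   expressed in units of `w`, so the default of 1 loses no generality.
#' @param min_block_len minimum alignment block length (bp) for an alignment
#'   to contribute an edge or an initial class.
#' @param containment_cov fraction of the shorter read that must be covered
#'   by an alignment to declare containment (in (0, 1]).
#' @return an object of class `overlap_params`.
#' @export
overlap_params <- function(w = 1, min_block_len = 500, containment_cov = 0.95) {
  stopifnot(is.numeric(w), length(w) == 1, w > 0,
            is.numeric(min_block_len), min_block_len >= 0,
            is.numeric(containment_cov),
            containment_cov > 0, containment_cov <= 1)
  structure(list(w = w, min_block_len = as.integer(min_block_len),
                 containment_cov = containment_cov),
            class = "overlap_params")
}

#' Overlap degree between two sequences
#'
#' The edge weight of the alignment label graph:
#' \deqn{od = \frac{al}{ql} \cdot \frac{al}{rl} \cdot \frac{m}{al} \cdot w
#'          = \frac{al \cdot m \cdot w}{ql \cdot rl}}
#' where `al` is the alignment block length, `ql` and `rl` the two sequence
#' lengths, `m` the number of residue matches and `w` a scale constant. It
#' combines the reciprocal overlap fractions with the match fraction, so a
#' long, accurate, mutually covering alignment scores close to `w`. `al = 0`
#' yields 0 by continuity.
#'
#' @param al alignment block length (bp); PAF column 11.
#' @param ql,rl query and target sequence lengths (bp); must be positive.
#' @param m residue matches (bp); PAF column 10.
#' @param params an [overlap_params()] object (supplies `w`).
#' @return numeric vector of weights (vectorized over the inputs).
#' @examples
#' overlap_degree(100, 100, 100, 100, overlap_params(w = 1)) # 1
#' overlap_degree(50, 100, 100, 50, overlap_params(w = 1))   # 0.25
#' @export
overlap_degree <- function(al, ql, rl, m, params = overlap_params()) {
  if (any(ql <= 0) || any(rl <= 0)) {
    stop("sequence lengths ql and rl must be positive", call. = FALSE)
  }
  if (any(al < 0) || any(m < 0) || any(m > al)) {
    stop("require 0 <= m <= al", call. = FALSE)
  }
  # algebraically (al/ql)*(al/rl)*(m/al)*w; this form is exact at al = 0
  (as.numeric(al) * as.numeric(m) * params$w) / (as.numeric(ql) * as.numeric(rl))
}

#' Initial chromosome classes from reference alignments
#'
#' Each read is labeled with the set of distinct chromosomes it aligns to,
#' counting primary and secondary alignments whose block length passes
#' `min_block_len` (suboptimal alignments are informative here: a read from
#' a shared repeat legitimately carries several classes). Reads with no
#' passing alignment get the class `"None"`.
#'
#' @param ref_alns data.frame of read-vs-reference alignments ([read_paf()]).
#' @param read_ids optional character vector of all read ids; reads absent
#'   from `ref_alns` are then included with class `"None"`.
#' @param min_block_len minimum block length (bp).
#' @return a named list mapping read_id to a character vector of classes.
#' @export
initial_classes <- function(ref_alns, read_ids = NULL, min_block_len = 500) {
  keep <- ref_alns$block_len >= min_block_len
  cls <- lapply(split(ref_alns$tname[keep], ref_alns$qname[keep]),
                function(x) sort(unique(x)))
  all_ids <- unique(c(ref_alns$qname, read_ids))
  out <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (id in all_ids) {
    v <- cls[[id]]
    out[[id]] <- if (is.null(v) || !length(v)) "None" else v
  }
  out
}

#' Classify a read-vs-read alignment as a containment
#'
#' A read is contained when the alignment covers at least `containment_cov`
#' of it and it is not longer than its partner. When both reads have equal
#' length and full mutual coverage, the lexicographically smaller id is the
#' one that collapses.
#'
#' @param aln one-row data.frame with PAF fields.
#' @param containment_cov coverage fraction threshold.
#' @return one of `"none"`, `"query_contained"`, `"target_contained"`.
#' @export
detect_containment <- function(aln, containment_cov = 0.95) {
  qcov <- (aln$qend - aln$qstart) / aln$qlen
  tcov <- (aln$tend - aln$tstart) / aln$tlen
  q_ok <- qcov >= containment_cov && aln$qlen <= aln$tlen
  t_ok <- tcov >= containment_cov && aln$tlen <= aln$qlen
  if (q_ok && t_ok) {
    if (aln$qname <= aln$tname) "query_contained" else "target_contained"
  } else if (q_ok) {
    "query_contained"
  } else if (t_ok) {
    "target_contained"
  } else {
    "none"
  }
}

# union-find where the representative is the longer read
# (ties: lexicographically larger id survives, smaller id collapses)
resolve_reps <- function(pairs_contained, pairs_rep, lens) {
  parent <- stats::setNames(names(lens), names(lens))
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  better <- function(a, b) {
    if (lens[[a]] != lens[[b]]) lens[[a]] > lens[[b]] else a > b
  }
  for (i in seq_along(pairs_contained)) {
    ra <- find(pairs_contained[i]); rb <- find(pairs_rep[i])
    if (ra == rb) next
    if (better(ra, rb)) parent[[rb]] <- ra else parent[[ra]] <- rb
  }
  vapply(names(lens), find, character(1))
}

#' Build the alignment label graph (ALG)
#'
#' Constructs the bidirectional read-overlap graph: containment pairs are
#' collapsed first (transitively, the shorter read into the longer), then
#' every remaining alignment with `block_len >= min_block_len` contributes a
#' forward edge and a paired reverse edge of identical weight
#' ([overlap_degree()]). Parallel edges between the same pair keep only the
#' maximum weight. Label sets come from `classes`; a collapsed read donates
#' its classes to its representative, and `"None"` is dropped from any set
#' that contains a concrete chromosome.
#'
#' @param read_alns data.frame of all-vs-all read alignments ([read_paf()]);
#'   self-alignments are ignored.
#' @param classes named list of class sets, from [initial_classes()].
#' @param params an [overlap_params()] object.
#' @return an object of class `alg`: list with elements `nodes` (character),
#'   `contained_in` (named character, contained read to representative),
#'   `labels` (named list of class sets, one per node), `enhanced` (named
#'   character, translocation override classes; `NA` when absent), `edges`
#'   (data.frame `from, to, weight, direction`) and `adj` (per-node
#'   neighbor tables sorted by decreasing weight, ties by id).
#' @export
build_alg <- function(read_alns, classes, params = overlap_params()) {
  alns <- read_alns[read_alns$qname != read_alns$tname, , drop = FALSE]

  lens <- integer(0)
  if (nrow(alns)) {
    lens <- c(stats::setNames(alns$qlen, alns$qname),
              stats::setNames(alns$tlen, alns$tname))
    lens <- lens[!duplicated(names(lens))]
  }
  extra <- setdiff(names(classes), names(lens))
  lens <- c(lens, stats::setNames(rep(NA_integer_, length(extra)), extra))

  # containment collapse
  rep_of <- stats::setNames(names(lens), names(lens))
  if (nrow(alns)) {
    qcov <- (alns$qend - alns$qstart) / alns$qlen
    tcov <- (alns$tend - alns$tstart) / alns$tlen
    q_ok <- qcov >= params$containment_cov & alns$qlen <= alns$tlen
    t_ok <- tcov >= params$containment_cov & alns$tlen <= alns$qlen
    both <- q_ok & t_ok
    q_cont <- (q_ok & !both) | (both & alns$qname <= alns$tname)
    t_cont <- (t_ok & !both) | (both & alns$qname > alns$tname)
    contained <- c(alns$qname[q_cont], alns$tname[t_cont])
    container <- c(alns$tname[q_cont], alns$qname[t_cont])
    if (length(contained)) {
      rep_of <- resolve_reps(contained, container, lens)
    }
  }
  contained_in <- rep_of[rep_of != names(rep_of)]
  nodes <- sort(names(rep_of)[rep_of == names(rep_of)])

  # edges between representatives
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(alns)) {
    keep <- alns$block_len >= params$min_block_len
    a <- alns[keep, , drop = FALSE]
    if (nrow(a)) {
      wgt <- overlap_degree(a$block_len, a$qlen, a$tlen, a$matches, params)
      ef <- rep_of[a$qname]; et <- rep_of[a$tname]
      live <- ef != et
      if (any(live)) {
        dt <- data.table::data.table(
          pair_lo = pmin(ef[live], et[live]),
          pair_hi = pmax(ef[live], et[live]),
          weight = wgt[live]
        )
        dt <- dt[, .(weight = max(weight)), by = .(pair_lo, pair_hi)]
        data.table::setorder(dt, pair_lo, pair_hi)
        edges <- data.frame(
          from = c(dt$pair_lo, dt$pair_hi),
          to = c(dt$pair_hi, dt$pair_lo),
          weight = c(dt$weight, dt$weight),
          direction = rep(c("forward", "reverse"), each = nrow(dt)),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  # labels: merge collapsed reads into representatives, default "None"
  labels <- stats::setNames(replicate(length(nodes), "None", simplify = FALSE),
                            nodes)
  for (id in names(classes)) {
    r <- rep_of[[id]]
    if (is.null(labels[[r]])) next
    labels[[r]] <- sort(unique(c(labels[[r]], classes[[id]])))
  }
  labels <- lapply(labels, function(x) {
    x <- setdiff(x, "None")
    if (!length(x)) "None" else x
  })

  adj <- build_adjacency(edges, nodes)
  structure(list(nodes = nodes, contained_in = contained_in,
                 labels = labels,
                 enhanced = stats::setNames(rep(NA_character_, length(nodes)),
                                            nodes),
                 edges = edges, adj = adj, params = params),
            class = "alg")
}

#' Construct an ALG directly from an edge table
#'
#' Builds an alignment label graph from explicit edges and labels, without
#' going through alignments — convenient for small worked examples and for
#' testing path-search behavior on known topologies. Each input row is one
#' undirected overlap; the paired forward/reverse edges are created
#' automatically.
#'
#' @param edges data.frame with columns `from, to, weight` (one row per
#'   node pair).
#' @param labels named list of class sets; nodes absent from it get
#'   `"None"`.
#' @param nodes optional explicit node set (defaults to every id seen in
#'   `edges` or `labels`).
#' @return an `alg` object.
#' @export
alg_from_edges <- function(edges, labels = list(), nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to, names(labels))))
  } else {
    nodes <- sort(nodes)
  }
  e <- data.frame(
    from = c(edges$from, edges$to),
    to = c(edges$to, edges$from),
    weight = c(edges$weight, edges$weight),
    direction = rep(c("forward", "reverse"), each = nrow(edges)),
    stringsAsFactors = FALSE
  )
  lab <- stats::setNames(replicate(length(nodes), "None", simplify = FALSE),
                         nodes)
  for (id in intersect(names(labels), nodes)) {
    x <- setdiff(sort(unique(labels[[id]])), "None")
    lab[[id]] <- if (!length(x)) "None" else x
  }
  structure(list(nodes = nodes, contained_in = character(0), labels = lab,
                 enhanced = stats::setNames(rep(NA_character_,
                                                length(nodes)), nodes),
                 edges = e, adj = build_adjacency(e, nodes),
                 params = overlap_params()),
            class = "alg")
}

# per-node candidate tables, sorted by decreasing weight then neighbor id —
# the greedy priority order of the path search
build_adjacency <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    sp <- split(seq_len(nrow(edges)), edges$from)
    for (nd in names(sp)) {
      e <- edges[sp[[nd]], c("to", "weight")]
      e <- e[order(-e$weight, e$to), , drop = FALSE]
      rownames(e) <- NULL
      adj[[nd]] <- e
    }
  }
  adj
}

#' @export
print.alg <- function(x, ...) {
  cat(sprintf(
    "Alignment label graph: %d nodes, %d edge pairs, %d contained reads\n",
    length(x$nodes), nrow(x$edges) / 2L, length(x$contained_in)))
  none <- sum(vapply(x$labels, function(l) identical(l, "None"), logical(1)))
  cat(sprintf("  unlabeled (None) nodes: %d; enhanced nodes: %d\n",
              none, sum(!is.na(x$enhanced))))
  invisible(x)
}

#' Serialize an ALG to TSV files for inspection
#'
#' Writes `alg_nodes.tsv` (node, comma-joined labels, enhanced class) and
#' `alg_edges.tsv` (from, to, weight, direction).
#'
#' @param alg an `alg` object.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_alg <- function(alg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- data.frame(
    node = alg$nodes,
    labels = vapply(alg$labels[alg$nodes], paste, character(1), collapse = ","),
    enhanced = unname(alg$enhanced[alg$nodes]),
    stringsAsFactors = FALSE
  )
  np <- file.path(dir, "alg_nodes.tsv")
  ep <- file.path(dir, "alg_edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(alg$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(np, ep))
}
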