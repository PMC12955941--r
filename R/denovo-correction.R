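#' Correction parameters
#'
#' Tunables of the randomized greedy class correction. All ties anywhere in
#' the corrector (edge weights, vote counts, iteration consensus) break
#' lexicographically, so a fixed seed reproduces results exactly.
#'
#' @param theta drop-rule fraction in `[0, 1)`: extension stops when the
#'   candidate edge weight falls to `theta` times the previous weight plus
#'   `epsilon`.
#' @param epsilon drop-rule additive constant, in units of the
#'   overlap-degree scale `w`.
#' @param sn_min minimum path support: a path must contain more than
#'   `sn_min` nodes for its majority class to overwrite its members.
#' @param m_iters number of randomized iterations `M` for the consensus.
#' @param seed RNG seed for the per-iteration node permutations.
#' @return an object of class `correction_params`.
#' @export
correction_params <- function(theta = 0.5, epsilon = 0.05, sn_min = 3,
                              m_iters = 5, seed = 42) {
  stopifnot(is.numeric(theta), theta >= 0, theta < 1,
            is.numeric(epsilon), epsilon >= 0,
            sn_min >= 1, m_iters >= 1)
  structure(list(theta = theta, epsilon = epsilon,
                 sn_min = as.integer(sn_min),
                 m_iters = as.integer(m_iters), seed = as.integer(seed)),
            class = "correction_params")
}

#' Drop-rule truncation check
#'
#' A path extension is truncated when the candidate edge shows a
#' significant drop in overlap degree relative to the edge just taken:
#' \deqn{w_{jq} \le \theta \cdot w_{ij} + \epsilon}
#' The boundary is inclusive.
#'
#' @param w_ij weight of the edge from the previous node to the current one.
#' @param w_jq weight of the candidate edge out of the current node.
#' @param params a [correction_params()] object.
#' @return logical: `TRUE` means truncate (vectorized).
#' @export
truncation_check <- function(w_ij, w_jq, params = correction_params()) {
  w_jq <= params$theta * w_ij + params$epsilon
}

# lexicographically smallest concrete class of a label set, or "None"
own_class <- function(label_set) {
  x <- setdiff(label_set, "None")
  if (!length(x)) "None" else sort(x)[1]
}

# majority with lexicographic tie-break over a character vector
majority_class <- function(x) {
  tab <- table(x)
  m <- max(tab)
  sort(names(tab)[tab == m])[1]
}

#' Grow a greedy bidirectional path from a start node
#'
#' Extends independently in the forward and then the reverse direction.
#' Each step takes the highest-weight edge to a node that is neither
#' visited nor already in the path (equal weights break by lexicographic
#' neighbor id); if the best candidate is ineligible the next-highest edge
#' is tried. The chosen candidate is then subjected to the drop rule
#' ([truncation_check()]) against the weight of the previous step; the
#' very first step out of the start node has no previous weight and is
#' never truncated (this holds for both directions). The returned node
#' order is reverse-extension (reversed), start, forward-extension.
#'
#' @param alg an `alg` object.
#' @param start a node id; must not be in `visited`.
#' @param visited previously visited nodes: a character vector, or a named
#'   logical vector over all nodes (faster).
#' @param params a [correction_params()] object.
#' @return an object of class `read_path`: list with `node_ids` (character)
#'   and `decided_class` (`NA` until voted on).
#' @export
grow_path <- function(alg, start, visited = character(0),
                      params = correction_params()) {
  if (!start %in% alg$nodes) stop("unknown start node: ", start,
                                  call. = FALSE)
  blocked <- if (is.logical(visited)) {
    visited
  } else {
    stats::setNames(alg$nodes %in% visited, alg$nodes)
  }
  if (isTRUE(blocked[[start]])) {
    stop("start node is already visited: ", start, call. = FALSE)
  }
  blocked[[start]] <- TRUE

  extend <- function(cur) {
    out <- character(0)
    prev_w <- NA_real_
    repeat {
      nb <- alg$adj[[cur]]
      if (is.null(nb) || !nrow(nb)) break
      ok <- which(!blocked[nb$to])
      if (!length(ok)) break
      i <- ok[1]
      if (!is.na(prev_w) && truncation_check(prev_w, nb$weight[i], params)) {
        break
      }
      nxt <- nb$to[i]
      out <- c(out, nxt)
      blocked[[nxt]] <<- TRUE
      prev_w <- nb$weight[i]
      cur <- nxt
    }
    out
  }
  fwd <- extend(start)
  bwd <- extend(start)
  structure(list(node_ids = c(rev(bwd), start, fwd),
                 decided_class = NA_character_),
            class = "read_path")
}

#' Majority chromosome class of a path
#'
#' Counts, for every concrete class, the number of path nodes whose label
#' set contains it (a multi-class node votes once per class it carries) and
#' returns the most frequent one. Ties break to the lexicographically
#' smallest class; a path whose nodes are all `"None"` returns `"None"` —
#' the placeholder never outvotes a concrete class.
#'
#' @param path a `read_path` object or character vector of node ids.
#' @param labels named list of label sets (the ALG `labels` field).
#' @return a class string, possibly `"None"`.
#' @export
vote_path_class <- function(path, labels) {
  ids <- if (is.character(path)) path else path$node_ids
  cl <- unlist(labels[ids], use.names = FALSE)
  cl <- cl[cl != "None"]
  if (!length(cl)) return("None")
  majority_class(cl)
}

#' One randomized correction iteration
#'
#' Traverses the nodes in the given order; every still-unvisited node seeds
#' a greedy bidirectional path ([grow_path()]). The path's class is decided
#' by, in precedence order: (1) if it contains enhanced nodes, the majority
#' of their enhanced classes (translocation override); (2) if it has more
#' than `sn_min` nodes, the path majority vote ([vote_path_class()]);
#' (3) otherwise each node keeps its own single-class reading (the
#' lexicographically smallest concrete label it carries, or `"None"`). All
#' path nodes are then marked visited, so every node is decided exactly
#' once per iteration.
#'
#' @param alg an `alg` object.
#' @param params a [correction_params()] object.
#' @param enhanced named character vector of override classes (`NA` =
#'   none); defaults to the ALG's own `enhanced` field.
#' @param order node traversal order; defaults to a permutation drawn from
#'   the current RNG state.
#' @return a named character vector node -> class, with attribute `paths`:
#'   the list of `read_path` objects grown, each with `decided_class` set
#'   (`NA` decided class means rule (3) applied per node).
#' @export
run_iteration <- function(alg, params = correction_params(),
                          enhanced = alg$enhanced,
                          order = sample(alg$nodes)) {
  nodes <- alg$nodes
  vis <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  node_hash <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  paths <- list()
  for (v in order) {
    if (vis[[v]]) next
    p <- grow_path(alg, v, vis, params)
    ids <- p$node_ids
    enh <- enhanced[ids]
    enh <- enh[!is.na(enh)]
    if (length(enh)) {
      cls <- majority_class(enh)
      node_hash[ids] <- cls
      p$decided_class <- cls
    } else if (length(ids) > params$sn_min) {
      cls <- vote_path_class(ids, alg$labels)
      node_hash[ids] <- cls
      p$decided_class <- cls
    } else {
      node_hash[ids] <- vapply(alg$labels[ids], own_class, character(1))
    }
    vis[ids] <- TRUE
    paths[[length(paths) + 1L]] <- p
  }
  attr(node_hash, "paths") <- paths
  node_hash
}

#' Consensus class over iteration records
#'
#' Majority vote over the `M` per-iteration classes of one node. `"None"`
#' entries are excluded unless every entry is `"None"`; ties break to the
#' lexicographically smallest class.
#'
#' @param entries character vector of per-iteration classes.
#' @return the consensus class string.
#' @export
consensus_vote <- function(entries) {
  x <- entries[entries != "None" & !is.na(entries)]
  if (!length(x)) return("None")
  majority_class(x)
}

#' Run the full randomized class correction
#'
#' Repeats [run_iteration()] `m_iters` times, each with a fresh node
#' permutation drawn from a single seeded RNG stream and a fresh visited
#' set, then takes the per-node consensus ([consensus_vote()]) across
#' iterations. With a fixed seed the result is exactly reproducible.
#'
#' @param alg an `alg` object.
#' @param params a [correction_params()] object.
#' @param enhanced named character override vector; defaults to the ALG's.
#' @return an object of class `correction_state`: list with `class_hash`
#'   (character matrix, nodes x iterations), `final_class` (named character)
#'   and `params`.
#' @export
correct_classes <- function(alg, params = correction_params(),
                            enhanced = alg$enhanced) {
  nodes <- alg$nodes
  ch <- matrix(NA_character_, nrow = length(nodes), ncol = params$m_iters,
               dimnames = list(nodes, NULL))
  with_rng(params$seed, {
    for (m in seq_len(params$m_iters)) {
      ord <- sample(nodes)
      ch[, m] <- run_iteration(alg, params, enhanced, ord)[nodes]
    }
  })
  final <- apply(ch, 1L, consensus_vote)
  structure(list(class_hash = ch,
                 final_class = stats::setNames(final, nodes),
                 params = params),
            class = "correction_state")
}

#' Bin reads by their final class
#'
#' Contained reads inherit the final class of their representative; nodes
#' whose final class is `"None"` go to the `"unassigned"` bin.
#'
#' @param state a `correction_state` object (or a named character vector of
#'   final classes).
#' @param contained_in named character vector mapping contained reads to
#'   their representatives (the ALG `contained_in` field).
#' @param enhanced optional named character vector of override classes used
#'   to set the `enhanced_flag` column.
#' @return a data.frame with columns `read_id, class, enhanced_flag`; the
#'   `class` column uses `"unassigned"` for unplaceable reads.
#' @export
bin_reads <- function(state, contained_in = character(0), enhanced = NULL) {
  final <- if (is.character(state)) state else state$final_class
  ids <- c(names(final), names(contained_in))
  cls <- c(unname(final), unname(final[contained_in]))
  cls[is.na(cls) | cls == "None"] <- "unassigned"
  enh <- rep(FALSE, length(ids))
  if (!is.null(enhanced)) {
    enh <- !is.na(enhanced[ids])
    enh[is.na(enh)] <- FALSE
  }
  out <- data.frame(read_id = ids, class = cls, enhanced_flag = enh,
                    stringsAsFactors = FALSE)
  out[order(out$read_id), , drop = FALSE]
}
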