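#' Build the pangenome label graph (PLG)
#'
#' Pangenome-graph segments become nodes; a segment inherits a chromosome
#' label from its rGFA stable name when that name starts with
#' `backbone_prefix` (the linear-reference backbone). Sample-derived
#' segments (stable names such as `NA...` or `HG...`) and unnamed bubble
#' segments stay unlabeled. Links give a symmetric adjacency used for label
#' propagation.
#'
#' @param graph a `pangenome_graph_raw` object from [read_rgfa()].
#' @param backbone_prefix prefix identifying reference-backbone stable names.
#' @return an object of class `plg`: list with `nodes`, `chrom_label`
#'   (named character, `NA` when unlabeled) and `adj` (named list of
#'   neighbor character vectors, symmetric).
#' @export
build_plg <- function(graph, backbone_prefix = "chr") {
  segs <- graph$segments
  nodes <- segs$segment_id
  lab <- ifelse(!is.na(segs$stable_name) &
                  startsWith(segs$stable_name, backbone_prefix),
                segs$stable_name, NA_character_)
  chrom_label <- stats::setNames(lab, nodes)
  adj <- stats::setNames(replicate(length(nodes), character(0),
                                   simplify = FALSE), nodes)
  if (nrow(graph$links)) {
    for (i in seq_len(nrow(graph$links))) {
      a <- graph$links$from[i]; b <- graph$links$to[i]
      if (a == b) next
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  structure(list(nodes = nodes, chrom_label = chrom_label, adj = adj),
            class = "plg")
}

#' Harmonize a graph alignment to a chromosome class
#'
#' If any segment on the alignment path is itself labeled, the label of the
#' first labeled segment in path order is returned (the read touches the
#' backbone directly). Otherwise a hop-bounded, breadth-ordered search runs
#' bidirectionally from the path's two terminal segments and returns the
#' label reached in the fewest hops. Distinct labels at the same hop
#' distance are a tie and yield `NA`; the search also gives up (returning
#' `NA`) after visiting `max_visits` nodes. Breadth ordering makes the
#' answer deterministic and independent of neighbor enumeration order,
#' which a plain depth-first walk would not be.
#'
#' @param plg a `plg` object.
#' @param aln either one row of a [read_gaf()] data.frame or a character
#'   vector of segment ids (the path in order).
#' @param max_visits node-visit budget for the search.
#' @return a chromosome label, or `NA_character_` when unresolved.
#' @export
harmonize_class <- function(plg, aln, max_visits = 10000) {
  path <- if (is.character(aln)) aln else aln$path[[1]]$segment
  if (!length(path)) return(NA_character_)
  unknown <- setdiff(path, plg$nodes)
  if (length(unknown)) {
    stop("alignment path contains unknown segment(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  on_path <- plg$chrom_label[path]
  hit <- which(!is.na(on_path))
  if (length(hit)) return(unname(on_path[hit[1]]))

  # breadth-ordered bidirectional search from the two terminal segments
  frontier <- unique(c(path[1], path[length(path)]))
  seen <- stats::setNames(rep(TRUE, length(path)), path)
  visits <- 0L
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- plg$adj[[v]]
      nb <- nb[is.na(seen[nb])]
      nxt <- c(nxt, nb)
    }
    nxt <- unique(nxt)
    if (!length(nxt)) return(NA_character_)
    visits <- visits + length(nxt)
    if (visits > max_visits) return(NA_character_)
    labs <- unique(plg$chrom_label[nxt])
    labs <- labs[!is.na(labs)]
    if (length(labs) == 1) return(unname(labs))
    if (length(labs) > 1) return(NA_character_)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  NA_character_
}

#' Assign classes to unclassified reads via the pangenome graph
#'
#' Only reads currently labeled `{"None"}` are touched: each such read with
#' a graph alignment is harmonized through the PLG, and on success its class
#' set becomes the harmonized chromosome. Reads that stay unresolved keep
#' `"None"`; reads that already carry a concrete class are never modified.
#' When a read has several graph alignments, its first record (primary) is
#' used.
#'
#' @param plg a `plg` object.
#' @param gaf_alns data.frame from [read_gaf()].
#' @param classes named list of class sets ([initial_classes()]).
#' @param max_visits search budget per read, see [harmonize_class()].
#' @return the updated `classes` list.
#' @export
assign_unclassified <- function(plg, gaf_alns, classes, max_visits = 10000) {
  if (!nrow(gaf_alns)) return(classes)
  first_idx <- !duplicated(gaf_alns$qname)
  gaf1 <- gaf_alns[first_idx, , drop = FALSE]
  for (i in seq_len(nrow(gaf1))) {
    id <- gaf1$qname[i]
    cur <- classes[[id]]
    if (is.null(cur) || !identical(cur, "None")) next
    h <- harmonize_class(plg, gaf1$path[[i]]$segment, max_visits)
    if (!is.na(h)) classes[[id]] <- h
  }
  classes
}
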