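#' Translocation-detection parameters
#'
#' @param max_read_gap maximum distance (bp) on the read between two split
#'   segments for them to count as one junction; segment pairs that overlap
#'   on the read by more than this amount (multi-mappings of the same
#'   stretch, e.g. repeat-induced secondaries) are excluded too.
#' @param th_bnd cluster radius (bp) on both breakpoint coordinates.
#' @param min_support minimum number of supporting signals per cluster.
#' @param min_seg_len minimum block length (bp) of each split segment; with
#'   error-free reads this makes the supporting reads exactly those that
#'   overlap the junction by at least this much on both sides.
#' @return an object of class `translocation_params`.
#' @export
translocation_params <- function(max_read_gap = 100, th_bnd = 1000,
                                 min_support = 3, min_seg_len = 500) {
  stopifnot(max_read_gap >= 0, th_bnd >= 0, min_support >= 0,
            min_seg_len >= 0)
  structure(list(max_read_gap = as.integer(max_read_gap),
                 th_bnd = as.integer(th_bnd),
                 min_support = as.integer(min_support),
                 min_seg_len = as.integer(min_seg_len)),
            class = "translocation_params")
}

empty_signals <- function() {
  data.frame(chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), read_id = character(), bases1 = integer(),
             bases2 = integer(), stringsAsFactors = FALSE)
}

#' Canonicalize a split-alignment pair into a breakpoint signal
#'
#' Given the two split segments of one read (`first` precedes `second` on
#' the read, on different chromosomes), derives the canonical breakpoint
#' signal. Which reference coordinate of each segment faces the junction
#' depends on the segment's strand: on `+` the first segment contributes
#' its reference end and the second its reference start, and each `-`
#' strand flips its segment's contribution. The output is always ordered so
#' `chrom1 < chrom2` lexicographically. The eight
#' (chromosome-order x strand-combination) cases are:
#'
#' | order            | strands | signal |
#' |------------------|---------|--------|
#' | chr1 < chr2      | + +     | (chr1, ref1_end, chr2, ref2_start) |
#' | chr2 < chr1      | + +     | (chr2, ref2_start, chr1, ref1_end) |
#' | chr1 < chr2      | + -     | (chr1, ref1_end, chr2, ref2_end)   |
#' | chr2 < chr1      | + -     | (chr2, ref2_end, chr1, ref1_end)   |
#' | chr1 < chr2      | - +     | (chr1, ref1_start, chr2, ref2_start) |
#' | chr2 < chr1      | - +     | (chr2, ref2_start, chr1, ref1_start) |
#' | chr1 < chr2      | - -     | (chr1, ref1_start, chr2, ref2_end)  |
#' | chr2 < chr1      | - -     | (chr2, ref2_end, chr1, ref1_start)  |
#'
#' @param first,second lists/one-row data.frames with fields `read_s,
#'   read_e, ref_s, ref_e, chrom, strand, read_id` (the segment earlier on
#'   the read first).
#' @return one-row data.frame with `chrom1, pos1, chrom2, pos2, read_id`
#'   plus `bases1, bases2` (aligned bases on each side, used downstream to
#'   orient breakpoints).
#' @export
canonicalize_bnd <- function(first, second) {
  if (first$chrom == second$chrom) {
    stop("split pair maps to a single chromosome; not a translocation signal",
         call. = FALSE)
  }
  ss <- paste0(first$strand, second$strand)
  p1 <- switch(ss,
               "++" = first$ref_e, "+-" = first$ref_e,
               "-+" = first$ref_s, "--" = first$ref_s,
               stop("invalid strand combination: ", ss, call. = FALSE))
  p2 <- switch(ss,
               "++" = second$ref_s, "+-" = second$ref_e,
               "-+" = second$ref_s, "--" = second$ref_e)
  b1 <- first$ref_e - first$ref_s
  b2 <- second$ref_e - second$ref_s
  if (first$chrom < second$chrom) {
    out <- data.frame(chrom1 = first$chrom, pos1 = p1,
                      chrom2 = second$chrom, pos2 = p2,
                      read_id = first$read_id, bases1 = b1, bases2 = b2,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom1 = second$chrom, pos1 = p2,
                      chrom2 = first$chrom, pos2 = p1,
                      read_id = first$read_id, bases1 = b2, bases2 = b1,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Extract inter-chromosomal split-alignment signals
#'
#' For every read, its reference alignments are sorted by start coordinate
#' on the read; each adjacent pair mapped to different chromosomes whose
#' read-coordinate gap is within `max_read_gap` (in absolute value, so a
#' few bases of junction micro-homology are tolerated while near-complete
#' multi-mappings are not) is canonicalized into a breakpoint signal.
#' Segments shorter than `min_seg_len` are ignored.
#'
#' @param ref_alns data.frame of read-vs-reference alignments.
#' @param params a [translocation_params()] object.
#' @return data.frame of signals (see [canonicalize_bnd()]).
#' @export
extract_split_signals <- function(ref_alns, params = translocation_params()) {
  a <- ref_alns[ref_alns$block_len >= params$min_seg_len, , drop = FALSE]
  if (!nrow(a)) return(empty_signals())
  out <- list()
  for (idx in split(seq_len(nrow(a)), a$qname)) {
    if (length(idx) < 2) next
    seg <- a[idx, , drop = FALSE]
    seg <- seg[order(seg$qstart, seg$qend), , drop = FALSE]
    for (i in seq_len(nrow(seg) - 1L)) {
      f <- seg[i, ]; s <- seg[i + 1L, ]
      if (f$tname == s$tname) next
      gap <- s$qstart - f$qend
      if (abs(gap) >= params$max_read_gap) next
      out[[length(out) + 1L]] <- canonicalize_bnd(
        list(read_s = f$qstart, read_e = f$qend, ref_s = f$tstart,
             ref_e = f$tend, chrom = f$tname, strand = f$strand,
             read_id = f$qname),
        list(read_s = s$qstart, read_e = s$qend, ref_s = s$tstart,
             ref_e = s$tend, chrom = s$tname, strand = s$strand,
             read_id = s$qname)
      )
    }
  }
  if (!length(out)) return(empty_signals())
  do.call(rbind, out)
}

# single-pass greedy clustering: signals are scanned in sorted order and
# join the first cluster whose seed (first member) is within radius on both
# coordinates
greedy_cluster <- function(pos1, pos2, radius) {
  n <- length(pos1)
  cluster <- integer(n)
  seeds1 <- numeric(0); seeds2 <- numeric(0)
  for (i in seq_len(n)) {
    hit <- which(abs(pos1[i] - seeds1) <= radius &
                   abs(pos2[i] - seeds2) <= radius)
    if (length(hit)) {
      cluster[i] <- hit[1]
    } else {
      seeds1 <- c(seeds1, pos1[i]); seeds2 <- c(seeds2, pos2[i])
      cluster[i] <- length(seeds1)
    }
  }
  cluster
}

#' Cluster breakpoint signals and call breakpoints
#'
#' Signals are partitioned by chromosome pair, sorted by coordinates, and
#' greedily clustered: a signal joins a cluster when both its coordinates
#' are within `th_bnd` of the cluster's first member. Clusters below
#' `min_support` are discarded. The surviving clusters' per-side median
#' positions are then re-clustered with the same rule, one chromosome at a
#' time: a merged side supported by two or more signal clusters is the
#' insertion breakpoint (a translocation produces two junctions that share
#' the acceptor position but have distinct donor positions), the remaining
#' sides are the deletion breakpoints. When no side merges (only one
#' junction had support) the side whose chromosome carries more aligned
#' bases within the cluster is taken as the acceptor.
#'
#' @param signals data.frame from [extract_split_signals()].
#' @param params a [translocation_params()] object.
#' @return data.frame of breakpoints with columns `kind` (`"insertion"` or
#'   `"deletion"`), `chrom`, `pos`, `n_support` and list-column
#'   `support_reads`.
#' @export
cluster_signals <- function(signals, params = translocation_params()) {
  empty <- data.frame(kind = character(), chrom = character(),
                      pos = integer(), n_support = integer(),
                      stringsAsFactors = FALSE)
  empty$support_reads <- list()
  if (!nrow(signals)) return(empty)

  # stage 1: cluster signals within each chromosome pair
  clusters <- list()
  for (idx in split(seq_len(nrow(signals)),
                    paste(signals$chrom1, signals$chrom2))) {
    s <- signals[idx, , drop = FALSE]
    s <- s[order(s$pos1, s$pos2, s$read_id), , drop = FALSE]
    cl <- greedy_cluster(s$pos1, s$pos2, params$th_bnd)
    for (k in split(seq_len(nrow(s)), cl)) {
      if (length(k) < params$min_support) next
      m <- s[k, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- list(
        chrom1 = m$chrom1[1], pos1 = stats::median(m$pos1),
        chrom2 = m$chrom2[1], pos2 = stats::median(m$pos2),
        bases1 = sum(m$bases1), bases2 = sum(m$bases2),
        reads = unique(m$read_id)
      )
    }
  }
  if (!length(clusters)) return(empty)

  # stage 2: pool per-side median positions and re-cluster per chromosome
  sides <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(chrom = c(cl$chrom1, cl$chrom2),
               pos = c(cl$pos1, cl$pos2),
               bases = c(cl$bases1, cl$bases2),
               cluster = i, stringsAsFactors = FALSE)
  }))
  bp <- list()
  merged_any <- FALSE
  for (idx in split(seq_len(nrow(sides)), sides$chrom)) {
    sd <- sides[idx, , drop = FALSE]
    sd <- sd[order(sd$pos), , drop = FALSE]
    grp <- greedy_cluster(sd$pos, rep(0, nrow(sd)), params$th_bnd)
    for (k in split(seq_len(nrow(sd)), grp)) {
      cl_ids <- unique(sd$cluster[k])
      kind <- if (length(cl_ids) >= 2) "insertion" else "deletion"
      if (kind == "insertion") merged_any <- TRUE
      reads <- sort(unique(unlist(lapply(clusters[cl_ids], `[[`, "reads"))))
      bp[[length(bp) + 1L]] <- list(
        kind = kind, chrom = sd$chrom[1],
        pos = as.integer(round(stats::median(sd$pos[k]))),
        reads = reads
      )
    }
  }

  # fallback acceptor orientation: no shared side, so use aligned bases
  if (!merged_any) {
    for (i in seq_along(clusters)) {
      cl <- clusters[[i]]
      acc <- if (cl$bases1 >= cl$bases2) cl$chrom1 else cl$chrom2
      for (j in seq_along(bp)) {
        if (bp[[j]]$kind == "deletion" && bp[[j]]$chrom == acc &&
              all(bp[[j]]$reads %in% cl$reads)) {
          bp[[j]]$kind <- "insertion"
        }
      }
    }
  }

  out <- data.frame(
    kind = vapply(bp, `[[`, character(1), "kind"),
    chrom = vapply(bp, `[[`, character(1), "chrom"),
    pos = vapply(bp, `[[`, integer(1), "pos"),
    n_support = vapply(bp, function(b) length(b$reads), integer(1)),
    stringsAsFactors = FALSE
  )
  out$support_reads <- lapply(bp, `[[`, "reads")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mark translocation-supporting reads as enhanced nodes
#'
#' Every read supporting an insertion breakpoint gets that breakpoint's
#' chromosome as its enhanced class: its label set is replaced by that
#' single class and, during path voting, any path containing the read
#' adopts it wholesale. Support reads that were containment-collapsed mark
#' their representative instead.
#'
#' @param alg an `alg` object.
#' @param breakpoints data.frame from [cluster_signals()].
#' @return the updated `alg`.
#' @export
mark_enhanced_nodes <- function(alg, breakpoints) {
  if (!nrow(breakpoints)) return(alg)
  ins <- breakpoints[breakpoints$kind == "insertion", , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    for (rd in ins$support_reads[[i]]) {
      node <- if (rd %in% alg$nodes) rd else unname(alg$contained_in[rd])
      if (is.na(node) || is.null(node) || !node %in% alg$nodes) next
      alg$enhanced[[node]] <- ins$chrom[i]
      alg$labels[[node]] <- ins$chrom[i]
    }
  }
  alg
}

#' Write breakpoints as BEDPE
#'
#' Insertion and deletion breakpoints are emitted as single-position BEDPE
#' features (`chrom, pos-1, pos` on both sides for deletions paired with
#' themselves is meaningless, so each breakpoint becomes one row with its
#' own coordinates duplicated when no partner applies).
#'
#' @param breakpoints data.frame from [cluster_signals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bedpe <- function(breakpoints, path) {
  lines <- character(0)
  if (nrow(breakpoints)) {
    lines <- vapply(seq_len(nrow(breakpoints)), function(i) {
      b <- breakpoints[i, ]
      paste(b$chrom, max(0L, b$pos - 1L), b$pos,
            b$chrom, max(0L, b$pos - 1L), b$pos,
            paste0(b$kind, "_", i), b$n_support, sep = "\t")
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}
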