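#' @name io_formats
#' @title Readers and writers for PAF, GAF, rGFA, FASTA/FASTQ, BED and bins
#' @description All coordinates in these containers are 0-based, half-open,
#'   matching the source formats; 1-based presentation happens only in
#'   messages. Gzipped inputs are read transparently.
NULL

# read all lines of a (possibly gzipped) text file
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

paf_columns <- function() {
  data.frame(
    qname = character(), qlen = integer(), qstart = integer(),
    qend = integer(), strand = character(), tname = character(),
    tlen = integer(), tstart = integer(), tend = integer(),
    matches = integer(), block_len = integer(), mapq = integer(),
    is_primary = logical(), stringsAsFactors = FALSE
  )
}

int_field <- function(x, line, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("PAF line %d: non-integer %s field '%s'",
                 line[bad[1]], what, x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read a PAF alignment file
#'
#' Parses minimap2-style PAF (12 mandatory columns plus optional SAM-like
#' tags). The `tp:A` tag is interpreted: `tp:A:P` (or an absent tag) marks a
#' primary alignment, anything else a secondary/supplementary one. Secondary
#' records are retained and flagged, never dropped at parse time — filtering
#' is the graph builder's policy.
#'
#' @param path path to a PAF file, optionally gzipped.
#' @return a data.frame with one row per record and columns `qname, qlen,
#'   qstart, qend, strand, tname, tlen, tstart, tend, matches, block_len,
#'   mapq, is_primary`. Coordinates are 0-based half-open.
#' @examples
#' tf <- tempfile(fileext = ".paf")
#' writeLines("r1\t100\t0\t100\t+\tchr1\t1000\t0\t100\t100\t100\t60", tf)
#' read_paf(tf)
#' @export
read_paf <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(paf_columns())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 12)) {
    i <- which(ncol < 12)[1]
    stop(sprintf("PAF line %d: expected >= 12 tab-separated columns, got %d",
                 i, ncol[i]), call. = FALSE)
  }
  ln <- seq_along(fields)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(
    qname = col(1),
    qlen = int_field(col(2), ln, "qlen"),
    qstart = int_field(col(3), ln, "qstart"),
    qend = int_field(col(4), ln, "qend"),
    strand = col(5),
    tname = col(6),
    tlen = int_field(col(7), ln, "tlen"),
    tstart = int_field(col(8), ln, "tstart"),
    tend = int_field(col(9), ln, "tend"),
    matches = int_field(col(10), ln, "matches"),
    block_len = int_field(col(11), ln, "block_len"),
    mapq = int_field(col(12), ln, "mapq"),
    stringsAsFactors = FALSE
  )
  # tp:A tag; absent => primary
  out$is_primary <- vapply(fields, function(f) {
    tags <- f[-(1:12)]
    tp <- tags[startsWith(tags, "tp:A:")]
    if (!length(tp)) TRUE else substring(tp[1], 6L) == "P"
  }, logical(1))
  bad_strand <- which(!out$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop(sprintf("PAF line %d: invalid strand '%s'",
                 bad_strand[1], out$strand[bad_strand[1]]), call. = FALSE)
  }
  bad <- which(out$qstart < 0 | out$qstart > out$qend | out$qend > out$qlen |
                 out$tstart < 0 | out$tstart > out$tend | out$tend > out$tlen)
  if (length(bad)) {
    stop(sprintf("PAF line %d: coordinates violate 0 <= start <= end <= length",
                 bad[1]), call. = FALSE)
  }
  bad <- which(out$matches > out$block_len)
  if (length(bad)) {
    stop(sprintf("PAF line %d: matches (%d) exceed block length (%d)",
                 bad[1], out$matches[bad[1]], out$block_len[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Write alignments as PAF
#'
#' Inverse of [read_paf()]: writes the 12 mandatory columns plus a `tp:A`
#' tag encoding primary/secondary status.
#'
#' @param alns data.frame as returned by [read_paf()] or [naive_align()].
#' @param path output path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_paf <- function(alns, path) {
  lines <- if (nrow(alns)) {
    paste(alns$qname, alns$qlen, alns$qstart, alns$qend, alns$strand,
          alns$tname, alns$tlen, alns$tstart, alns$tend, alns$matches,
          alns$block_len, alns$mapq,
          ifelse(alns$is_primary, "tp:A:P", "tp:A:S"),
          sep = "\t")
  } else character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}

#' Read a GAF graph-alignment file
#'
#' Parses minigraph-style GAF. Column 6 (the path) is expanded into a list
#' of oriented segment steps.
#'
#' @param path path to a GAF file, optionally gzipped.
#' @return a data.frame with columns `qname, qlen, qstart, qend, path_start,
#'   path_end, matches` and a list-column `path`, each element a data.frame
#'   with columns `segment` and `orient` (`">"` or `"<"`).
#' @export
read_gaf <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      path_start = integer(), path_end = integer(),
                      matches = integer(), stringsAsFactors = FALSE)
  empty$path <- list()
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 12)) {
    i <- which(ncol < 12)[1]
    stop(sprintf("GAF line %d: expected >= 12 columns, got %d", i, ncol[i]),
         call. = FALSE)
  }
  ln <- seq_along(fields)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  paths <- col(6)
  parsed <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!grepl("^([><][^\t ><]+)+$", p)) {
      stop(sprintf("GAF line %d: unparseable path '%s'", i, p), call. = FALSE)
    }
    m <- regmatches(p, gregexpr("[><][^><]+", p))[[1]]
    data.frame(segment = substring(m, 2L), orient = substring(m, 1L, 1L),
               stringsAsFactors = FALSE)
  })
  out <- data.frame(
    qname = col(1),
    qlen = int_field(col(2), ln, "qlen"),
    qstart = int_field(col(3), ln, "qstart"),
    qend = int_field(col(4), ln, "qend"),
    path_start = int_field(col(8), ln, "path_start"),
    path_end = int_field(col(9), ln, "path_end"),
    matches = int_field(col(10), ln, "matches"),
    stringsAsFactors = FALSE
  )
  out$path <- parsed
  out
}

#' Read an rGFA / GFA1 pangenome graph
#'
#' Keeps segment lengths, the rGFA stable-name (`SN:Z`) and stable-offset
#' (`SO:i`) tags, and the link list. Sequence content is not retained.
#'
#' @param path path to a GFA file, optionally gzipped.
#' @return an object of class `pangenome_graph_raw`: a list with `segments`
#'   (data.frame `segment_id, length, stable_name, stable_offset`) and
#'   `links` (data.frame `from, from_orient, to, to_orient`).
#' @export
read_rgfa <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  seg <- list(); lnk <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3) stop(sprintf("GFA line %d: malformed S-line", i),
                              call. = FALSE)
      tags <- if (length(f) > 3) f[-(1:3)] else character(0)
      getz <- function(prefix) {
        t <- tags[startsWith(tags, prefix)]
        if (length(t)) substring(t[1], nchar(prefix) + 1L) else NA_character_
      }
      len <- if (f[3] != "*") nchar(f[3]) else {
        ln_tag <- getz("LN:i:")
        if (is.na(ln_tag)) stop(
          sprintf("GFA line %d: S-line with '*' sequence needs LN tag", i),
          call. = FALSE)
        as.integer(ln_tag)
      }
      so <- getz("SO:i:")
      seg[[length(seg) + 1L]] <- data.frame(
        segment_id = f[2], length = as.integer(len),
        stable_name = getz("SN:Z:"),
        stable_offset = if (is.na(so)) NA_integer_ else as.integer(so),
        stringsAsFactors = FALSE
      )
    } else if (f[1] == "L") {
      if (length(f) < 5) stop(sprintf("GFA line %d: malformed L-line", i),
                              call. = FALSE)
      lnk[[length(lnk) + 1L]] <- data.frame(
        from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
        stringsAsFactors = FALSE
      )
    }
  }
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(segment_id = character(), length = integer(),
               stable_name = character(), stable_offset = integer(),
               stringsAsFactors = FALSE)
  links <- if (length(lnk)) do.call(rbind, lnk) else
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character(),
               stringsAsFactors = FALSE)
  missing <- setdiff(c(links$from, links$to), segments$segment_id)
  if (length(missing)) {
    stop("GFA L-line references unknown segment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(segments = segments, links = links),
            class = "pangenome_graph_raw")
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path sequence file (`.fa/.fasta/.fq/.fastq`, optionally gzipped).
#' @return a named character vector of sequences (ids are the first token of
#'   each header).
#' @export
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a BED3 file of intervals
#'
#' @param path BED file (0-based half-open), optionally gzipped.
#' @return data.frame with columns `chrom, start, end`.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1),
    start = as.integer(vapply(f, `[[`, character(1), 2)),
    end = as.integer(vapply(f, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start) | is.na(out$end) | out$start < 0 |
            out$start >= out$end)) {
    stop("BED intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  out
}

#' Write per-chromosome read bins
#'
#' Writes one FASTA per class plus an `assignments.tsv` with columns
#' `read_id, class, enhanced_flag`. Every input read lands in exactly one
#' bin; reads missing from `assignments` (or assigned `"None"`/`NA`) go to
#' the `"unassigned"` bin, so the bins always partition the read set.
#'
#' @param assignments data.frame with columns `read_id`, `class` and
#'   optionally `enhanced_flag` (as produced by [bin_reads()]).
#' @param reads named character vector of read sequences.
#' @param outdir output directory, created if needed.
#' @param gzip compress the per-bin FASTA files.
#' @return invisibly, a named character vector mapping class to bin path.
#' @export
write_bins <- function(assignments, reads, outdir, gzip = FALSE) {
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    stop("'reads' must be a named character vector", call. = FALSE)
  }
  if (nrow(assignments)) {
    miss <- setdiff(assignments$read_id, names(reads))
    if (length(miss)) {
      stop("assigned reads missing a sequence: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  cls <- stats::setNames(rep("unassigned", length(reads)), names(reads))
  if (nrow(assignments)) {
    a_cls <- assignments$class
    a_cls[is.na(a_cls) | a_cls == "None"] <- "unassigned"
    cls[assignments$read_id] <- a_cls
  }
  enh <- stats::setNames(rep(FALSE, length(reads)), names(reads))
  if (nrow(assignments) && "enhanced_flag" %in% names(assignments)) {
    enh[assignments$read_id] <- assignments$enhanced_flag %in% TRUE
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fa.gz" else ".fa"
  paths <- character(0)
  for (cl in sort(unique(cls))) {
    ids <- names(cls)[cls == cl]
    p <- file.path(outdir, paste0(cl, ext))
    write_fasta(reads[ids], p)
    paths[cl] <- p
  }
  tsv <- data.frame(read_id = names(cls), class = unname(cls),
                    enhanced_flag = unname(enh), stringsAsFactors = FALSE)
  tsv <- tsv[order(tsv$read_id), , drop = FALSE]
  utils::write.table(tsv, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
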