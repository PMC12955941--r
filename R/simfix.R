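#' @name simfix
#' @title Synthetic genomes, reads and a naive alignment oracle
#' @description Generates small multi-chromosome genomes (optionally with an
#'   inter-chromosomal shared repeat family and a planted translocation),
#'   samples long reads with known chromosome-of-origin, and aligns them
#'   with an exact-k-mer seed-and-extend aligner — so the whole binning
#'   pipeline is exercised without external binaries. The aligner assumes
#'   substitution-only, low-error sequences; real data goes through
#'   minimap2/minigraph.
NULL

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# substitute bases at the given 1-based positions with a different base
mutate_positions <- function(seq, pos) {
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  alphabet <- c("A", "C", "G", "T")
  for (p in pos) {
    ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a multi-chromosome genome with a shared repeat family
#'
#' Chromosomes are independent random sequences. When a repeat family is
#' requested, one master repeat sequence is planted `n_repeat_copies`
#' times per chromosome at non-overlapping random positions (overwriting
#' the background, so chromosome lengths are unchanged). Each planted copy
#' diverges from the master by `repeat_divergence` substitutions — repeat
#' family members in real genomes are never identical copies, and that
#' slight divergence is what makes reads from a copy attributable to their
#' chromosome at all.
#'
#' @param n_chrom number of chromosomes (named `chr1..chrN`).
#' @param chrom_len chromosome length (bp).
#' @param shared_repeat_len repeat unit length (bp); 0 disables repeats.
#' @param n_repeat_copies copies planted per chromosome.
#' @param seed RNG seed; the genome is a pure function of the arguments.
#' @param repeat_divergence per-base substitution rate of each planted copy
#'   relative to the master repeat.
#' @return an object of class `synthetic_genome`: list with `chromosomes`
#'   (named character), `truth_translocations` (data.frame, empty here) and
#'   `repeat_annotations` (data.frame `chrom, start, end, family_id`,
#'   0-based half-open).
#' @export
simulate_genome <- function(n_chrom = 3, chrom_len = 200000,
                            shared_repeat_len = 0, n_repeat_copies = 0,
                            seed = 1, repeat_divergence = 0.01) {
  stopifnot(shared_repeat_len < chrom_len)
  with_rng(seed, {
    chroms <- stats::setNames(
      vapply(seq_len(n_chrom), function(i) random_dna(chrom_len),
             character(1)),
      paste0("chr", seq_len(n_chrom))
    )
    ann <- data.frame(chrom = character(), start = integer(),
                      end = integer(), family_id = character(),
                      stringsAsFactors = FALSE)
    if (shared_repeat_len > 0 && n_repeat_copies > 0) {
      master <- random_dna(shared_repeat_len)
      for (cn in names(chroms)) {
        taken <- integer(0)
        for (j in seq_len(n_repeat_copies)) {
          # rejection-sample a start that stays clear of previous copies
          for (try in 1:1000) {
            st <- sample.int(chrom_len - shared_repeat_len + 1L, 1L) - 1L
            if (!length(taken) ||
                  all(abs(st - taken) >= shared_repeat_len + 1000L)) break
          }
          taken <- c(taken, st)
          n_mut <- stats::rbinom(1L, shared_repeat_len, repeat_divergence)
          pos <- if (n_mut) sort(sample.int(shared_repeat_len, n_mut)) else
            integer(0)
          copy <- mutate_positions(master, pos)
          chroms[cn] <- paste0(
            substr(chroms[cn], 1L, st),
            copy,
            substr(chroms[cn], st + shared_repeat_len + 1L,
                   nchar(chroms[cn]))
          )
          ann <- rbind(ann, data.frame(
            chrom = cn, start = st, end = st + shared_repeat_len,
            family_id = "rpt1", stringsAsFactors = FALSE))
        }
      }
    }
    structure(list(chromosomes = chroms,
                   truth_translocations = data.frame(
                     donor_chrom = character(), donor_start = integer(),
                     donor_end = integer(), acceptor_chrom = character(),
                     acceptor_pos = integer(), stringsAsFactors = FALSE),
                   repeat_annotations = ann),
              class = "synthetic_genome")
  })
}

#' Plant an inter-chromosomal translocation
#'
#' Excises `[donor_start, donor_end)` from the donor chromosome and inserts
#' it at `acceptor_pos` of the acceptor (coordinates refer to the sequences
#' as passed in). The operation is deterministic. The truth table gains one
#' row recording the three junction coordinates implied by the event: the
#' two donor-side deletion breakpoints (`donor_start`, `donor_end`) and the
#' acceptor-side insertion breakpoint (`acceptor_pos`).
#'
#' @param genome a `synthetic_genome`.
#' @param donor,acceptor chromosome names; must differ.
#' @param donor_start,donor_end 0-based half-open excised interval.
#' @param acceptor_pos 0-based insertion point on the acceptor.
#' @return the modified `synthetic_genome`.
#' @export
plant_translocation <- function(genome, donor, donor_start, donor_end,
                                acceptor, acceptor_pos) {
  if (donor == acceptor) {
    stop("donor and acceptor chromosomes must differ", call. = FALSE)
  }
  dlen <- nchar(genome$chromosomes[[donor]])
  alen <- nchar(genome$chromosomes[[acceptor]])
  stopifnot(donor_start >= 0, donor_start < donor_end, donor_end <= dlen,
            acceptor_pos >= 0, acceptor_pos <= alen)
  tt <- genome$truth_translocations
  if (nrow(tt)) {
    clash <- any(
      (tt$donor_chrom == donor &
         pmax(tt$donor_start, donor_start) < pmin(tt$donor_end, donor_end)) |
        (tt$acceptor_chrom == donor) | (tt$donor_chrom == acceptor)
    )
    if (clash) stop("translocation overlaps a previously planted event",
                    call. = FALSE)
  }
  seg <- substr(genome$chromosomes[[donor]], donor_start + 1L, donor_end)
  genome$chromosomes[[donor]] <- paste0(
    substr(genome$chromosomes[[donor]], 1L, donor_start),
    substr(genome$chromosomes[[donor]], donor_end + 1L, dlen)
  )
  genome$chromosomes[[acceptor]] <- paste0(
    substr(genome$chromosomes[[acceptor]], 1L, acceptor_pos),
    seg,
    substr(genome$chromosomes[[acceptor]], acceptor_pos + 1L, alen)
  )
  genome$truth_translocations <- rbind(tt, data.frame(
    donor_chrom = donor, donor_start = donor_start, donor_end = donor_end,
    acceptor_chrom = acceptor, acceptor_pos = acceptor_pos,
    stringsAsFactors = FALSE))
  genome
}

#' Sample long reads with known origin
#'
#' Reads are sampled uniformly along every chromosome to the target
#' coverage. Lengths are truncated-normal; about half the reads are
#' reverse-complemented; substitutions are i.i.d. per base. The returned
#' truth labels name the chromosome and 0-based start the read was drawn
#' from in the supplied genome (for a rearranged genome that is the
#' rearranged coordinate system).
#'
#' @param genome a `synthetic_genome`.
#' @param coverage target sequencing depth (x).
#' @param mean_len,len_sd read-length distribution (bp).
#' @param subst_rate per-base substitution rate in `[0, 1)`.
#' @param seed RNG seed.
#' @return a data.frame of class `simulated_reads` with columns `read_id,
#'   sequence, length, truth_chrom, truth_start, strand`.
#' @export
simulate_reads <- function(genome, coverage = 5, mean_len = 10000,
                           len_sd = 1000, subst_rate = 0, seed = 1) {
  stopifnot(subst_rate >= 0, subst_rate < 1)
  with_rng(seed, {
    rows <- list()
    counter <- 0L
    for (cn in names(genome$chromosomes)) {
      clen <- nchar(genome$chromosomes[[cn]])
      n <- max(1L, as.integer(round(coverage * clen / mean_len)))
      lens <- pmin(clen, pmax(200L, as.integer(round(
        stats::rnorm(n, mean_len, len_sd)))))
      starts <- vapply(lens, function(L) {
        sample.int(clen - L + 1L, 1L) - 1L
      }, integer(1))
      strands <- sample(c("+", "-"), n, replace = TRUE)
      for (i in seq_len(n)) {
        counter <- counter + 1L
        sq <- substr(genome$chromosomes[[cn]], starts[i] + 1L,
                     starts[i] + lens[i])
        if (subst_rate > 0) {
          n_mut <- stats::rbinom(1L, lens[i], subst_rate)
          if (n_mut) {
            sq <- mutate_positions(sq, sort(sample.int(lens[i], n_mut)))
          }
        }
        if (strands[i] == "-") sq <- revcomp(sq)
        rows[[counter]] <- data.frame(
          read_id = sprintf("read%05d", counter), sequence = sq,
          length = lens[i], truth_chrom = cn, truth_start = starts[i],
          strand = strands[i], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("simulated_reads", class(out))
    out
  })
}

# exact k-mer index over a set of named sequences: data.table(kmer, target,
# tpos) keyed by kmer, tpos 1-based
kmer_index <- function(seqs, k) {
  parts <- lapply(names(seqs), function(nm) {
    L <- nchar(seqs[[nm]])
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table::data.table(
      kmer = substring(seqs[[nm]], starts, starts + k - 1L),
      target = nm, tpos = starts)
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt)) data.table::setkey(dt, kmer)
  dt
}

# seed positions for one query: a regular stride plus the final k-mer
seed_positions <- function(L, k, stride) {
  if (L < k) return(integer(0))
  unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
}

#' Exact-match seed-and-extend aligner
#'
#' A deliberately simple alignment oracle for synthetic data: exact
#' `k`-mer seeds on both strands are chained by diagonal (substitutions do
#' not shift the diagonal, and the simulator introduces no indels), each
#' chain is extended outward while the bases match exactly, and mismatches
#' inside the chained span are counted toward the PAF `matches` field.
#' Reads from a shared repeat produce secondary records on every homologous
#' copy; reads spanning a rearrangement junction split into separate
#' records per side. In all-vs-all mode self-pairs are skipped.
#'
#' @param reads a `simulated_reads` data.frame or named character vector of
#'   query sequences.
#' @param target a `synthetic_genome`, a named character vector of target
#'   sequences, or `NULL` for all-vs-all alignment of `reads` against
#'   themselves.
#' @param k seed k-mer length.
#' @param stride distance (bp) between query seed positions.
#' @param min_chain_bp drop chains whose extended block is shorter than
#'   this (suppresses incidental shared k-mers).
#' @return a PAF-style data.frame with the [read_paf()] columns. Per query
#'   the record with the most matches is primary (`mapq` 60), all others
#'   secondary (`mapq` 0).
#' @export
naive_align <- function(reads, target = NULL, k = 21, stride = 50,
                        min_chain_bp = 100) {
  qseqs <- if (is.data.frame(reads)) {
    stats::setNames(reads$sequence, reads$read_id)
  } else reads
  tseqs <- if (is.null(target)) {
    qseqs
  } else if (inherits(target, "synthetic_genome")) {
    target$chromosomes
  } else if (is.data.frame(target)) {
    stats::setNames(target$sequence, target$read_id)
  } else target
  ava <- is.null(target)

  idx <- kmer_index(tseqs, k)
  if (!nrow(idx)) return(paf_columns())

  qnames <- names(qseqs)
  qlens <- stats::setNames(nchar(qseqs), qnames)
  rcseqs <- stats::setNames(vapply(qseqs, revcomp, character(1)), qnames)

  qparts <- lapply(qnames, function(nm) {
    pos <- seed_positions(qlens[[nm]], k, stride)
    if (!length(pos)) return(NULL)
    data.table::rbindlist(list(
      data.table::data.table(
        qname = nm, strand = "+", qpos = pos,
        kmer = substring(qseqs[[nm]], pos, pos + k - 1L)),
      data.table::data.table(
        qname = nm, strand = "-", qpos = pos,
        kmer = substring(rcseqs[[nm]], pos, pos + k - 1L))
    ))
  })
  qdt <- data.table::rbindlist(qparts)
  if (!nrow(qdt)) return(paf_columns())

  hits <- idx[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (ava) hits <- hits[qname != target]
  if (!nrow(hits)) return(paf_columns())
  hits[, diag_id := tpos - qpos]
  chains <- hits[, .(qs = min(qpos), qe = max(qpos) + k - 1L,
                     ts = min(tpos), te = max(tpos) + k - 1L,
                     nseed = .N),
                 by = .(qname, target, strand, diag_id)]

  traw <- lapply(tseqs, charToRaw)
  qraw_fwd <- lapply(qseqs, charToRaw)
  qraw_rev <- lapply(rcseqs, charToRaw)

  n <- nrow(chains)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    qn <- chains$qname[i]; tn <- chains$target[i]
    qr <- if (chains$strand[i] == "+") qraw_fwd[[qn]] else qraw_rev[[qn]]
    tr <- traw[[tn]]
    qs <- chains$qs[i]; qe <- chains$qe[i]
    ts <- chains$ts[i]; te <- chains$te[i]
    while (qs > 1L && ts > 1L && qr[qs - 1L] == tr[ts - 1L]) {
      qs <- qs - 1L; ts <- ts - 1L
    }
    qmax <- length(qr); tmax <- length(tr)
    while (qe < qmax && te < tmax && qr[qe + 1L] == tr[te + 1L]) {
      qe <- qe + 1L; te <- te + 1L
    }
    blk <- qe - qs + 1L
    if (blk < min_chain_bp) next
    mism <- sum(qr[qs:qe] != tr[ts:te])
    qlen <- qlens[[qn]]
    if (chains$strand[i] == "+") {
      q0s <- qs - 1L; q0e <- qe
    } else {
      q0s <- qlen - qe; q0e <- qlen - qs + 1L
    }
    rows[[i]] <- data.frame(
      qname = qn, qlen = qlen, qstart = q0s, qend = q0e,
      strand = chains$strand[i], tname = tn,
      tlen = length(tr), tstart = ts - 1L, tend = te,
      matches = blk - mism, block_len = blk,
      mapq = 0L, is_primary = FALSE, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(paf_columns())
  out <- do.call(rbind, rows)

  # collapse duplicate chains that extended to the same block
  key <- paste(out$qname, out$tname, out$strand, out$qstart, out$qend,
               out$tstart, out$tend)
  out <- out[!duplicated(key), , drop = FALSE]

  # primary = most matches per query (ties by target then coordinates)
  out <- out[order(out$qname, -out$matches, out$tname, out$tstart), ,
             drop = FALSE]
  out$is_primary <- !duplicated(out$qname)
  out$mapq <- ifelse(out$is_primary, 60L, 0L)
  rownames(out) <- NULL
  out
}
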