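#' Precision / recall / F1 from raw counts
#'
#' Direct arithmetic on a confusion triple:
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). A denominator of
#' zero yields `NA` for the affected rate (an undefined flag rather than a
#' silent 0); F1 is 0 when precision + recall is 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return an object of class `eval_report`: list with `tp, fp, fn,
#'   precision, recall, f1`.
#' @examples
#' eval_report(9, 1, 3) # precision 0.9, recall 0.75, F1 ~ 0.818
#' @export
eval_report <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall)) {
    if (precision + recall > 0) 2 * precision * recall / (precision + recall)
    else 0
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  precision=%.4f recall=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# fraction of each interval in `a` covered by the union of intervals in `b`
# (same chromosome only); both data.frames chrom/start/end, 0-based half-open
covered_fraction <- function(a, b) {
  out <- numeric(nrow(a))
  if (!nrow(a)) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    qr <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    if (!length(bi)) { out[ai] <- 0; next }
    tr <- IRanges::reduce(IRanges::IRanges(start = b$start[bi] + 1L,
                                           end = b$end[bi]))
    ov <- IRanges::findOverlaps(qr, tr)
    inter <- IRanges::pintersect(qr[S4Vectors::queryHits(ov)],
                                 tr[S4Vectors::subjectHits(ov)])
    cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    res <- numeric(length(ai))
    res[as.integer(names(cov))] <- as.numeric(cov)
    out[ai] <- res / IRanges::width(qr)
  }
  out
}

#' Interval-set consistency (bubble-region evaluation)
#'
#' Compares two BED-style interval sets. A query interval is a true
#' positive when the fraction of its length covered by the union of truth
#' intervals on the same chromosome strictly exceeds `min_overlap_frac`,
#' otherwise a false positive. A truth interval whose covered fraction by
#' the query union does not exceed the threshold is a false negative.
#' Precision is the query-side TP rate; recall is measured truth-side (the
#' fraction of truth intervals recovered), which makes the metric exactly
#' symmetric: swapping query and truth exchanges precision and recall.
#' Coverage is by the union of overlapping intervals, so several query
#' intervals may jointly satisfy one truth interval.
#'
#' @param query,truth data.frames with columns `chrom, start, end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param min_overlap_frac strict coverage threshold in `[0, 1]`.
#' @return an `eval_report` whose `tp`/`fp` count query intervals and `fn`
#'   counts truth intervals; `recall` equals
#'   `(n_truth - fn) / n_truth`.
#' @export
bubble_consistency <- function(query, truth, min_overlap_frac = 0.8) {
  stopifnot(min_overlap_frac >= 0, min_overlap_frac <= 1)
  qcov <- covered_fraction(query, truth)
  tcov <- covered_fraction(truth, query)
  tp <- sum(qcov > min_overlap_frac)
  fp <- nrow(query) - tp
  fn <- sum(!(tcov > min_overlap_frac))
  tp_truth <- nrow(truth) - fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp_truth + fn > 0) tp_truth / (tp_truth + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall)) {
    if (precision + recall > 0) 2 * precision * recall / (precision + recall)
    else 0
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_report")
}

#' Binning accuracy against truth labels
#'
#' Accuracy is computed over classified reads only (final class not
#' `"unassigned"`/`"None"`); the unassigned fraction is reported
#' separately, since leaving a read unbinned and misbinning it are
#' different failure modes.
#'
#' @param assignments data.frame with columns `read_id`, `class` (from
#'   [bin_reads()] or a read `assignments.tsv`).
#' @param truth_labels named character vector mapping read_id to the true
#'   chromosome; must cover every assigned read.
#' @return list with `accuracy` (`NA` when nothing is classified),
#'   `none_fraction`, `n_classified`, `n_reads` and `confusion` (a
#'   truth-by-assigned contingency table over classified reads).
#' @export
binning_accuracy <- function(assignments, truth_labels) {
  miss <- setdiff(assignments$read_id, names(truth_labels))
  if (length(miss)) {
    stop("reads missing from truth: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  cls <- assignments$class
  classified <- !(is.na(cls) | cls %in% c("None", "unassigned"))
  truth <- truth_labels[assignments$read_id]
  acc <- if (any(classified)) {
    mean(cls[classified] == truth[classified])
  } else NA_real_
  confusion <- if (any(classified)) {
    table(truth = truth[classified], assigned = cls[classified])
  } else table(truth = character(0), assigned = character(0))
  list(accuracy = acc,
       none_fraction = mean(!classified),
       n_classified = sum(classified),
       n_reads = nrow(assignments),
       confusion = confusion)
}
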