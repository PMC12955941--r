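#' Pipeline configuration
#'
#' @param reads path to the read sequences (FASTA/FASTQ, optionally
#'   gzipped).
#' @param ref_paf path to read-vs-reference alignments (PAF).
#' @param ava_paf path to all-vs-all read alignments (PAF).
#' @param out_dir output directory.
#' @param gfa,gaf optional pangenome graph (rGFA) and read-vs-graph
#'   alignments (GAF); supplying both activates PLG harmonization of
#'   unclassified reads.
#' @param overlap an [overlap_params()] object.
#' @param correction a [correction_params()] object.
#' @param transloc a [translocation_params()] object.
#' @param assembler_cmd optional external assembler command template with
#'   placeholders `{bin_fasta}` and `{out_dir}`; invoked once per bin. When
#'   absent no external process is ever spawned.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, ref_paf, ava_paf, out_dir,
                            gfa = NULL, gaf = NULL,
                            overlap = overlap_params(),
                            correction = correction_params(),
                            transloc = translocation_params(),
                            assembler_cmd = NULL) {
  structure(list(reads = reads, ref_paf = ref_paf, ava_paf = ava_paf,
                 out_dir = out_dir, gfa = gfa, gaf = gaf,
                 overlap = overlap, correction = correction,
                 transloc = transloc, assembler_cmd = assembler_cmd),
            class = "pipeline_config")
}

#' Run the chromosome-binning pipeline
#'
#' Stages, in order: parse inputs; initial classes from reference
#' alignments; optional pangenome-graph harmonization of unclassified
#' reads; ALG construction with containment collapse; translocation signal
#' extraction, clustering and enhanced-node marking (before correction, so
#' the overrides are visible during path voting); randomized class
#' correction; binning and output. Outputs written to `out_dir`: per-class
#' FASTA bins, `assignments.tsv`, `breakpoints.bedpe`, `enhanced_reads.tsv`,
#' ALG debug TSVs and a JSON `report.json` echoing parameters, per-stage
#' counts and timings.
#'
#' @param config a [pipeline_config()] object.
#' @return invisibly, a list of class `pipeline_result` with elements
#'   `report`, `assignments`, `state`, `alg`, `breakpoints` and `classes`.
#' @export
run_pipeline <- function(config) {
  inputs <- c(config$reads, config$ref_paf, config$ava_paf,
              config$gfa, config$gaf)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) timings[[name]] <<- round(tic() - t0, 3)

  t0 <- tic()
  reads <- read_seqs(config$reads)
  ref <- read_paf(config$ref_paf)
  ava <- read_paf(config$ava_paf)
  stage("parse", t0)

  t0 <- tic()
  classes <- initial_classes(ref, read_ids = names(reads),
                             min_block_len = config$overlap$min_block_len)
  none_before <- mean(vapply(classes, identical, logical(1), y = "None"))
  if (!is.null(config$gfa) && !is.null(config$gaf)) {
    plg <- build_plg(read_rgfa(config$gfa))
    classes <- assign_unclassified(plg, read_gaf(config$gaf), classes)
  }
  stage("classes", t0)

  t0 <- tic()
  alg <- build_alg(ava, classes, config$overlap)
  stage("alg", t0)

  t0 <- tic()
  signals <- extract_split_signals(ref, config$transloc)
  breakpoints <- cluster_signals(signals, config$transloc)
  alg <- mark_enhanced_nodes(alg, breakpoints)
  stage("translocation", t0)

  t0 <- tic()
  state <- correct_classes(alg, config$correction)
  assignments <- bin_reads(state, alg$contained_in, alg$enhanced)
  stage("correction", t0)

  t0 <- tic()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bin_paths <- write_bins(assignments, reads, config$out_dir)
  write_breakpoints_bedpe(breakpoints,
                          file.path(config$out_dir, "breakpoints.bedpe"))
  enh <- alg$enhanced[!is.na(alg$enhanced)]
  utils::write.table(
    data.frame(read_id = names(enh), class = unname(enh),
               stringsAsFactors = FALSE),
    file.path(config$out_dir, "enhanced_reads.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_alg(alg, config$out_dir)
  stage("write", t0)

  assembler_log <- list()
  if (!is.null(config$assembler_cmd)) {
    t0 <- tic()
    for (cl in names(bin_paths)) {
      cmd <- gsub("{bin_fasta}", bin_paths[[cl]], config$assembler_cmd,
                  fixed = TRUE)
      cmd <- gsub("{out_dir}", config$out_dir, cmd, fixed = TRUE)
      status <- tryCatch(system(cmd), error = function(e) -1L)
      assembler_log[[cl]] <- list(command = cmd, status = status)
      if (!identical(status, 0L)) {
        warning("assembler failed for bin ", cl, " (exit ", status, ")",
                call. = FALSE)
      }
    }
    stage("assembly", t0)
  }

  n_total <- length(reads)
  n_unassigned <- sum(assignments$class == "unassigned")
  bin_sizes <- table(assignments$class)
  report <- list(
    n_reads = n_total,
    n_classified = n_total - n_unassigned,
    n_unassigned = n_unassigned,
    none_fraction_before = round(none_before, 6),
    none_fraction_after = round(n_unassigned / n_total, 6),
    n_alg_nodes = length(alg$nodes),
    n_alg_edge_pairs = nrow(alg$edges) / 2L,
    n_contained = length(alg$contained_in),
    n_breakpoints = nrow(breakpoints),
    n_enhanced = sum(!is.na(alg$enhanced)),
    bins = as.list(bin_sizes),
    parameters = list(overlap = unclass(config$overlap),
                      correction = unclass(config$correction),
                      translocation = unclass(config$transloc)),
    seed = config$correction$seed,
    timings_sec = as.list(timings),
    assembler = assembler_log
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(list(report = report, assignments = assignments,
                           state = state, alg = alg,
                           breakpoints = breakpoints, classes = classes),
                      class = "pipeline_result"))
}

#' Merge per-bin assemblies into one FASTA
#'
#' Concatenates the contigs of every bin assembly, rewriting each contig id
#' to `<bin>#<original_id>` so ids colliding across bins stay unique. Empty
#' or absent bin files are skipped with a warning.
#'
#' @param bin_fasta_paths character vector of per-bin FASTA paths; names
#'   (or file basenames) provide the bin prefix.
#' @param out_path merged FASTA output path.
#' @return `out_path`, invisibly.
#' @export
merge_contigs <- function(bin_fasta_paths, out_path) {
  prefixes <- names(bin_fasta_paths)
  if (is.null(prefixes)) {
    prefixes <- sub("\\.(fa|fasta)(\\.gz)?$", "",
                    basename(bin_fasta_paths))
  }
  merged <- character(0)
  for (i in seq_along(bin_fasta_paths)) {
    p <- bin_fasta_paths[i]
    if (!file.exists(p) || file.size(p) == 0) {
      warning("skipping empty bin file: ", p, call. = FALSE)
      next
    }
    seqs <- tryCatch(read_seqs(p), error = function(e) character(0))
    if (!length(seqs)) {
      warning("skipping empty bin file: ", p, call. = FALSE)
      next
    }
    names(seqs) <- paste0(prefixes[i], "#", names(seqs))
    merged <- c(merged, seqs)
  }
  if (anyDuplicated(names(merged))) {
    stop("duplicate contig ids after prefixing: ",
         paste(unique(names(merged)[duplicated(names(merged))]),
               collapse = ", "), call. = FALSE)
  }
  write_fasta(merged, out_path)
  invisible(out_path)
}
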