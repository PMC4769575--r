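# End-to-end detection pipeline and its configuration.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with validated defaults.
#' Fields are grouped by stage: QC (`low_quality_threshold`,
#' `max_low_fraction`), classification (`min_element_match`, `min_identity`,
#' `min_genomic_tail`, `full_match_slack`, `terminal_seed_k`), assembly
#' (`assembly_k`, `min_kmer_count`), mapping/clustering (`genome_k`,
#' `map_min_identity`, `map_min_len`, `window`, `hc_min_support`), zygosity
#' (`min_span`, `max_mismatch`, `max_fragment`), alignment scoring (`match`,
#' `mismatch`, `gap`) and `seed`.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    low_quality_threshold = 20L, max_low_fraction = 0.5,
    min_element_match = 15L, min_identity = 0.9, min_genomic_tail = 20L,
    full_match_slack = 3L, terminal_seed_k = 11L,
    assembly_k = 21L, min_kmer_count = 2L,
    genome_k = 13L, map_min_identity = 0.95, map_min_len = 20L,
    window = 600L, hc_min_support = 3L,
    min_span = 3L, max_mismatch = 6L, max_fragment = 2000L,
    match = 1L, mismatch = -2L, gap = -3L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  int_fields <- c("low_quality_threshold", "min_element_match",
                  "min_genomic_tail", "full_match_slack", "terminal_seed_k",
                  "assembly_k", "min_kmer_count", "genome_k", "map_min_len",
                  "window", "hc_min_support", "min_span", "max_mismatch",
                  "max_fragment", "match", "mismatch", "gap", "seed")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  stopifnot(cfg$max_low_fraction >= 0, cfg$max_low_fraction <= 1,
            cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$map_min_identity > 0, cfg$map_min_identity <= 1,
            cfg$assembly_k %% 2L == 1L, cfg$assembly_k >= 15L,
            cfg$assembly_k <= 31L,
            cfg$genome_k >= 8L, cfg$terminal_seed_k >= 8L,
            cfg$window >= 0L, cfg$hc_min_support >= 1L, cfg$min_span >= 1L,
            cfg$match > 0L, cfg$mismatch < 0L, cfg$gap < 0L)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Write/read a pipeline configuration as key=value text
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` invisibly / a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=",
                    vapply(config, format, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(pipeline_config, stats::setNames(vals, trimws(sapply(kv, `[[`, 1))))
}

as_genome_tibble <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    read_fasta(genome)
  } else if (is.data.frame(genome)) {
    genome
  } else if (is.character(genome) && !is.null(names(genome))) {
    tibble::tibble(name = names(genome), sequence = unname(genome))
  } else stop("genome must be a FASTA path, a name/sequence tibble, or a named character vector")
}

#' Run the full insertion-detection pipeline
#'
#' QC-filters the pairs, classifies them into the five pair types, extracts
#' hybrid junction reads, assembles rescue reads into nodes, maps all
#' evidence to the reference, clusters it into loci, assigns confidence,
#' numbers loci, and estimates zygosity from the type 2 pairs. The run is a
#' deterministic function of its inputs and configuration.
#'
#' @param pairs A pair tibble ([pair_reads()]), or a length-2 character
#'   vector of FASTQ paths (mate 1, mate 2).
#' @param genome Reference genome: FASTA path, tibble, or named character
#'   vector.
#' @param element Transposon element: a `transposon_ref` or FASTA path.
#' @param config A [pipeline_config()].
#' @return An object of class `tnt_detect`: a list with `loci` (the
#'   insertion table), `type_counts`, `qc`, `map_report`, `config` and run
#'   metadata. See [tidy.tnt_detect()], [glance.tnt_detect()],
#'   [autoplot.tnt_detect()].
#' @export
detect_insertions <- function(pairs, genome, element,
                              config = pipeline_config()) {
  if (is.character(pairs)) {
    stopifnot(length(pairs) == 2L)
    pairs <- pair_reads(read_fastq(pairs[1], mate = 1L),
                        read_fastq(pairs[2], mate = 2L))
  }
  if (!inherits(element, "transposon_ref")) element <- load_transposon(element)
  genome <- as_genome_tibble(genome)
  scoring <- alignment_scoring(config$match, config$mismatch, config$gap)
  cls_params <- classify_params(config$min_element_match, config$min_identity,
                                config$min_genomic_tail,
                                config$full_match_slack,
                                config$terminal_seed_k)

  n_in <- nrow(pairs)
  kept <- qc_filter_pairs(pairs, config$low_quality_threshold,
                          config$max_low_fraction)
  qc <- qc_report(kept)
  message("QC: ", qc$pairs_kept, "/", qc$pairs_in, " pairs kept")

  classified <- classify_pairs(kept, element, cls_params, scoring)
  counts <- pair_type_counts(classified)
  message("pair types: ",
          paste(sprintf("T%d=%d", counts$type, counts$n), collapse = " "))

  genome_index <- build_kmer_index(genome, k = config$genome_k)
  hybrids <- extract_hybrids(classified) |>
    drop_reference_hybrids(genome_index, max_mismatch = config$max_mismatch)
  rescue <- collect_rescue_reads(classified)
  nodes <- assemble_rescue_nodes(rescue, k = config$assembly_k,
                                 min_kmer_count = config$min_kmer_count)
  message(nrow(hybrids), " hybrid read(s) (",
          attr(hybrids, "n_reference_matching"),
          " reference-matching dropped), ", nrow(rescue),
          " rescue read(s) -> ", nrow(nodes), " node(s)")
  evidence <- map_evidence(hybrids, nodes, genome_index,
                           min_identity = config$map_min_identity,
                           min_mapped_len = config$map_min_len,
                           scoring = scoring)
  mrep <- map_report(evidence)
  message("evidence mapped: ", mrep$n_mapped, "/", mrep$n_evidence,
          " (", mrep$n_multimapped, " multi-mapping discarded)")

  loci <- cluster_evidence(evidence, window = config$window) |>
    assign_confidence(hc_min_support = config$hc_min_support) |>
    number_loci(chrom_order = genome$name)

  type2 <- classified[classified$type == 2L, , drop = FALSE]
  placed <- place_read_pairs(type2, genome_index,
                             max_mismatch = config$max_mismatch,
                             max_fragment = config$max_fragment)
  loci <- estimate_zygosity(loci, placed, min_span = config$min_span,
                            hc_min_support = config$hc_min_support)
  message(nrow(loci), " loci (", sum(loci$confidence == "HC"), " HC)")

  structure(list(
    loci = loci,
    type_counts = counts,
    qc = qc,
    map_report = mrep,
    n_pairs_in = n_in,
    n_hybrids = nrow(hybrids),
    n_rescue_reads = nrow(rescue),
    n_nodes = nrow(nodes),
    n_placed_type2 = nrow(placed),
    chrom_order = genome$name,
    config = config), class = "tnt_detect")
}

locus_table_columns <- c("insertion_id", "chrom", "position", "confidence",
                         "support_total", "support_hybrid_LE",
                         "support_hybrid_RE", "support_node", "zygosity",
                         "spanning_pairs")

#' Write pipeline outputs to a directory
#'
#' Writes `insertions.tsv` (the locus table), `insertions.bed` (BED6),
#' `classification_summary.tsv` (pair-type counts), `qc_report.tsv`,
#' `map_report.tsv` and `config.txt`. Output bytes are a pure function of
#' the result object, so identical runs give identical files.
#'
#' @param result A `tnt_detect` object.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing outputs (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_detect_outputs <- function(result, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("insertions.tsv", "insertions.bed",
                            "classification_summary.tsv", "qc_report.tsv",
                            "map_report.tsv", "config.txt"))
  if (!force && any(file.exists(paths))) {
    stop("output files already exist in '", dir, "' (use force = TRUE)")
  }
  tab <- as.data.frame(result$loci[locus_table_columns])
  write.table(tab, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(result$loci, paths[2])
  write.table(as.data.frame(result$type_counts), paths[3], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$qc), paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(result$map_report), paths[5], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_config(result$config, paths[6])
  invisible(dir)
}

#' @export
print.tnt_detect <- function(x, ...) {
  cat("<tnt_detect> ", x$qc$pairs_kept, " pairs analysed; ",
      nrow(x$loci), " insertion loci (",
      sum(x$loci$confidence == "HC"), " HC, ",
      sum(x$loci$confidence == "LC"), " LC)\n", sep = "")
  print(x$loci[locus_table_columns], n = 10)
  invisible(x)
}

#' Tidy the insertion loci of a detection run
#'
#' @param x A `tnt_detect` object.
#' @param ... Unused.
#' @return The locus tibble (one row per insertion locus).
#' @export
tidy.tnt_detect <- function(x, ...) x$loci[locus_table_columns]

#' One-row summary of a detection run
#'
#' @param x A `tnt_detect` object.
#' @param ... Unused.
#' @return A one-row tibble with pair, evidence and locus counts.
#' @export
glance.tnt_detect <- function(x, ...) {
  tc <- stats::setNames(x$type_counts$n, paste0("type", x$type_counts$type))
  tibble::tibble(
    pairs_in = x$qc$pairs_in, pairs_kept = x$qc$pairs_kept,
    !!!tc,
    n_hybrids = x$n_hybrids, n_nodes = x$n_nodes,
    evidence_mapped = x$map_report$n_mapped,
    evidence_multimapped = x$map_report$n_multimapped,
    n_loci = nrow(x$loci),
    n_hc = sum(x$loci$confidence == "HC"),
    n_lc = sum(x$loci$confidence == "LC"))
}

#' Plot insertion loci along the reference
#'
#' Support totals by position, coloured by confidence tier and shaped by
#' zygosity, one panel per reference sequence.
#'
#' @param object A `tnt_detect` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnt_detect <- function(object, ...) {
  df <- object$loci
  df$chrom <- factor(df$chrom, levels = object$chrom_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1e3,
                                   y = .data$support_total,
                                   colour = .data$confidence,
                                   shape = .data$zygosity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position / 1e3, yend = 0),
                          linewidth = 0.3, show.legend = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (kb)", y = "supporting reads/nodes",
                  colour = "confidence", shape = "zygosity") +
    ggplot2::theme_bw()
}
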