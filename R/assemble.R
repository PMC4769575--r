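# Rescue-read collection and de Bruijn unitig assembly of genomic mates.

#' Collect rescue reads from classified pairs
#'
#' The genomic-labelled mates of type 4 (genomic-hybrid) and type 5
#' (genomic-element) pairs carry purely genomic sequence from next to an
#' insertion; they are collected for assembly, grouped by the element end
#' (LE/RE) implied by their mate's terminal hit. Hybrid mates of type 4 pairs
#' are junction evidence in their own right and are routed through
#' [extract_hybrids()], not here.
#'
#' @param classified Output of [classify_pairs()].
#' @return A tibble with `read_id`, `sequence` and `end_group` (`LE`/`RE`).
#' @export
collect_rescue_reads <- function(classified) {
  one_mate <- function(mate) {
    pre <- paste0("r", mate, "_")
    other <- paste0("r", 3L - mate, "_")
    lab <- classified[[paste0(pre, "label")]]
    rows <- which(classified$type %in% c(4L, 5L) & lab == "genomic")
    if (!length(rows)) return(NULL)
    tibble::tibble(
      read_id = paste0(classified$pair_id[rows], "/", mate),
      sequence = classified[[paste0("seq", mate)]][rows],
      end_group = classified[[paste0(other, "end")]][rows])
  }
  out <- dplyr::bind_rows(one_mate(1L), one_mate(2L))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          end_group = character()))
  }
  out
}

#' Assemble reads into unitig nodes
#'
#' Builds a de Bruijn graph on canonical k-mers occurring at least
#' `min_kmer_count` times (both strands collapsed) and emits the maximal
#' non-branching paths (unitigs) as nodes. Dead-end branches shorter than
#' `2k` hanging off the graph are clipped. Nodes are emitted in canonical
#' orientation (lexicographic minimum of sequence and reverse complement)
#' and sorted lexicographically, so output is deterministic and invariant
#' under reverse-complementing the input reads.
#'
#' @param reads A tibble with `read_id` and `sequence` (e.g. from
#'   [collect_rescue_reads()]), or a character vector of sequences.
#' @param k Odd k-mer size between 15 and 31 (default 21).
#' @param min_kmer_count Minimum k-mer multiplicity (default 2; use 1 for
#'   error-free data).
#' @param clip_tips Clip short dead-end branches (default TRUE).
#' @return A tibble of nodes: `node_id`, `sequence`, `k`, `n_support` and
#'   `support_reads` (list column of read ids sharing a retained k-mer with
#'   the node).
#' @export
assemble_nodes <- function(reads, k = 21L, min_kmer_count = 2L,
                           clip_tips = TRUE) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 31L) {
    stop("k must be odd and between 15 and 31")
  }
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = as.character(seq_along(reads)),
                            sequence = reads)
  }
  usable <- nchar(reads$sequence) >= k
  reads <- reads[usable, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(tibble::tibble(node_id = character(), sequence = character(),
                          k = integer(), n_support = integer(),
                          support_reads = list()))
  }
  res <- assemble_unitigs_cpp(reads$sequence, k, as.integer(min_kmer_count),
                              isTRUE(clip_tips))
  support <- lapply(res$support, function(ix) reads$read_id[ix])
  tibble::tibble(
    node_id = paste0("node_", seq_along(res$sequence)),
    sequence = as.character(res$sequence),
    k = k,
    n_support = lengths(support),
    support_reads = support)
}

#' Assemble rescue reads per end group
#'
#' Runs [assemble_nodes()] separately for the LE and RE rescue-read groups
#' (mirroring the per-end workflow) and tags nodes with their group.
#'
#' @param rescue Output of [collect_rescue_reads()].
#' @inheritParams assemble_nodes
#' @return Node tibble with an extra `end_group` column; `node_id`s are
#'   unique across groups.
#' @export
assemble_rescue_nodes <- function(rescue, k = 21L, min_kmer_count = 2L,
                                  clip_tips = TRUE) {
  groups <- c("LE", "RE")
  out <- purrr::map(groups, function(g) {
    sub <- rescue[!is.na(rescue$end_group) & rescue$end_group == g, ,
                  drop = FALSE]
    nodes <- assemble_nodes(sub, k = k, min_kmer_count = min_kmer_count,
                            clip_tips = clip_tips)
    if (nrow(nodes)) nodes$end_group <- g
    nodes
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) out$node_id <- paste0("node_", seq_len(nrow(out)))
  else out$end_group <- character()
  out
}
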