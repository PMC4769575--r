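# Mapping junction evidence to the reference, clustering into insertion loci,
# confidence assignment, deterministic numbering, zygosity estimation.

#' Map hybrid fragments and assembled nodes to the reference genome
#'
#' Aligns each hybrid read's genomic fragment and each node with the seeded
#' aligner, keeps hits passing identity and length cutoffs, and derives the
#' junction breakpoint from the junction-proximal end of the mapped interval:
#' for hybrids, the end where the element adjoins the fragment
#' (`element_side` mapped through the hit strand); for nodes, the
#' element-facing end implied by the recruiting mates' LE/RE group (an
#' upstream/LE flank faces the element at its high-coordinate end, a
#' downstream/RE flank at its low end). Evidence with more than one
#' equally-best-scoring location is discarded and counted as multi-mapping.
#'
#' @param hybrids Tibble from [extract_hybrids()] (may be empty).
#' @param nodes Tibble from [assemble_rescue_nodes()] (may be empty).
#' @param genome_index A [build_kmer_index()] over the reference genome.
#' @param min_identity Minimum alignment identity (default 0.95).
#' @param min_mapped_len Minimum mapped query length in bases (default 20).
#' @param scoring Alignment scoring.
#' @return A tibble of evidence hits: `evidence_id`, `evidence_kind`
#'   (`hybrid_LE`/`hybrid_RE`/`node`), `chrom`, `breakpoint` (1-based),
#'   `strand`, `t_start`, `t_end` (0-based half-open) and `identity`; with a
#'   `map_report` attribute counting unmapped and multi-mapping evidence
#'   (see [map_report()]).
#' @export
map_evidence <- function(hybrids, nodes, genome_index, min_identity = 0.95,
                         min_mapped_len = 20L, scoring = alignment_scoring()) {
  q <- dplyr::bind_rows(
    if (!is.null(hybrids) && nrow(hybrids)) {
      tibble::tibble(evidence_id = hybrids$read_id,
                     evidence_kind = paste0("hybrid_", hybrids$end),
                     sequence = hybrids$genomic_fragment,
                     junction_high_if_plus = hybrids$element_side == "right")
    },
    if (!is.null(nodes) && nrow(nodes)) {
      tibble::tibble(evidence_id = nodes$node_id,
                     evidence_kind = "node",
                     sequence = nodes$sequence,
                     junction_high_if_plus = NA)
    })
  empty <- tibble::tibble(evidence_id = character(), evidence_kind = character(),
                          chrom = character(), breakpoint = integer(),
                          strand = character(), t_start = integer(),
                          t_end = integer(), identity = double())
  report0 <- tibble::tibble(n_evidence = 0L, n_mapped = 0L, n_unmapped = 0L,
                            n_multimapped = 0L)
  if (is.null(q) || nrow(q) == 0L) {
    attr(empty, "map_report") <- report0
    return(empty)
  }
  node_end <- if (!is.null(nodes) && nrow(nodes)) {
    stats::setNames(nodes$end_group, nodes$node_id)
  } else c()
  hits <- seeded_local_align(stats::setNames(q$sequence, q$evidence_id),
                             genome_index, scoring,
                             min_score = as.integer(min_mapped_len))
  hits <- hits[hits$identity >= min_identity &
                 (hits$q_end - hits$q_start) >= min_mapped_len, , drop = FALSE]
  n_in <- nrow(q)
  if (nrow(hits) == 0L) {
    report0$n_evidence <- n_in
    report0$n_unmapped <- n_in
    attr(empty, "map_report") <- report0
    return(empty)
  }
  best <- hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::mutate(n_best = dplyr::n()) |>
    dplyr::ungroup()
  multi <- unique(best$query_id[best$n_best > 1L])
  best <- best[best$n_best == 1L, , drop = FALSE]
  best <- dplyr::left_join(best,
                           q[c("evidence_id", "evidence_kind",
                               "junction_high_if_plus")],
                           by = c(query_id = "evidence_id"))
  jh <- ifelse(best$evidence_kind == "node",
               node_end[best$query_id] == "LE",
               best$junction_high_if_plus == (best$strand == "+"))
  out <- tibble::tibble(
    evidence_id = best$query_id,
    evidence_kind = best$evidence_kind,
    chrom = best$target_id,
    breakpoint = as.integer(ifelse(jh, best$t_end, best$t_start + 1L)),
    strand = best$strand,
    t_start = best$t_start, t_end = best$t_end,
    identity = best$identity)
  attr(out, "map_report") <- tibble::tibble(
    n_evidence = n_in,
    n_mapped = nrow(out),
    n_unmapped = n_in - nrow(out) - length(multi),
    n_multimapped = length(multi))
  out
}

#' Retrieve the mapping report attached by [map_evidence()]
#' @param hits Output of [map_evidence()].
#' @return One-row tibble with evidence/mapped/unmapped/multi-mapped counts.
#' @export
map_report <- function(hits) {
  rep <- attr(hits, "map_report")
  if (is.null(rep)) stop("no map_report attribute; was map_evidence() run?")
  rep
}

# lower median: for even counts take the smaller of the two central values
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Cluster evidence hits into candidate insertion loci
#'
#' Single-linkage clustering per chromosome: consecutive breakpoints join one
#' cluster while the gap is at most `window`. LE-side and RE-side evidence
#' within the window merge into one locus, since both junctions belong to one
#' inserted element (the target-site duplication offsets the two sides by
#' only a few bases). The cluster position is the median member breakpoint
#' (lower of the two central values for even counts); with tens of hybrid
#' reads per junction the median tracks the base-accurate hybrid
#' breakpoints, not the node ends.
#'
#' @param hits Evidence tibble from [map_evidence()].
#' @param window Maximum gap in bases between neighbouring members (default
#'   600). The window must absorb the largest junction-to-evidence offset:
#'   hybrid breakpoints are base-accurate, but a rescue-mate node ends about
#'   `insert_mean - 2*read_length` bases short of the junction (the
#'   unsequenced fragment interior), roughly 320 bases for a 500 bp library
#'   of 90 bp reads, plus assembly end variation.
#' @return A tibble with one row per cluster: `chrom`, `position`,
#'   `support_hybrid_LE`, `support_hybrid_RE`, `support_node`,
#'   `support_total` (distinct evidence), and `members` (list column of
#'   evidence ids).
#' @export
cluster_evidence <- function(hits, window = 600L) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(chrom = character(), position = integer(),
                          support_hybrid_LE = integer(),
                          support_hybrid_RE = integer(),
                          support_node = integer(), support_total = integer(),
                          members = list()))
  }
  hits |>
    dplyr::arrange(.data$chrom, .data$breakpoint, .data$evidence_id) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(gap = .data$breakpoint - dplyr::lag(.data$breakpoint),
                  new = is.na(.data$gap) | .data$gap > window,
                  cluster = cumsum(.data$new)) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      position = as.integer(lower_median(.data$breakpoint)),
      support_hybrid_LE = sum(.data$evidence_kind == "hybrid_LE"),
      support_hybrid_RE = sum(.data$evidence_kind == "hybrid_RE"),
      support_node = sum(.data$evidence_kind == "node"),
      support_total = dplyr::n_distinct(.data$evidence_id),
      members = list(.data$evidence_id),
      .groups = "drop") |>
    dplyr::select(-"cluster")
}

#' Assign confidence tiers to clustered loci
#'
#' A locus is high confidence (HC) when supported by at least
#' `hc_min_support` distinct reads/nodes, low confidence (LC) otherwise;
#' each physical read or node counts once.
#'
#' @param clusters Output of [cluster_evidence()].
#' @param hc_min_support Minimum distinct support for HC (default 3).
#' @return The cluster tibble with a `confidence` column (`"HC"`/`"LC"`).
#' @export
assign_confidence <- function(clusters, hc_min_support = 3L) {
  dplyr::mutate(clusters,
                confidence = ifelse(.data$support_total >= hc_min_support,
                                    "HC", "LC"))
}

#' Number loci deterministically
#'
#' Loci are sorted by confidence (HC before LC), then chromosome rank
#' (chromosomes in `chrom_order` first, unplaced scaffolds after, both in
#' the given/alphabetical order), then ascending position; remaining ties are
#' broken by descending support and the lexicographically smallest member
#' evidence id. Ids `Insertion-1`, `Insertion-2`, ... are assigned in that
#' order. The numbering is a pure function of its inputs.
#'
#' @param loci Output of [assign_confidence()].
#' @param chrom_order Character vector of reference names in rank order.
#' @return The loci with `insertion_id` assigned, in numbering order.
#' @export
number_loci <- function(loci, chrom_order) {
  if (nrow(loci) == 0L) {
    loci$insertion_id <- character()
    return(dplyr::relocate(loci, "insertion_id"))
  }
  rank <- match(loci$chrom, chrom_order)
  scaff <- is.na(rank)
  rank[scaff] <- length(chrom_order) + rank(loci$chrom[scaff],
                                            ties.method = "min")
  first_member <- purrr::map_chr(loci$members,
                                 function(m) sort(as.character(m))[1])
  ord <- order(loci$confidence != "HC", rank, loci$position,
               -loci$support_total, first_member)
  out <- loci[ord, , drop = FALSE]
  out$insertion_id <- paste0("Insertion-", seq_len(nrow(out)))
  dplyr::relocate(out, "insertion_id")
}

#' Place genomic read pairs on the reference
#'
#' Fast seed-and-verify placement of whole reads (exact k-mer seed plus
#' mismatch counting): the bulk mapper used to position type 2
#' (genomic-genomic) pairs for zygosity estimation. Reads with two
#' equally-good placements are dropped as ambiguous; pairs are kept when
#' both mates place on the same chromosome, in opposite orientations, with a
#' plausible implied fragment.
#'
#' @param pairs Pair tibble (needs `pair_id`, `seq1`, `seq2`).
#' @param genome_index A [build_kmer_index()] over the reference genome.
#' @param max_mismatch Maximum mismatches per read (default 6).
#' @param max_fragment Maximum implied fragment span in bases (default 2000).
#' @return A tibble of properly-placed pairs: `pair_id`, `chrom`,
#'   `left_start`, `left_end`, `right_start`, `right_end` (1-based
#'   inclusive read intervals, left = lower-coordinate mate).
#' @export
place_read_pairs <- function(pairs, genome_index, max_mismatch = 6L,
                             max_fragment = 2000L) {
  empty <- tibble::tibble(pair_id = character(), chrom = character(),
                          left_start = integer(), left_end = integer(),
                          right_start = integer(), right_end = integer())
  if (nrow(pairs) == 0L) return(empty)
  p1 <- place_reads_cpp(pairs$seq1, genome_index$ptr, as.integer(max_mismatch))
  p2 <- place_reads_cpp(pairs$seq2, genome_index$ptr, as.integer(max_mismatch))
  len1 <- nchar(pairs$seq1); len2 <- nchar(pairs$seq2)
  ok <- p1$placed & p2$placed & p1$target == p2$target & p1$strand != p2$strand
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(empty)
  s1 <- p1$start[ok] + 1L; e1 <- p1$start[ok] + len1[ok]
  s2 <- p2$start[ok] + 1L; e2 <- p2$start[ok] + len2[ok]
  first_left <- s1 <= s2
  out <- tibble::tibble(
    pair_id = pairs$pair_id[ok],
    chrom = genome_index$targets[p1$target[ok]],
    left_start = ifelse(first_left, s1, s2),
    left_end = ifelse(first_left, e1, e2),
    right_start = ifelse(first_left, s2, s1),
    right_end = ifelse(first_left, e2, e1))
  out[out$right_end - out$left_start + 1L <= max_fragment, , drop = FALSE]
}

#' Estimate zygosity of insertion loci from spanning genomic pairs
#'
#' A placed genomic fragment "spans" a junction when its two mates lie
#' strictly on opposite sides of the breakpoint. A homozygous insertion
#' leaves no intact reference allele, so no genomic fragment can span its
#' junction; a heterozygous one is spanned by fragments from the unmodified
#' haplotype. A locus is called homozygous when zero fragments span it and
#' its junction support is at least `hc_min_support`; heterozygous when at
#' least `min_span` fragments span it; undetermined otherwise.
#'
#' @param loci Numbered loci from [number_loci()].
#' @param placed_pairs Output of [place_read_pairs()] on the type 2 pairs.
#' @param min_span Minimum spanning fragments for a heterozygous call
#'   (default 3).
#' @param hc_min_support Junction support required for a homozygous call
#'   (default 3).
#' @return The loci with `spanning_pairs` and `zygosity`
#'   (`homozygous`/`heterozygous`/`undetermined`) columns.
#' @export
estimate_zygosity <- function(loci, placed_pairs, min_span = 3L,
                              hc_min_support = 3L) {
  count_span <- function(chrom, pos) {
    sub <- placed_pairs[placed_pairs$chrom == chrom, , drop = FALSE]
    sum(sub$left_end < pos & sub$right_start > pos)
  }
  spanning <- purrr::map2_int(loci$chrom, loci$position, count_span)
  dplyr::mutate(loci,
    spanning_pairs = spanning,
    zygosity = dplyr::case_when(
      spanning == 0L & .data$support_total >= hc_min_support ~ "homozygous",
      spanning >= min_span ~ "heterozygous",
      TRUE ~ "undetermined"))
}

#' Write insertion loci as BED6
#'
#' Converts the 1-based locus positions to 0-based half-open BED intervals;
#' `name` is the insertion id and `score` the total support.
#'
#' @param loci Locus tibble with `chrom`, `position`, `insertion_id`,
#'   `support_total`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom,
                    start = loci$position - 1L,
                    end = loci$position,
                    name = loci$insertion_id,
                    score = loci$support_total,
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
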