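# Local alignment: exact Smith-Waterman oracle and k-mer seeded production
# aligner. Coordinates are 0-based half-open internally; the insertion report
# converts to 1-based at the boundary.

#' Alignment scoring parameters
#'
#' Defaults approximate megablast-like behaviour: match +1, mismatch -2,
#' linear gap penalty -3 per base. `N` mismatches everything, including `N`.
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @param gap Per-base gap penalty (negative integer).
#' @return A list with components `match`, `mismatch`, `gap`.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L, gap = -3L) {
  stopifnot(match > 0, mismatch < 0, gap < 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap))
}

#' Exact Smith-Waterman local alignment
#'
#' Quadratic-time local alignment with a linear gap penalty; the exact oracle
#' against which the seeded aligner is held. Returns the maximum-scoring local
#' alignment; ties are broken deterministically by smallest query start, then
#' smallest target start. Alignments scoring below 1 are reported as no hit.
#'
#' @param query,target DNA strings over A, C, G, T, N.
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @return A one-row tibble with `query_start`, `query_end`, `target_start`,
#'   `target_end` (0-based half-open), `score` and `identity` (matching
#'   fraction of aligned columns), or a zero-row tibble if no local alignment
#'   scores at least 1.
#' @export
#' @examples
#' smith_waterman("TTACGTACGTTT", "ACGTACGT")
smith_waterman <- function(query, target, scoring = alignment_scoring()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  h <- sw_align_cpp(query, target, scoring$match, scoring$mismatch, scoring$gap)
  if (length(h) == 0L) {
    return(tibble::tibble(query_start = integer(), query_end = integer(),
                          target_start = integer(), target_end = integer(),
                          score = integer(), identity = double()))
  }
  tibble::as_tibble(h[c("query_start", "query_end", "target_start",
                        "target_end", "score", "identity")])
}

#' Build a k-mer index over named target sequences
#'
#' Every k-mer occurrence of every target is recorded; k-mers containing `N`
#' are skipped. Default k of 13 suits genome mapping; 11 suits matching
#' against the short element terminals (seeds must fit in a 90 bp read with
#' one error).
#'
#' @param targets A tibble with `name`/`sequence` columns (e.g. from
#'   [read_fasta()]) or a named character vector.
#' @param k K-mer size (8..31).
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(targets, k = 13L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be at least 8")
  if (is.data.frame(targets)) {
    nm <- targets$name; sq <- targets$sequence
  } else {
    nm <- names(targets); sq <- unname(targets)
    if (is.null(nm)) stop("targets must be named")
  }
  ptr <- kmer_index_build_cpp(nm, sq, k)
  structure(list(ptr = ptr, k = k, targets = nm,
                 target_lengths = kmer_index_target_lengths_cpp(ptr)),
            class = "kmer_index")
}

#' Look up a single k-mer in an index
#'
#' @param index A `kmer_index`.
#' @param kmer A k-length DNA string.
#' @return Tibble of occurrences: `target` (name) and `offset` (0-based).
#' @export
kmer_lookup <- function(index, kmer) {
  hits <- kmer_index_lookup_cpp(index$ptr, kmer)
  tibble::tibble(target = index$targets[hits$target], offset = hits$offset)
}

#' Number of k-mer occurrences stored in an index
#' @param index A `kmer_index`.
#' @return Total occurrence count (double; can exceed .Machine$integer.max).
#' @export
kmer_index_size <- function(index) kmer_index_n_kmers_cpp(index$ptr)

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$targets), " target(s), ",
      format(kmer_index_size(x), big.mark = ","), " k-mer occurrence(s)\n",
      sep = "")
  invisible(x)
}

#' K-mer seeded local alignment against an indexed target set
#'
#' Seeds exact k-mer matches on both strands (the query is
#' reverse-complemented for `-` strand hits), extends each seed band with the
#' same Smith-Waterman scoring as [smith_waterman()], and reports all hits
#' scoring at least `min_score`, merged so that no two reported hits on the
#' same target overlap by more than 50% on the query. Query coordinates of
#' `-` strand hits are mapped back to the original read orientation.
#'
#' @param queries Character vector of query sequences (names, if present,
#'   become `query_id`).
#' @param index A `kmer_index` built with `k <=` the query length.
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @param min_score Minimum reported alignment score.
#' @return A tibble with `query_id`, `target_id`, `q_start`, `q_end`,
#'   `t_start`, `t_end` (0-based half-open), `strand`, `score`, `identity`.
#'   Empty when no seed matches.
#' @export
seeded_local_align <- function(queries, index, scoring = alignment_scoring(),
                               min_score = 20L) {
  qid <- names(queries)
  if (is.null(qid)) qid <- as.character(seq_along(queries))
  hits <- seeded_align_cpp(unname(as.character(queries)), index$ptr,
                           scoring$match, scoring$mismatch, scoring$gap,
                           as.integer(min_score), 0.5)
  tibble::tibble(query_id = qid[hits$query],
                 target_id = index$targets[hits$target],
                 q_start = hits$q_start, q_end = hits$q_end,
                 t_start = hits$t_start, t_end = hits$t_end,
                 strand = hits$strand, score = hits$score,
                 identity = hits$identity)
}
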