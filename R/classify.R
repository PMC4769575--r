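# Read classification against the transposon terminals: element / genomic /
# hybrid per read, the five pair types, and hybrid-junction extraction.

#' Default classification thresholds
#'
#' 90 bp reads must split into an element portion long enough to anchor
#' (`min_element_match`) and a genomic portion long enough to map
#' (`min_genomic_tail`); `full_match_slack` tolerates a few unaligned bases
#' at read edges and at the junction.
#'
#' @param min_element_match Minimum element bases for a hybrid call (15).
#' @param min_identity Minimum identity of the terminal hit (0.9).
#' @param min_genomic_tail Minimum genomic bases for a hybrid call (20).
#' @param full_match_slack Edge slack in bases (3).
#' @param seed_k K-mer size for the terminal-seed prefilter (11).
#' @return Named list of thresholds.
#' @export
classify_params <- function(min_element_match = 15L, min_identity = 0.9,
                            min_genomic_tail = 20L, full_match_slack = 3L,
                            seed_k = 11L) {
  list(min_element_match = as.integer(min_element_match),
       min_identity = min_identity,
       min_genomic_tail = as.integer(min_genomic_tail),
       full_match_slack = as.integer(full_match_slack),
       seed_k = as.integer(seed_k))
}

#' Classify reads against the transposon terminals
#'
#' Each read's best local hit against the left-end (LE) and right-end (RE)
#' terminal baits is computed on both strands. A read is labelled `element`
#' when the hit covers it end-to-end within `full_match_slack` bases;
#' `hybrid` when the hit is long and clean enough, is anchored at the
#' terminal's outward edge (position 0 of the LE bait, or the last position
#' of the RE bait -- the edge where genome meets element), reaches the read
#' edge on the element-continuation side, and leaves a genomic tail of at
#' least `min_genomic_tail` bases; and `genomic` otherwise. Because the two
#' LTR copies are identical, LE/RE assignment reflects junction geometry, not
#' which physical LTR the bases came from.
#'
#' @param reads A tibble with `read_id` and `sequence` columns, or a
#'   character vector of sequences.
#' @param tn A [load_transposon()] object.
#' @param params Thresholds from [classify_params()].
#' @param scoring Alignment scoring from [alignment_scoring()].
#' @return A tibble with one row per read: `read_id`, `label`, `end`
#'   (`"LE"`/`"RE"` or `NA`), `strand`, `elem_start`/`elem_end` (element
#'   interval in read coordinates, 0-based half-open), `score`, `identity`,
#'   `junction_offset` (read position where element meets genome) and
#'   `genomic_side` (`"left"`/`"right"` of the read, hybrids only).
#' @export
classify_reads <- function(reads, tn, params = classify_params(),
                           scoring = alignment_scoring()) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = as.character(seq_along(reads)),
                            sequence = reads)
  }
  seqs <- reads$sequence
  len <- nchar(seqs)
  hits <- terminal_hits_cpp(seqs, tn$left_terminal, tn$right_terminal,
                            params$seed_k, scoring$match, scoring$mismatch,
                            scoring$gap)
  tlen <- tn$terminal_length
  slack <- params$full_match_slack
  hitlen <- hits$q_end - hits$q_start
  covers_read <- hits$has_hit & hits$q_start <= slack & (len - hits$q_end) <= slack
  good <- hits$has_hit & hitlen >= params$min_element_match &
    hits$identity >= params$min_identity
  # oriented-query coordinates: LE hybrids carry the genomic part on the left,
  # RE hybrids on the right
  hyb_le <- good & hits$end == 1L & hits$t_start <= slack &
    (len - hits$q_end) <= slack & hits$q_start >= params$min_genomic_tail
  hyb_re <- good & hits$end == 2L & (tlen - hits$t_end) <= slack &
    hits$q_start <= slack & (len - hits$q_end) >= params$min_genomic_tail
  label <- rep("genomic", length(seqs))
  label[!is.na(covers_read) & covers_read] <- "element"
  is_hyb <- !covers_read & (hyb_le | hyb_re)
  is_hyb[is.na(is_hyb)] <- FALSE
  label[is_hyb] <- "hybrid"

  end <- ifelse(hits$end == 1L, "LE", "RE")
  end[label == "genomic"] <- NA_character_
  minus <- !is.na(hits$strand) & hits$strand == "-"
  # element interval in read orientation
  elem_start <- ifelse(minus, len - hits$q_end, hits$q_start)
  elem_end <- ifelse(minus, len - hits$q_start, hits$q_end)
  # genomic side in read orientation (hybrids): LE oriented-left, RE
  # oriented-right; a '-' strand hit flips the side
  side_oriented <- ifelse(hits$end == 1L, "left", "right")
  genomic_side <- ifelse(minus,
                         ifelse(side_oriented == "left", "right", "left"),
                         side_oriented)
  genomic_side[label != "hybrid"] <- NA_character_
  junction_offset <- ifelse(genomic_side == "left", elem_start, elem_end)
  junction_offset[label != "hybrid"] <- NA_integer_

  keep_hit <- label != "genomic"
  tibble::tibble(
    read_id = reads$read_id,
    label = label,
    end = end,
    strand = ifelse(keep_hit, hits$strand, NA_character_),
    elem_start = as.integer(ifelse(keep_hit, elem_start, NA_integer_)),
    elem_end = as.integer(ifelse(keep_hit, elem_end, NA_integer_)),
    score = ifelse(keep_hit, hits$score, NA_integer_),
    identity = ifelse(keep_hit, hits$identity, NA_real_),
    junction_offset = as.integer(junction_offset),
    genomic_side = genomic_side)
}

#' Map mate labels to the five pair types
#'
#' Type 1: element-element; type 2: genomic-genomic; type 3: hybrid with an
#' element mate (a hybrid-hybrid pair is also recorded as type 3, keeping
#' both junctions as evidence); type 4: genomic with a hybrid mate; type 5:
#' genomic with an element mate. Order-insensitive and total over the nine
#' label combinations.
#'
#' @param label1,label2 Character vectors of read labels
#'   (`"element"`/`"genomic"`/`"hybrid"`).
#' @return Integer vector of pair types (1-5).
#' @export
pair_type_from_labels <- function(label1, label2) {
  stopifnot(length(label1) == length(label2))
  a <- pmin(label1, label2)  # lexicographic: element < genomic < hybrid
  b <- pmax(label1, label2)
  dplyr::case_when(
    a == "element" & b == "element" ~ 1L,
    a == "genomic" & b == "genomic" ~ 2L,
    a == "element" & b == "hybrid" ~ 3L,
    a == "hybrid" & b == "hybrid" ~ 3L,
    a == "genomic" & b == "hybrid" ~ 4L,
    a == "element" & b == "genomic" ~ 5L)
}

#' Classify read pairs into the five pair types
#'
#' Classifies both mates with [classify_reads()] and combines the labels with
#' [pair_type_from_labels()]. Read-level fields are kept with `r1_`/`r2_`
#' prefixes so hybrid extraction and rescue-read collection need no second
#' alignment pass.
#'
#' @param pairs Pair tibble from [pair_reads()] / [qc_filter_pairs()].
#' @param tn A [load_transposon()] object.
#' @param params Thresholds from [classify_params()].
#' @param scoring Alignment scoring.
#' @return The pair tibble with `type` plus prefixed per-mate classification
#'   columns.
#' @export
classify_pairs <- function(pairs, tn, params = classify_params(),
                           scoring = alignment_scoring()) {
  c1 <- classify_reads(tibble::tibble(read_id = pairs$pair_id,
                                      sequence = pairs$seq1), tn, params, scoring)
  c2 <- classify_reads(tibble::tibble(read_id = pairs$pair_id,
                                      sequence = pairs$seq2), tn, params, scoring)
  add_prefix <- function(x, p) {
    stats::setNames(x[setdiff(names(x), "read_id")],
                    paste0(p, setdiff(names(x), "read_id")))
  }
  dplyr::bind_cols(
    pairs,
    tibble::tibble(type = pair_type_from_labels(c1$label, c2$label)),
    add_prefix(c1, "r1_"), add_prefix(c2, "r2_"))
}

#' Count pairs by type
#'
#' @param classified Output of [classify_pairs()].
#' @return A tibble with `type` (1-5) and `n`, all five types present.
#' @export
pair_type_counts <- function(classified) {
  tibble::tibble(type = 1:5) |>
    dplyr::left_join(dplyr::count(classified, .data$type), by = "type") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Extract hybrid junction records from classified pairs
#'
#' For every hybrid-labelled mate, the genomic portion of the read (the
#' maximal substring outside the element interval, in read orientation) is
#' extracted together with the junction geometry. `element_side` records on
#' which side of the extracted fragment the element continues, which later
#' determines the junction-proximal end of its genome alignment.
#'
#' @param classified Output of [classify_pairs()].
#' @return A tibble with `read_id` (pair id suffixed `/1` or `/2`), `end`
#'   (`LE`/`RE`), `elem_start`, `elem_end`, `junction_offset`,
#'   `genomic_fragment` and `element_side` (`"left"`/`"right"`).
#' @export
extract_hybrids <- function(classified) {
  one_mate <- function(mate) {
    pre <- paste0("r", mate, "_")
    lab <- classified[[paste0(pre, "label")]]
    rows <- which(lab == "hybrid")
    if (!length(rows)) return(NULL)
    seqs <- classified[[paste0("seq", mate)]][rows]
    side <- classified[[paste0(pre, "genomic_side")]][rows]
    es <- classified[[paste0(pre, "elem_start")]][rows]
    ee <- classified[[paste0(pre, "elem_end")]][rows]
    len <- nchar(seqs)
    frag <- ifelse(side == "left", substr(seqs, 1L, es),
                   substr(seqs, ee + 1L, len))
    tibble::tibble(
      read_id = paste0(classified$pair_id[rows], "/", mate),
      end = classified[[paste0(pre, "end")]][rows],
      elem_start = es, elem_end = ee,
      junction_offset = classified[[paste0(pre, "junction_offset")]][rows],
      genomic_fragment = frag,
      element_side = ifelse(side == "left", "right", "left"),
      read_sequence = seqs)
  }
  out <- dplyr::bind_rows(one_mate(1L), one_mate(2L))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(read_id = character(), end = character(),
                          elem_start = integer(), elem_end = integer(),
                          junction_offset = integer(),
                          genomic_fragment = character(),
                          element_side = character(),
                          read_sequence = character()))
  }
  out
}

#' Drop hybrid calls explainable by the reference alone
#'
#' A read spanning a real element-genome junction cannot be placed
#' full-length on the reference: its element portion does not exist there.
#' A rare genomic locus that happens to resemble a terminal edge, however,
#' turns every read ending across it into a false hybrid call -- and those
#' reads place on the reference end-to-end with at most a handful of
#' sequencing errors. This filter arbitrates the two cases by full-length
#' placement, keeping only hybrids the reference cannot explain.
#'
#' @param hybrids Output of [extract_hybrids()].
#' @param genome_index A [build_kmer_index()] over the reference genome.
#' @param max_mismatch Placement mismatch budget (default 6); a true hybrid
#'   with `min_element_match` or more element bases always exceeds it.
#' @return The filtered hybrid tibble, with a `n_reference_matching`
#'   attribute counting the dropped calls.
#' @export
drop_reference_hybrids <- function(hybrids, genome_index, max_mismatch = 6L) {
  if (nrow(hybrids) == 0L) {
    attr(hybrids, "n_reference_matching") <- 0L
    return(hybrids)
  }
  p <- place_reads_cpp(hybrids$read_sequence, genome_index$ptr,
                       as.integer(max_mismatch))
  drop <- p$placed | p$ambiguous
  out <- hybrids[!drop, , drop = FALSE]
  attr(out, "n_reference_matching") <- sum(drop)
  out
}
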