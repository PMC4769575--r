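# Synthetic-data generator: toy genome, planted insertions with known
# positions/zygosity, paired-end read simulation, recovery scoring.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the stated GC content; deterministic for a fixed seed.
#'
#' @param n_chroms Number of chromosomes (named `chr1` ... `chrN`).
#' @param length_per_chrom Chromosome length in bases (at least 10 kb).
#' @param gc GC proportion in (0, 1).
#' @param seed Integer seed.
#' @return A tibble with `name` and `sequence`, usable wherever a
#'   [read_fasta()] result is.
#' @export
generate_genome <- function(n_chroms = 1L, length_per_chrom = 1e6,
                            gc = 0.5, seed = 1L) {
  stopifnot(length_per_chrom >= 1e4, gc > 0, gc < 1, n_chroms >= 1)
  withr::with_seed(seed, {
    tibble::tibble(
      name = paste0("chr", seq_len(n_chroms)),
      sequence = purrr::map_chr(seq_len(n_chroms),
                                function(i) random_dna(length_per_chrom, gc)))
  })
}

#' A synthetic Tnt1-like element
#'
#' A 5,300 bp element with identical 610 bp terminal repeats, generated at a
#' fixed seed, standing in for the real element so no external sequence is
#' needed; supply the real element FASTA via [load_transposon()] to use it
#' instead. The synthetic element reproduces the structural features the
#' pipeline relies on (identical LTRs, distinct 90 bp end baits) but not the
#' element's coding content.
#'
#' @param seed Integer seed.
#' @param length Total element length (default 5300).
#' @param ltr_length LTR length (default 610).
#' @param terminal_length Terminal bait length (default 90).
#' @return A `transposon_ref` (see [load_transposon()]).
#' @export
synthetic_tnt1 <- function(seed = 8675309L, length = 5300L, ltr_length = 610L,
                           terminal_length = 90L) {
  stopifnot(length >= 2L * ltr_length)
  withr::with_seed(seed, {
    ltr <- random_dna(ltr_length)
    interior <- random_dna(length - 2L * ltr_length)
    load_transposon(tibble::tibble(name = "Tnt1_synthetic",
                                   sequence = paste0(ltr, interior, ltr)),
                    ltr_length = ltr_length,
                    terminal_length = terminal_length)
  })
}

#' Plant transposon insertions into a genome
#'
#' Builds two haplotypes per chromosome. At each drawn site the element (in
#' the drawn orientation) is inserted together with a target-site duplication
#' of the `tsd_length` bases preceding the insertion point: the haplotype
#' becomes `genome[1..p] + element + genome[p-tsd+1..]`, so its length grows
#' by the element length plus `tsd_length`. Homozygous sites alter both
#' haplotypes, heterozygous sites only haplotype 1. Sites are kept at least
#' `end_margin` bases from chromosome ends and `min_spacing` apart so
#' neighbouring insertions stay resolvable.
#'
#' @param genome Tibble from [generate_genome()] or [read_fasta()].
#' @param element A `transposon_ref`.
#' @param n Number of insertions.
#' @param het_fraction Proportion of heterozygous insertions (default 0).
#' @param tsd_length Target-site duplication length (default 5, typical for
#'   copia-family LTR elements).
#' @param seed Integer seed.
#' @param end_margin Minimum distance from chromosome ends (default 1000,
#'   i.e. twice the default insert size).
#' @param min_spacing Minimum distance between insertions (default 2000).
#' @return A list with `haplotypes` (tibble: `chrom`, `haplotype` 1/2,
#'   `sequence`) and `truth`, a tibble of planted insertions (`chrom`,
#'   `position` = 1-based last reference base before the element,
#'   `orientation`, `zygosity`, `tsd_length`) carrying the generator
#'   parameters as attributes.
#' @export
plant_insertions <- function(genome, element, n, het_fraction = 0,
                             tsd_length = 5L, seed = 1L,
                             end_margin = 1000L, min_spacing = 2000L) {
  stopifnot(n >= 1, het_fraction >= 0, het_fraction <= 1, tsd_length >= 0)
  withr::with_seed(seed, {
    lens <- nchar(genome$sequence)
    usable <- pmax(0, lens - 2L * end_margin)
    if (sum(usable) < n * min_spacing) {
      stop("cannot place ", n, " insertions ", min_spacing,
           " bp apart in this genome; use a longer genome")
    }
    # draw sites chromosome-proportionally, rejecting crowded draws
    sites <- NULL
    for (attempt in 1:200) {
      ch <- sample(seq_len(nrow(genome)), n, replace = TRUE,
                   prob = usable / sum(usable))
      pos <- end_margin + as.integer(ceiling(runif(n) * usable[ch]))
      cand <- tibble::tibble(ci = ch, position = pos) |>
        dplyr::arrange(.data$ci, .data$position)
      gaps <- cand |>
        dplyr::group_by(.data$ci) |>
        dplyr::mutate(gap = .data$position - dplyr::lag(.data$position)) |>
        dplyr::pull(.data$gap)
      if (all(is.na(gaps) | gaps >= min_spacing)) { sites <- cand; break }
    }
    if (is.null(sites)) {
      stop("cannot place ", n, " insertions ", min_spacing,
           " bp apart in this genome; use a longer genome")
    }
    n_het <- round(het_fraction * n)
    zyg <- sample(c(rep("heterozygous", n_het),
                    rep("homozygous", n - n_het)))
    orientation <- sample(c("+", "-"), n, replace = TRUE)
    truth <- tibble::tibble(chrom = genome$name[sites$ci],
                            position = sites$position,
                            orientation = orientation,
                            zygosity = zyg,
                            tsd_length = as.integer(tsd_length))
    elem_fwd <- element$sequence
    elem_rev <- revcomp(elem_fwd)
    build_hap <- function(ci, include_het) {
      s <- genome$sequence[ci]
      ins <- truth[truth$chrom == genome$name[ci], , drop = FALSE]
      if (!include_het) ins <- ins[ins$zygosity == "homozygous", , drop = FALSE]
      if (nrow(ins) == 0L) return(s)
      ins <- ins[order(-ins$position), , drop = FALSE]  # right to left
      for (i in seq_len(nrow(ins))) {
        p <- ins$position[i]
        el <- if (ins$orientation[i] == "+") elem_fwd else elem_rev
        s <- paste0(substr(s, 1L, p), el,
                    substr(s, p - tsd_length + 1L, nchar(s)))
      }
      s
    }
    haplotypes <- tidyr::expand_grid(ci = seq_len(nrow(genome)),
                                     haplotype = 1:2) |>
      dplyr::mutate(chrom = genome$name[.data$ci],
                    sequence = purrr::map2_chr(.data$ci, .data$haplotype,
                      function(ci, h) build_hap(ci, include_het = h == 1L))) |>
      dplyr::select("chrom", "haplotype", "sequence")
    attr(truth, "element") <- element$name
    attr(truth, "seed") <- seed
    list(haplotypes = haplotypes, truth = truth)
  })
}

#' Simulate paired-end reads from haplotypes
#'
#' Fragments are drawn uniformly along the haplotypes (a heterozygous
#' insertion is therefore covered at roughly half depth), with lengths
#' Normal(`insert_mean`, `insert_sd`) truncated below at twice the read
#' length. Read 1 is the fragment's 5' end; read 2 the reverse complement of
#' its 3' end. Substitution errors are i.i.d. at `error_rate`; base
#' qualities are Q35 with errored bases written at Q15. Output is
#' deterministic for a fixed seed; total read bases approximate
#' `coverage` times the haploid genome length.
#'
#' @param haplotypes Haplotype tibble from [plant_insertions()] (any tibble
#'   with `chrom`, `haplotype`, `sequence` works).
#' @param coverage Total fold coverage of the haploid genome (default 40).
#' @param read_length Read length in bases (default 90).
#' @param insert_mean,insert_sd Fragment length distribution (defaults
#'   500 and 50).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param seed Integer seed.
#' @return A pair tibble (`pair_id`, `seq1`, `qual1`, `seq2`, `qual2`) with
#'   the read parameters attached as the `read_params` attribute.
#' @export
simulate_read_pairs <- function(haplotypes, coverage = 40, read_length = 90L,
                                insert_mean = 500, insert_sd = 50,
                                error_rate = 0.001, seed = 1L) {
  stopifnot(insert_mean > 2 * read_length)
  withr::with_seed(seed, {
    lens <- nchar(haplotypes$sequence)
    haploid <- sum(lens) / 2
    n_frag <- as.integer(round(coverage * haploid / (2 * read_length)))
    hidx <- sample(seq_along(lens), n_frag, replace = TRUE,
                   prob = lens / sum(lens))
    flen <- pmax(2L * read_length,
                 as.integer(round(rnorm(n_frag, insert_mean, insert_sd))))
    flen <- pmin(flen, lens[hidx])
    start <- 1L + as.integer(floor(runif(n_frag) * (lens[hidx] - flen + 1)))
    seq1 <- substring(haplotypes$sequence[hidx], start,
                      start + read_length - 1L)
    seq2 <- revcomp(substring(haplotypes$sequence[hidx],
                              start + flen - read_length, start + flen - 1L))
    q0 <- strrep(rawToChar(as.raw(35L + 33L)), read_length)
    qual1 <- rep(q0, n_frag)
    qual2 <- rep(q0, n_frag)
    inject <- function(seqs, quals) {
      n_err <- rbinom(length(seqs), read_length, error_rate)
      idx <- which(n_err > 0L)
      qe <- rawToChar(as.raw(15L + 33L))
      for (i in idx) {
        pos <- sample.int(read_length, n_err[i])
        s <- seqs[i]; q <- quals[i]
        for (p in pos) {
          orig <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
          substr(q, p, p) <- qe
        }
        seqs[i] <- s; quals[i] <- q
      }
      list(seqs = seqs, quals = quals)
    }
    if (error_rate > 0) {
      r1 <- inject(seq1, qual1); seq1 <- r1$seqs; qual1 <- r1$quals
      r2 <- inject(seq2, qual2); seq2 <- r2$seqs; qual2 <- r2$quals
    }
    out <- tibble::tibble(
      pair_id = sprintf("frag_%07d", seq_len(n_frag)),
      seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2)
    attr(out, "read_params") <- tibble::tibble(
      read_length = as.integer(read_length), insert_mean = insert_mean,
      insert_sd = insert_sd, coverage = coverage, error_rate = error_rate,
      seed = as.integer(seed), n_fragments = n_frag,
      fragment_lengths = list(flen))
    out
  })
}

#' Write a pair tibble as two FASTQ files
#'
#' @param pairs Pair tibble.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with read ids suffixed `/1` and `/2`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_pair_fastq <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  write_fastq(tibble::tibble(read_id = paste0(pairs$pair_id, "/1"),
                             sequence = pairs$seq1, quality = pairs$qual1), p1)
  write_fastq(tibble::tibble(read_id = paste0(pairs$pair_id, "/2"),
                             sequence = pairs$seq2, quality = pairs$qual2), p2)
  invisible(c(p1, p2))
}

#' Simulate a complete ground-truthed dataset
#'
#' Convenience wrapper: [generate_genome()], [synthetic_tnt1()] (unless an
#' element is supplied), [plant_insertions()], [simulate_read_pairs()].
#' Sub-seeds are derived from `seed` (seed, seed + 1, seed + 2) so one
#' integer pins the whole dataset.
#'
#' @param seed Integer seed.
#' @param n_chroms,length_per_chrom,gc Genome parameters.
#' @param element Optional `transposon_ref`; defaults to [synthetic_tnt1()].
#' @param n_insertions Number of planted insertions (default 20).
#' @param het_fraction Proportion heterozygous (default 0).
#' @param tsd_length Target-site duplication length (default 5).
#' @param coverage,read_length,insert_mean,insert_sd,error_rate Read
#'   simulation parameters (defaults 40, 90, 500, 50, 0.001).
#' @return A list with `genome`, `element`, `haplotypes`, `truth`, `pairs`.
#' @export
simulate_dataset <- function(seed = 1L, n_chroms = 1L, length_per_chrom = 1e6,
                             gc = 0.5, element = NULL, n_insertions = 20L,
                             het_fraction = 0, tsd_length = 5L, coverage = 40,
                             read_length = 90L, insert_mean = 500,
                             insert_sd = 50, error_rate = 0.001) {
  genome <- generate_genome(n_chroms, length_per_chrom, gc, seed = seed)
  if (is.null(element)) element <- synthetic_tnt1()
  planted <- plant_insertions(genome, element, n = n_insertions,
                              het_fraction = het_fraction,
                              tsd_length = tsd_length, seed = seed + 1L,
                              end_margin = as.integer(2 * insert_mean),
                              min_spacing = as.integer(4 * insert_mean))
  pairs <- simulate_read_pairs(planted$haplotypes, coverage = coverage,
                               read_length = read_length,
                               insert_mean = insert_mean,
                               insert_sd = insert_sd,
                               error_rate = error_rate, seed = seed + 2L)
  list(genome = genome, element = element, haplotypes = planted$haplotypes,
       truth = planted$truth, pairs = pairs)
}

#' Score called loci against the simulation truth
#'
#' Greedy one-to-one matching by distance: called loci (HC by default) are
#' matched to planted insertions on the same chromosome within `tolerance`
#' bases, nearest pairs first.
#'
#' @param loci Locus tibble from the detection pipeline.
#' @param truth Truth tibble from [plant_insertions()].
#' @param tolerance Maximum |offset| in bases for a true positive
#'   (default 10).
#' @param confidence Confidence tier(s) of calls to score (default `"HC"`;
#'   use `c("HC", "LC")` for all).
#' @return A list with `metrics` (one-row tibble: `n_truth`, `n_called`,
#'   `n_matched`, `recall`, `precision`, `mean_abs_offset`,
#'   `max_nearest_truth_distance`) and `per_locus` (each scored call with its
#'   matched insertion, `offset`, `nearest_truth_distance` and support).
#' @export
evaluate_recovery <- function(loci, truth, tolerance = 10L,
                              confidence = "HC") {
  called <- loci
  if ("confidence" %in% names(called)) {
    called <- called[called$confidence %in% confidence, , drop = FALSE]
  }
  if (nrow(called) == 0L) {
    return(list(
      metrics = tibble::tibble(n_truth = nrow(truth), n_called = 0L,
                               n_matched = 0L, recall = 0,
                               precision = NA_real_,
                               mean_abs_offset = NA_real_,
                               max_nearest_truth_distance = NA_real_),
      per_locus = tibble::tibble()))
  }
  cand <- tidyr::expand_grid(ci = seq_len(nrow(called)),
                             ti = seq_len(nrow(truth))) |>
    dplyr::filter(called$chrom[.data$ci] == truth$chrom[.data$ti]) |>
    dplyr::mutate(dist = abs(called$position[.data$ci] -
                               truth$position[.data$ti]))
  nearest <- cand |>
    dplyr::group_by(.data$ci) |>
    dplyr::summarise(nearest_truth_distance = min(.data$dist))
  cand <- cand[cand$dist <= tolerance, , drop = FALSE] |>
    dplyr::arrange(.data$dist, .data$ci, .data$ti)
  used_c <- logical(nrow(called)); used_t <- logical(nrow(truth))
  match_t <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(cand))) {
    ci <- cand$ci[i]; ti <- cand$ti[i]
    if (!used_c[ci] && !used_t[ti]) {
      used_c[ci] <- TRUE; used_t[ti] <- TRUE; match_t[ci] <- ti
    }
  }
  per_locus <- tibble::tibble(
    insertion_id = called$insertion_id,
    chrom = called$chrom,
    position = called$position,
    support_total = called$support_total,
    matched = !is.na(match_t),
    truth_position = ifelse(is.na(match_t), NA_integer_,
                            truth$position[match_t]),
    offset = ifelse(is.na(match_t), NA_integer_,
                    called$position - truth$position[match_t])) |>
    dplyr::left_join(
      tibble::tibble(insertion_id = called$insertion_id[nearest$ci],
                     nearest_truth_distance = nearest$nearest_truth_distance),
      by = "insertion_id") |>
    dplyr::mutate(nearest_truth_distance =
                    dplyr::coalesce(.data$nearest_truth_distance, Inf))
  n_matched <- sum(per_locus$matched)
  metrics <- tibble::tibble(
    n_truth = nrow(truth),
    n_called = nrow(called),
    n_matched = n_matched,
    recall = n_matched / nrow(truth),
    precision = n_matched / nrow(called),
    mean_abs_offset = if (n_matched) mean(abs(per_locus$offset),
                                          na.rm = TRUE) else NA_real_,
    max_nearest_truth_distance =
      if (nrow(per_locus)) suppressWarnings(
        max(per_locus$nearest_truth_distance, na.rm = TRUE)) else NA_real_)
  list(metrics = metrics, per_locus = per_locus)
}
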