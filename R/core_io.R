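# FASTA/FASTQ readers and writers, read QC, transposon terminal handling.

#' Reverse-complement DNA strings
#'
#' @param seqs Character vector of DNA sequences over A, C, G, T, N
#'   (case preserved in the complement, N maps to N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seqs) revcomp_cpp(as.character(seqs))

#' Read a FASTQ file into a tibble of reads
#'
#' Parses 4-line-record FASTQ with Phred+33 qualities. Records are validated:
#' a missing `+` separator, a header not starting with `@`, or a quality
#' string whose length differs from the sequence raise a parse error naming
#' the offending line.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @param mate Mate number to record for every read (1 or 2).
#' @return A tibble with columns `read_id`, `sequence`, `quality` (Phred+33
#'   string) and `mate`. Use [phred_scores()] to decode qualities to integers.
#' @export
read_fastq <- function(path, mate = 1L) {
  stopifnot(mate %in% c(1L, 2L))
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), mate = integer()))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", n,
         " lines is not a multiple of 4 (truncated record near line ", n, ")")
  }
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': header missing '@' at line ",
         (bad[1] - 1L) * 4L + 1L)
  }
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': separator missing '+' at line ",
         (bad[1] - 1L) * 4L + 3L)
  }
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': sequence and quality lengths differ at line ",
         (bad[1] - 1L) * 4L + 4L)
  }
  ids <- sub("\\s.*$", "", substring(hd, 2L))
  # reject encodings other than Phred+33 up front
  low_quality_fraction_cpp(ql, 0L)
  tibble::tibble(read_id = ids, sequence = toupper(sq), quality = ql,
                 mate = as.integer(mate))
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
#' @examples
#' phred_scores("IIII")[[1]]  # 40 40 40 40
phred_scores <- function(quality) phred_decode_cpp(as.character(quality))

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: writing the tibble returned by [read_fastq()]
#' reproduces a well-formed Phred+33 input byte-identically.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$quality)
  writeLines(rec, con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; record names are the first whitespace token of
#' each header. Duplicate names are an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  nm <- sub("\\s.*$", "", names(ss))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate sequence name(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  }
  tibble::tibble(name = nm, sequence = unname(toupper(as.character(ss))))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs A tibble with `name` and `sequence` columns, or a named
#'   character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    x <- stats::setNames(seqs$sequence, seqs$name)
  } else {
    x <- seqs
  }
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Combine mate tibbles into a read-pair tibble
#'
#' @param reads1,reads2 Tibbles from [read_fastq()] for mate 1 and mate 2,
#'   in matching order.
#' @return A tibble with one row per fragment: `pair_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
pair_reads <- function(reads1, reads2) {
  if (nrow(reads1) != nrow(reads2)) {
    stop("mate files have different read counts (", nrow(reads1), " vs ",
         nrow(reads2), ")")
  }
  id1 <- sub("/[12]$", "", reads1$read_id)
  id2 <- sub("/[12]$", "", reads2$read_id)
  if (!all(id1 == id2)) {
    stop("mate read ids do not match at record ", which(id1 != id2)[1])
  }
  tibble::tibble(pair_id = id1,
                 seq1 = reads1$sequence, qual1 = reads1$quality,
                 seq2 = reads2$sequence, qual2 = reads2$quality)
}

#' Quality-filter read pairs
#'
#' Removes a pair when either mate has strictly more than `max_low_fraction`
#' of its bases below `low_quality_threshold` (Phred). The conventional Q20
#' cutoff defines a "low quality base"; the removal fraction mirrors the
#' common >50% rule used by sequencing providers. Adapter trimming is not
#' performed: input reads are assumed adapter-free ("clean") already.
#'
#' @param pairs Pair tibble from [pair_reads()].
#' @param low_quality_threshold Phred score below which a base counts as low
#'   quality (default 20).
#' @param max_low_fraction Maximum tolerated fraction of low-quality bases
#'   per read (default 0.5); removal requires strictly greater.
#' @return The kept pairs, with a `qc_report` attribute (a one-row tibble
#'   with `pairs_in`, `pairs_removed`, `pairs_kept`); see [qc_report()].
#' @export
qc_filter_pairs <- function(pairs, low_quality_threshold = 20L,
                            max_low_fraction = 0.5) {
  stopifnot(max_low_fraction >= 0, max_low_fraction <= 1)
  f1 <- low_quality_fraction_cpp(pairs$qual1, as.integer(low_quality_threshold))
  f2 <- low_quality_fraction_cpp(pairs$qual2, as.integer(low_quality_threshold))
  drop <- f1 > max_low_fraction | f2 > max_low_fraction
  kept <- pairs[!drop, , drop = FALSE]
  attr(kept, "qc_report") <- tibble::tibble(
    pairs_in = nrow(pairs),
    pairs_removed = sum(drop),
    pairs_kept = nrow(kept))
  kept
}

#' Retrieve the QC report attached by [qc_filter_pairs()]
#'
#' @param pairs A pair tibble returned by [qc_filter_pairs()].
#' @return A one-row tibble with `pairs_in`, `pairs_removed`, `pairs_kept`.
#' @export
qc_report <- function(pairs) {
  rep <- attr(pairs, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; was qc_filter_pairs() run?")
  rep
}

#' Load a transposon element and derive its terminal sequences
#'
#' The element is expected to carry identical long terminal repeats (LTRs) at
#' both ends; the first and last `terminal_length` bases are extracted as the
#' left-end (LE) and right-end (RE) classification baits. If the two LTR
#' copies differ, a warning is raised (the pipeline still runs; classification
#' tolerates mismatches up to its identity threshold).
#'
#' @param x Path to a single-record FASTA, a plain DNA string, or a tibble
#'   from [read_fasta()].
#' @param ltr_length LTR length in bases (default 610).
#' @param terminal_length Terminal bait length in bases (default 90).
#' @return An object of class `transposon_ref`: a list with `name`,
#'   `sequence`, `ltr_length`, `terminal_length`, `left_terminal`,
#'   `right_terminal`.
#' @export
load_transposon <- function(x, ltr_length = 610L, terminal_length = 90L) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fa <- read_fasta(x)
    if (nrow(fa) != 1L) stop("element FASTA must contain exactly one record")
    name <- fa$name[1]; seq <- fa$sequence[1]
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("element table must contain exactly one record")
    name <- x$name[1]; seq <- x$sequence[1]
  } else {
    name <- "element"; seq <- toupper(as.character(x))
  }
  ltr_length <- as.integer(ltr_length)
  terminal_length <- as.integer(terminal_length)
  len <- nchar(seq)
  if (len < 2L * ltr_length) {
    stop("element (", len, " bp) is shorter than two LTRs (2 x ",
         ltr_length, " bp)")
  }
  if (terminal_length < 1L || terminal_length > ltr_length) {
    stop("terminal_length must satisfy 0 < terminal_length <= ltr_length")
  }
  ltr1 <- substr(seq, 1L, ltr_length)
  ltr2 <- substr(seq, len - ltr_length + 1L, len)
  if (ltr1 != ltr2) {
    warning("the two LTR copies of '", name, "' are not identical")
  }
  structure(list(
    name = name,
    sequence = seq,
    ltr_length = ltr_length,
    terminal_length = terminal_length,
    left_terminal = substr(seq, 1L, terminal_length),
    right_terminal = substr(seq, len - terminal_length + 1L, len)),
    class = "transposon_ref")
}

#' @export
print.transposon_ref <- function(x, ...) {
  cat("<transposon_ref> ", x$name, ": ", nchar(x$sequence), " bp, LTR ",
      x$ltr_length, " bp, terminals ", x$terminal_length, " bp\n", sep = "")
  invisible(x)
}
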