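# Independent oracles and small fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Global alignment score of two (sub)strings by Needleman-Wunsch with linear
# gaps; the building block of the exhaustive local-alignment oracle below.
nw_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- gap * (0:n); H[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(
        H[i, j] + if (av[i] == bv[j]) match else mismatch,
        H[i, j + 1] + gap,
        H[i + 1, j] + gap)
    }
  }
  H[n + 1, m + 1]
}

# Exhaustive local-alignment oracle: the best global score over every pair of
# substrings. Cubic-ish and only usable on tiny inputs; independent of the
# dynamic-programming path used by the package.
sw_oracle <- function(q, t, ...) {
  best <- 0
  for (qs in seq_len(nchar(q))) for (qe in qs:nchar(q)) {
    for (ts in seq_len(nchar(t))) for (te in ts:nchar(t)) {
      s <- nw_score(substr(q, qs, qe), substr(t, ts, te), ...)
      if (s > best) best <- s
    }
  }
  best
}

# Junction read straddling the left or right end of an inserted element:
# `n_elem` element bases and `read_length - n_elem` flank bases.
junction_read <- function(flank, element_seq, n_elem, side = c("left", "right"),
                          read_length = 90L) {
  side <- match.arg(side)
  n_gen <- read_length - n_elem
  if (side == "left") {
    # genomic flank then the element's first bases
    paste0(substr(flank, nchar(flank) - n_gen + 1L, nchar(flank)),
           substr(element_seq, 1L, n_elem))
  } else {
    # the element's last bases then genomic flank
    paste0(substr(element_seq, nchar(element_seq) - n_elem + 1L,
                  nchar(element_seq)),
           substr(flank, 1L, n_gen))
  }
}

# Constant-quality pair tibble from raw sequences.
make_pairs <- function(seq1, seq2, q = "I") {
  tibble::tibble(pair_id = sprintf("p%03d", seq_along(seq1)),
                 seq1 = seq1, qual1 = strrep(q, nchar(seq1)),
                 seq2 = seq2, qual2 = strrep(q, nchar(seq2)))
}
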