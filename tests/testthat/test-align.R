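test_that("Smith-Waterman recovers self-alignment and rejects junk", {
  hit <- smith_waterman("ACGTACGT", "ACGTACGT")
  expect_equal(hit$score, 8L)
  expect_equal(hit$identity, 1)
  expect_equal(c(hit$query_start, hit$query_end), c(0L, 8L))
  expect_equal(nrow(smith_waterman("AAAA", "CCCC")), 0L)
  expect_error(smith_waterman("ACGX", "ACGT"), "invalid character")
})

test_that("Smith-Waterman matches the exhaustive substring oracle", {
  hit <- smith_waterman("TTACGTACGTTT", "ACGTACGT")
  expect_equal(hit$score, 8L)
  expect_equal(c(hit$query_start, hit$query_end), c(2L, 10L))
  expect_equal(hit$score, sw_oracle("TTACGTACGTTT", "ACGTACGT"))
  withr::with_seed(7, {
    for (i in 1:5) {
      q <- rand_dna(sample(4:9, 1)); t <- rand_dna(sample(4:9, 1))
      got <- smith_waterman(q, t)
      want <- sw_oracle(q, t)
      expect_equal(if (nrow(got)) got$score else 0L, want)
    }
  })
})

test_that("Smith-Waterman agrees with Biostrings local alignment", {
  mat <-Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  withr::with_seed(42, {
    for (i in 1:20) {
      q <- rand_dna(sample(20:80, 1)); t <- rand_dna(sample(20:80, 1))
      ref <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 3)
      got <- smith_waterman(q, t)
      expect_equal(if (nrow(got)) got$score else 0,
                   max(0, Biostrings::score(ref)))
    }
  })
})

test_that("k-mer index stores every occurrence and skips N windows", {
  idx <- build_kmer_index(c(t1 = "ACGTACGT"), k = 8)
  expect_equal(kmer_index_size(idx), 1)
  idx <- build_kmer_index(c(t1 = "AAAAAAAAAA"), k = 8)
  expect_equal(kmer_lookup(idx, "AAAAAAAA")$offset, c(0L, 1L, 2L))
  idx <- build_kmer_index(c(t1 = "AAAANAAAANAAAA"), k = 8)
  expect_equal(kmer_index_size(idx), 0)
  expect_error(build_kmer_index(c(t1 = "ACGT"), k = 8), "larger than every")
  expect_error(build_kmer_index(c(t1 = "ACGTACGTT"), k = 4), "at least 8")
})

test_that("seeded aligner finds verbatim and reverse-complement copies", {
  withr::with_seed(11, g <- rand_dna(10000))
  idx <- build_kmer_index(c(chr = g), k = 13)
  read <- substr(g, 2001, 2090)
  hit <- seeded_local_align(c(r = read), idx, min_score = 30)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(c(hit$t_start, hit$t_end), c(2000L, 2090L))
  expect_equal(c(hit$q_start, hit$q_end), c(0L, 90L))
  expect_equal(hit$identity, 1)
  rhit <- seeded_local_align(c(r = revcomp(read)), idx, min_score = 30)
  expect_equal(rhit$strand, "-")
  expect_equal(c(rhit$t_start, rhit$t_end), c(2000L, 2090L))
  expect_equal(c(rhit$q_start, rhit$q_end), c(0L, 90L))
  expect_equal(nrow(seeded_local_align(c(r = rand_dna(50)), idx,
                                       min_score = 30)), 0L)
})

test_that("a split read yields one hit per target, each matching the oracle", {
  withr::with_seed(12, { a <- rand_dna(2000); b <- rand_dna(2000) })
  idx <- build_kmer_index(c(A = a, B = b), k = 13)
  read <- paste0(substr(a, 501, 545), substr(b, 901, 945))
  hits <- seeded_local_align(c(r = read), idx, min_score = 20)
  hits <- hits[order(hits$target_id), ]
  expect_equal(hits$target_id, c("A", "B"))
  expect_equal(hits$score[1], smith_waterman(read, a)$score)
  expect_equal(hits$score[2], smith_waterman(read, b)$score)
  # each hit covers (about) its 45 bp half; chance matches at the junction
  # may extend an alignment by a base or two
  expect_true(all(abs((hits$q_end - hits$q_start) - 45L) <= 3L))
})

test_that("strand symmetry maps query coordinates through x -> L - x", {
  withr::with_seed(13, g <- rand_dna(5000))
  idx <- build_kmer_index(c(chr = g), k = 13)
  read <- paste0(rand_dna(10), substr(g, 1001, 1060), rand_dna(5))
  fwd <- seeded_local_align(c(r = read), idx, min_score = 25)
  rev <- seeded_local_align(c(r = revcomp(read)), idx, min_score = 25)
  L <- nchar(read)
  expect_equal(rev$strand, "-")
  expect_equal(rev$q_start, L - fwd$q_end)
  expect_equal(rev$q_end, L - fwd$q_start)
  expect_equal(rev$t_start, fwd$t_start)
  expect_equal(rev$score, fwd$score)
})

test_that("one mismatch never increases the alignment score", {
  withr::with_seed(14, g <- rand_dna(3000))
  idx <- build_kmer_index(c(chr = g), k = 13)
  read <- substr(g, 101, 190)
  base <- seeded_local_align(c(r = read), idx, min_score = 20)$score
  for (pos in c(1L, 45L, 90L)) {
    mut <- read
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, pos, pos))[1]
    s <- seeded_local_align(c(r = mut), idx, min_score = 20)$score
    expect_lte(max(s, 0L), base)
  }
})

test_that("seeded score equals Smith-Waterman when an exact seed exists", {
  withr::with_seed(15, {
    for (i in 1:50) {
      t <- rand_dna(sample(60:200, 1))
      core_len <- sample(25:45, 1)  # long enough that the optimum contains the seed
      ts <- sample(nchar(t) - core_len, 1)
      q <- paste0(rand_dna(sample(0:30, 1)),
                  substr(t, ts, ts + core_len - 1L),
                  rand_dna(sample(0:30, 1)))
      idx <- build_kmer_index(c(t = t), k = 13)
      hits <- seeded_local_align(c(q = q), idx, min_score = 10)
      expect_gt(nrow(hits), 0L)
      expect_equal(max(hits$score), smith_waterman(q, t)$score)
    }
  })
})
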