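test_that("genome generation is seeded, sized and GC-balanced", {
  g1 <- generate_genome(2, 1e4, seed = 5)
  g2 <- generate_genome(2, 1e4, seed = 5)
  expect_identical(g1, g2)
  expect_equal(g1$name, c("chr1", "chr2"))
  expect_equal(nchar(g1$sequence), c(1e4, 1e4))
  big <- generate_genome(1, 1e5, gc = 0.5, seed = 6)
  gc_obs <- sum(strsplit(big$sequence, "")[[1]] %in% c("G", "C")) / 1e5
  expect_gt(gc_obs, 0.49)
  expect_lt(gc_obs, 0.51)
  expect_false(identical(generate_genome(1, 1e4, seed = 1)$sequence,
                         generate_genome(1, 1e4, seed = 2)$sequence))
})

test_that("planting builds the TSD-element-TSD structure on both haplotypes", {
  g <- generate_genome(1, 2e4, seed = 7)
  tn <- synthetic_tnt1()
  planted <- plant_insertions(g, tn, n = 1, tsd_length = 5, seed = 7,
                              end_margin = 1000, min_spacing = 1000)
  p <- planted$truth$position[1]
  expect_equal(planted$truth$tsd_length, 5L)
  elem <- if (planted$truth$orientation == "+") tn$sequence else revcomp(tn$sequence)
  expected_junction <- paste0(substr(g$sequence, p - 4, p), elem,
                              substr(g$sequence, p - 4, p))
  for (h in 1:2) {
    hap <- planted$haplotypes$sequence[planted$haplotypes$haplotype == h]
    expect_equal(nchar(hap), 2e4 + 5300 + 5)
    expect_true(grepl(expected_junction, hap, fixed = TRUE))
  }
})

test_that("heterozygous insertions only alter haplotype 1", {
  g <- generate_genome(1, 3e4, seed = 8)
  tn <- synthetic_tnt1()
  planted <- plant_insertions(g, tn, n = 4, het_fraction = 0.5, seed = 8,
                              end_margin = 1000, min_spacing = 2000)
  expect_equal(sum(planted$truth$zygosity == "heterozygous"), 2L)
  n_hom <- sum(planted$truth$zygosity == "homozygous")
  hap1 <- planted$haplotypes$sequence[planted$haplotypes$haplotype == 1]
  hap2 <- planted$haplotypes$sequence[planted$haplotypes$haplotype == 2]
  expect_equal(nchar(hap1), 3e4 + 4 * 5305)
  expect_equal(nchar(hap2), 3e4 + n_hom * 5305)
})

test_that("reverse-orientation insertions carry the reverse complement", {
  g <- generate_genome(1, 2e4, seed = 12)
  tn <- synthetic_tnt1()
  for (s in 1:6) {
    planted <- plant_insertions(g, tn, n = 1, seed = s, end_margin = 1000,
                                min_spacing = 1000)
    hap <- planted$haplotypes$sequence[1]
    want <- if (planted$truth$orientation == "-") revcomp(tn$sequence) else tn$sequence
    expect_true(grepl(want, hap, fixed = TRUE))
  }
  expect_setequal(
    vapply(1:6, function(s) plant_insertions(g, tn, 1, seed = s,
                                             end_margin = 1000,
                                             min_spacing = 1000)$truth$orientation,
           character(1)) |> unique(), c("+", "-"))
})

test_that("unplaceable insertion requests fail with advice", {
  g <- generate_genome(1, 1e4, seed = 9)
  expect_error(plant_insertions(g, synthetic_tnt1(), n = 50, seed = 1),
               "longer genome")
})

test_that("read simulation hits the coverage and insert-length targets", {
  g <- generate_genome(1, 6e4, seed = 10)
  haps <- tibble::tibble(chrom = "chr1", haplotype = 1:2,
                         sequence = rep(g$sequence, 2))
  pairs <- simulate_read_pairs(haps, coverage = 40, seed = 10)
  params <- attr(pairs, "read_params")
  total_bases <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
  expect_lt(abs(total_bases - 40 * 6e4) / (40 * 6e4), 0.02)
  flen <- params$fragment_lengths[[1]]
  expect_gte(length(flen), 1e4)
  expect_lt(abs(mean(flen) - 500) / 500, 0.02)
  expect_identical(pairs, simulate_read_pairs(haps, coverage = 40, seed = 10))
  expect_false(identical(pairs$seq1,
                         simulate_read_pairs(haps, coverage = 40,
                                             seed = 11)$seq1))
})

test_that("error-free reads are exact haplotype substrings", {
  g <- generate_genome(1, 2e4, seed = 11)
  haps <- tibble::tibble(chrom = "chr1", haplotype = 1:2,
                         sequence = rep(g$sequence, 2))
  pairs <- simulate_read_pairs(haps, coverage = 2, error_rate = 0, seed = 11)
  idx <- sample(nrow(pairs), 25)
  for (i in idx) {
    expect_true(grepl(pairs$seq1[i], g$sequence, fixed = TRUE))
    expect_true(grepl(revcomp(pairs$seq2[i]), g$sequence, fixed = TRUE))
  }
  expect_true(all(phred_scores(pairs$qual1[idx[1]])[[1]] == 35L))
})

test_that("errored bases are flagged at low quality", {
  g <- generate_genome(1, 2e4, seed = 13)
  haps <- tibble::tibble(chrom = "chr1", haplotype = 1, sequence = g$sequence)
  pairs <- simulate_read_pairs(haps, coverage = 4, error_rate = 0.05, seed = 13)
  q <- unlist(phred_scores(pairs$qual1))
  expect_setequal(unique(q), c(35L, 15L))
  err_frac <- mean(q == 15L)
  expect_gt(err_frac, 0.03); expect_lt(err_frac, 0.07)
})

test_that("FASTQ output round-trips the simulated pairs", {
  g <- generate_genome(1, 1e4, seed = 14)
  haps <- tibble::tibble(chrom = "chr1", haplotype = 1, sequence = g$sequence)
  pairs <- simulate_read_pairs(haps, coverage = 1, seed = 14)
  prefix <- file.path(withr::local_tempdir(), "reads")
  write_pair_fastq(pairs, prefix)
  back <- pair_reads(read_fastq(paste0(prefix, "_1.fastq"), mate = 1),
                     read_fastq(paste0(prefix, "_2.fastq"), mate = 2))
  expect_equal(back$pair_id, pairs$pair_id)
  expect_equal(back$seq1, pairs$seq1)
  expect_equal(back$qual2, pairs$qual2)
})

test_that("recovery scoring handles exact, empty and spurious call sets", {
  truth <- tibble::tibble(chrom = "chr1", position = c(1000L, 5000L),
                          orientation = "+", zygosity = "homozygous",
                          tsd_length = 5L)
  calls <- tibble::tibble(insertion_id = c("Insertion-1", "Insertion-2"),
                          chrom = "chr1", position = c(1000L, 5000L),
                          confidence = "HC", support_total = 5L)
  ev <- evaluate_recovery(calls, truth)
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$precision, 1)
  expect_equal(ev$metrics$mean_abs_offset, 0)
  ev0 <- evaluate_recovery(calls[0, ], truth)
  expect_equal(ev0$metrics$recall, 0)
  spur <- dplyr::bind_rows(calls, tibble::tibble(
    insertion_id = "Insertion-3", chrom = "chr1", position = 15000L,
    confidence = "HC", support_total = 4L))
  evs <- evaluate_recovery(spur, truth)
  expect_lt(evs$metrics$precision, 1)
  expect_equal(evs$metrics$max_nearest_truth_distance, 10000)
})

test_that("greedy matching is one-to-one by distance", {
  truth <- tibble::tibble(chrom = "chr1", position = 1000L)
  calls <- tibble::tibble(insertion_id = c("a", "b"), chrom = "chr1",
                          position = c(1002L, 1005L), confidence = "HC",
                          support_total = 3L)
  ev <- evaluate_recovery(calls, truth)
  expect_equal(ev$metrics$n_matched, 1L)
  expect_equal(ev$per_locus$matched, c(TRUE, FALSE))  # nearest call wins
})
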