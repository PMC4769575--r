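tn <- synthetic_tnt1()

test_that("a read identical to a terminal is element; no seed means genomic", {
  cls <- classify_reads(c(tn$left_terminal, tn$right_terminal,
                          revcomp(tn$left_terminal)), tn)
  expect_equal(cls$label, rep("element", 3))
  withr::with_seed(21, cls2 <- classify_reads(rand_dna(90), tn))
  expect_equal(cls2$label, "genomic")
  expect_true(is.na(cls2$end))
})

test_that("junction reads split at the exact offset with the right end", {
  withr::with_seed(22, flank <- rand_dna(200))
  # last 40 bp of the right terminal followed by 50 bp of genome
  r_re <- junction_read(flank, tn$sequence, 40, "right")
  cls <- classify_reads(r_re, tn)
  expect_equal(cls$label, "hybrid")
  expect_equal(cls$end, "RE")
  expect_equal(cls$junction_offset, 40L)
  expect_equal(cls$genomic_side, "right")
  expect_equal(c(cls$elem_start, cls$elem_end), c(0L, 40L))
  # genomic then the element's first 40 bp: a left-junction read
  r_le <- junction_read(flank, tn$sequence, 40, "left")
  cls <- classify_reads(r_le, tn)
  expect_equal(cls$label, "hybrid")
  expect_equal(cls$end, "LE")
  expect_equal(cls$junction_offset, 50L)
  expect_equal(cls$genomic_side, "left")
  # the reverse-complemented read carries the same junction, mirrored
  cls <- classify_reads(revcomp(r_le), tn)
  expect_equal(cls$label, "hybrid")
  expect_equal(cls$end, "LE")
  expect_equal(cls$strand, "-")
  expect_equal(cls$junction_offset, 40L)
  expect_equal(cls$genomic_side, "right")
})

test_that("each portion of a hybrid read matches its source by the oracle", {
  withr::with_seed(23, flank <- rand_dna(200))
  read <- junction_read(flank, tn$sequence, 40, "right")
  elem_part <- smith_waterman(substr(read, 1, 40), tn$right_terminal)
  expect_equal(elem_part$score, 40L)
  gen_part <- smith_waterman(substr(read, 41, 90), flank)
  expect_equal(gen_part$score, 50L)
})

test_that("too-short element or genomic portions do not call hybrid", {
  withr::with_seed(24, flank <- rand_dna(200))
  cls <- classify_reads(junction_read(flank, tn$sequence, 14, "left"), tn)
  expect_equal(cls$label, "genomic")  # 14 < min_element_match
  cls <- classify_reads(junction_read(flank, tn$sequence, 75, "left"), tn)
  expect_equal(cls$label, "genomic")  # genomic tail 15 < min_genomic_tail
})

test_that("an unanchored internal terminal match stays genomic", {
  withr::with_seed(25, flank <- rand_dna(200))
  # element bases 20..59 of the left terminal: not the outward edge
  read <- paste0(substr(tn$sequence, 21, 60), substr(flank, 1, 50))
  expect_equal(classify_reads(read, tn)$label, "genomic")
})

test_that("a read wholly inside an LTR is element, never hybrid", {
  # with whole-LTR terminals every in-LTR read matches both baits fully
  ltr <- substr(tn$sequence, 1, 610)
  tn_full <- load_transposon(tn$sequence, ltr_length = 610,
                             terminal_length = 610)
  for (off in c(1L, 200L, 521L)) {
    cls <- classify_reads(substr(ltr, off, off + 89L), tn_full)
    expect_equal(cls$label, "element")
  }
})

test_that("pair types cover all nine label combinations", {
  labs <- c("element", "genomic", "hybrid")
  combos <- expand.grid(a = labs, b = labs, stringsAsFactors = FALSE)
  got <- pair_type_from_labels(combos$a, combos$b)
  want <- c(1L, 5L, 3L,  # element x (e, g, h)
            5L, 2L, 4L,  # genomic x (e, g, h)
            3L, 4L, 3L)  # hybrid  x (e, g, h)
  expect_equal(got, want)
})

test_that("hybrid extraction returns the genomic portion in read orientation", {
  withr::with_seed(26, flank <- rand_dna(200))
  r_le <- junction_read(flank, tn$sequence, 40, "left")       # genomic left
  r_re <- junction_read(flank, tn$sequence, 40, "right")      # genomic right
  pairs <- make_pairs(c(r_le, revcomp(r_le)), c(r_re, rand_dna(90)))
  classified <- classify_pairs(pairs, tn)
  hyb <- extract_hybrids(classified)
  h1 <- hyb[hyb$read_id == "p001/1", ]
  expect_equal(h1$genomic_fragment, substr(r_le, 1, 50))
  expect_equal(h1$element_side, "right")
  h2 <- hyb[hyb$read_id == "p001/2", ]
  expect_equal(h2$genomic_fragment, substr(r_re, 41, 90))
  expect_equal(h2$element_side, "left")
  # '-' strand hybrid: fragment still reported as read bases
  h3 <- hyb[hyb$read_id == "p002/1", ]
  expect_equal(h3$genomic_fragment, substr(revcomp(r_le), 41, 90))
  expect_equal(h3$genomic_fragment, revcomp(substr(r_le, 1, 50)))
})

test_that("classification is exhaustive and deterministic", {
  withr::with_seed(27, {
    reads <- c(replicate(20, rand_dna(90)),
               junction_read(rand_dna(100), tn$sequence, 30, "left"),
               tn$left_terminal)
  })
  c1 <- classify_reads(reads, tn)
  c2 <- classify_reads(reads, tn)
  expect_identical(c1, c2)
  expect_true(all(c1$label %in% c("element", "genomic", "hybrid")))
})

test_that("hybrids explainable by the reference alone are dropped", {
  withr::with_seed(28, g <- rand_dna(5000))
  idx <- build_kmer_index(c(chr = g), k = 13)
  real <- junction_read(substr(g, 1001, 1100), tn$sequence, 40, "left")
  hybrids <- tibble::tibble(
    read_id = c("real", "fake"), end = "LE",
    elem_start = c(50L, 50L), elem_end = c(90L, 90L),
    junction_offset = 50L,
    genomic_fragment = c(substr(real, 1, 50), substr(g, 2001, 2050)),
    element_side = "right",
    read_sequence = c(real, substr(g, 2001, 2090)))  # fake = pure genome read
  kept <- drop_reference_hybrids(hybrids, idx)
  expect_equal(kept$read_id, "real")
  expect_equal(attr(kept, "n_reference_matching"), 1L)
})
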