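make_hits <- function(breakpoints, chrom = "chr1", kind = "hybrid_LE",
                      ids = NULL) {
  tibble::tibble(
    evidence_id = ids %||% sprintf("e%03d", seq_along(breakpoints)),
    evidence_kind = rep_len(kind, length(breakpoints)),
    chrom = rep_len(chrom, length(breakpoints)),
    breakpoint = as.integer(breakpoints),
    strand = "+",
    t_start = as.integer(breakpoints) - 50L,
    t_end = as.integer(breakpoints),
    identity = 1)
}

test_that("clustering joins neighbours and takes the median position", {
  cl <- cluster_evidence(make_hits(c(1000, 1004, 1010)), window = 100)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$position, 1004L)
  cl2 <- cluster_evidence(make_hits(c(1000, 5000)), window = 100)
  expect_equal(nrow(cl2), 2L)
  # even count: lower of the two central values
  cl3 <- cluster_evidence(make_hits(c(1000, 1004)), window = 100)
  expect_equal(cl3$position, 1000L)
})

test_that("LE and RE evidence within the window merge into one locus", {
  hits <- dplyr::bind_rows(
    make_hits(1000, kind = "hybrid_LE", ids = "le1"),
    make_hits(1005, kind = "hybrid_RE", ids = "re1"),
    make_hits(950, kind = "node", ids = "node_1"))
  cl <- cluster_evidence(hits, window = 100)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support_hybrid_LE, 1L)
  expect_equal(cl$support_hybrid_RE, 1L)
  expect_equal(cl$support_node, 1L)
  expect_equal(cl$support_total, 3L)
})

test_that("confidence is HC at three distinct supports, LC below", {
  for (n in 1:4) {
    cl <- cluster_evidence(make_hits(rep(1000, n)), window = 100)
    conf <- assign_confidence(cl, hc_min_support = 3)$confidence
    expect_equal(conf, if (n >= 3) "HC" else "LC")
  }
})

test_that("numbering sorts HC first, then chromosome rank and position", {
  loci <- dplyr::bind_rows(
    assign_confidence(cluster_evidence(make_hits(100, chrom = "chr2"))),
    assign_confidence(cluster_evidence(make_hits(rep(500, 3), chrom = "chr1",
                                                 ids = paste0("a", 1:3)))),
    assign_confidence(cluster_evidence(make_hits(rep(100, 4), chrom = "chr2",
                                                 ids = paste0("b", 1:4)))),
    assign_confidence(cluster_evidence(make_hits(900, chrom = "scaffold7",
                                                 ids = "s1"))))
  out <- number_loci(loci, chrom_order = c("chr1", "chr2"))
  expect_equal(out$insertion_id, paste0("Insertion-", 1:4))
  expect_equal(out$chrom, c("chr1", "chr2", "chr2", "scaffold7"))
  expect_equal(out$confidence, c("HC", "HC", "LC", "LC"))
  # LC loci get the largest numbers; scaffolds rank after chromosomes
  expect_equal(out$insertion_id[out$chrom == "scaffold7"], "Insertion-4")
  # numbering is a pure function: shuffled input gives the same table
  shuf <- loci[c(3, 1, 4, 2), ]
  expect_equal(number_loci(shuf, c("chr1", "chr2")), out)
})

test_that("a single locus is Insertion-1", {
  loci <- assign_confidence(cluster_evidence(make_hits(1000)))
  expect_equal(number_loci(loci, "chr1")$insertion_id, "Insertion-1")
})

test_that("breakpoints derive from the junction-proximal end of the mapping", {
  withr::with_seed(41, g <- rand_dna(20000))
  idx <- build_kmer_index(c(chr1 = g), k = 13)
  p <- 5000L
  frag_up <- substr(g, p - 49L, p)      # upstream flank, junction at its right
  hybrids <- tibble::tibble(
    read_id = c("h_plus", "h_minus"), end = "LE",
    elem_start = 50L, elem_end = 90L, junction_offset = 50L,
    genomic_fragment = c(frag_up, revcomp(frag_up)),
    element_side = c("right", "left"),
    read_sequence = c(paste0(frag_up, rand_dna(40)),
                      paste0(revcomp(frag_up), rand_dna(40))))
  hits <- map_evidence(hybrids, NULL, idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$breakpoint, c(p, p))  # same junction from both strands
  expect_setequal(hits$strand, c("-", "+"))
  # downstream flank: junction at the fragment's left edge
  frag_dn <- substr(g, p + 1L, p + 50L)
  hyb2 <- tibble::tibble(read_id = "h_re", end = "RE", elem_start = 0L,
                         elem_end = 40L, junction_offset = 40L,
                         genomic_fragment = frag_dn, element_side = "left",
                         read_sequence = paste0(rand_dna(40), frag_dn))
  expect_equal(map_evidence(hyb2, NULL, idx)$breakpoint, p + 1L)
})

test_that("node breakpoints face the element per their end group", {
  withr::with_seed(42, g <- rand_dna(20000))
  idx <- build_kmer_index(c(chr1 = g), k = 13)
  nodes <- tibble::tibble(node_id = c("node_1", "node_2"),
                          sequence = c(substr(g, 4500, 4950),
                                       substr(g, 5100, 5400)),
                          k = 21L, n_support = 3L,
                          support_reads = list("r1", "r2"),
                          end_group = c("LE", "RE"))
  hits <- map_evidence(NULL, nodes, idx)
  expect_equal(hits$breakpoint[hits$evidence_id == "node_1"], 4950L)
  expect_equal(hits$breakpoint[hits$evidence_id == "node_2"], 5100L)
})

test_that("evidence mapping equally well to two places is discarded", {
  withr::with_seed(43, {
    core <- rand_dna(60)
    g <- paste0(rand_dna(3000), core, rand_dna(3000), core, rand_dna(3000))
  })
  idx <- build_kmer_index(c(chr1 = g), k = 13)
  hybrids <- tibble::tibble(read_id = "dup", end = "LE", elem_start = 60L,
                            elem_end = 90L, junction_offset = 60L,
                            genomic_fragment = core, element_side = "right",
                            read_sequence = paste0(core, rand_dna(30)))
  hits <- map_evidence(hybrids, NULL, idx)
  expect_equal(nrow(hits), 0L)
  expect_equal(map_report(hits)$n_multimapped, 1L)
})

test_that("zygosity follows spanning pairs and junction support", {
  withr::with_seed(44, g <- rand_dna(30000))
  idx <- build_kmer_index(c(chr1 = g), k = 13)
  bp_spanned <- 10000L; bp_clear <- 20000L
  # fragments spanning bp_spanned: mates on opposite sides
  starts <- seq(bp_spanned - 400L, bp_spanned - 200L, by = 50L)
  pairs <- make_pairs(substring(g, starts, starts + 89L),
                      revcomp(substring(g, starts + 410L, starts + 499L)))
  placed <- place_read_pairs(pairs, idx)
  expect_equal(nrow(placed), length(starts))
  loci <- dplyr::bind_rows(
    number_loci(assign_confidence(cluster_evidence(
      make_hits(rep(bp_spanned, 4)))), "chr1"),
    number_loci(assign_confidence(cluster_evidence(
      make_hits(rep(bp_clear, 4), ids = paste0("z", 1:4)))), "chr1"))
  loci$insertion_id <- c("Insertion-1", "Insertion-2")
  z <- estimate_zygosity(loci, placed, min_span = 3, hc_min_support = 3)
  expect_equal(z$spanning_pairs, c(length(starts), 0L))
  expect_equal(z$zygosity, c("heterozygous", "homozygous"))
  # one junction read and one spanning pair: undetermined
  weak <- number_loci(assign_confidence(cluster_evidence(
    make_hits(bp_spanned + 5000L))), "chr1")
  onepair <- place_read_pairs(
    make_pairs(substring(g, bp_spanned + 4700L, bp_spanned + 4789L),
               revcomp(substring(g, bp_spanned + 5110L, bp_spanned + 5199L))),
    idx)
  zweak <- estimate_zygosity(weak, onepair)
  expect_equal(zweak$spanning_pairs, 1L)
  expect_equal(zweak$zygosity, "undetermined")
})

test_that("every HC locus satisfies the support floor by construction", {
  withr::with_seed(45, bps <- sort(sample(1e6, 60, replace = TRUE)))
  loci <- make_hits(bps) |>
    cluster_evidence(window = 600) |>
    assign_confidence()
  expect_true(all(loci$support_total[loci$confidence == "HC"] >= 3))
  expect_true(all(loci$support_total >= 1))
})

test_that("BED export converts to 0-based half-open intervals", {
  loci <- number_loci(assign_confidence(cluster_evidence(
    make_hits(rep(1000, 3)))), "chr1")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(loci, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, 999L)
  expect_equal(bed$V3, 1000L)
  expect_equal(bed$V4, "Insertion-1")
  expect_equal(bed$V5, 3L)
})
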