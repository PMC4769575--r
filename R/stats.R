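# Companion statistics: FST deduplication and overlap, Mendelian segregation
# chi-square, fold-coverage estimation.

#' Deduplicate flanking-sequence-tag records across experiments
#'
#' Two mapped records on the same chromosome within `window` bases are the
#' same insertion (single-linkage). Sources are processed in their order of
#' first appearance (e.g. R0, then R1, then BC1F2): a record is "novel" when
#' no record from an earlier source matches it. Unmapped records are compared
#' by exact sequence identity when a `sequence` column is supplied, otherwise
#' kept distinct.
#'
#' @param records Tibble with `source`, `chrom` (or `"unmapped"`), `position`
#'   (NA when unmapped) and optionally `sequence`.
#' @param window Matching window in bases (default 100, consistent with the
#'   locus clustering window).
#' @return The unique records (first representative of each duplicate group),
#'   with a `novelty_report` attribute: per-source totals, novel counts and
#'   redundant counts. Deduplication is idempotent.
#' @export
dedup_fsts <- function(records, window = 100L) {
  empty_rep <- tibble::tibble(source = character(), n_records = integer(),
                              n_novel = integer(), n_redundant = integer())
  if (nrow(records) == 0L) {
    attr(records, "novelty_report") <- empty_rep
    return(records)
  }
  src_order <- unique(records$source)
  rec <- dplyr::mutate(records,
                       .src_rank = match(.data$source, src_order),
                       .row = dplyr::row_number()) |>
    dplyr::arrange(.data$.src_rank, .data$.row)
  n <- nrow(rec)
  group <- rep(NA_integer_, n)
  next_group <- 0L
  for (i in seq_len(n)) {
    gi <- NA_integer_
    for (j in seq_len(i - 1L)) {
      same <- if (rec$chrom[i] == "unmapped" || rec$chrom[j] == "unmapped") {
        rec$chrom[i] == "unmapped" && rec$chrom[j] == "unmapped" &&
          "sequence" %in% names(rec) &&
          !is.na(rec$sequence[i]) && !is.na(rec$sequence[j]) &&
          rec$sequence[i] == rec$sequence[j]
      } else {
        rec$chrom[i] == rec$chrom[j] &&
          abs(rec$position[i] - rec$position[j]) <= window
      }
      if (same) { gi <- group[j]; break }
    }
    if (is.na(gi)) { next_group <- next_group + 1L; gi <- next_group }
    group[i] <- gi
  }
  rec$.group <- group
  # a record is novel iff no earlier-source record shares its group
  rec$.novel <- purrr::map2_lgl(rec$.group, rec$.src_rank, function(g, r) {
    !any(rec$.group == g & rec$.src_rank < r)
  })
  report <- rec |>
    dplyr::group_by(source = .data$source) |>
    dplyr::summarise(n_records = dplyr::n(),
                     n_novel = sum(.data$.novel & !duplicated(.data$.group)),
                     n_redundant = dplyr::n() -
                       sum(.data$.novel & !duplicated(.data$.group)),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$source, src_order))
  uniq <- rec[!duplicated(rec$.group), , drop = FALSE] |>
    dplyr::select(-dplyr::starts_with("."))
  attr(uniq, "novelty_report") <- report
  uniq
}

#' Retrieve the per-source novelty report from [dedup_fsts()]
#' @param records Output of [dedup_fsts()].
#' @return Tibble with `source`, `n_records`, `n_novel`, `n_redundant`.
#' @export
novelty_report <- function(records) {
  rep <- attr(records, "novelty_report")
  if (is.null(rep)) stop("no novelty_report attribute; was dedup_fsts() run?")
  rep
}

#' Overlap two insertion-site sets (Venn counts)
#'
#' Greedy one-to-one nearest-first matching of records on the same chromosome
#' within `window` bases; both sets are assumed internally deduplicated. The
#' three counts partition the union.
#'
#' @param a,b Tibbles with `chrom` and `position` columns.
#' @param window Matching window in bases (default 100).
#' @return One-row tibble: `a_only`, `b_only`, `shared`.
#' @export
overlap_sets <- function(a, b, window = 100L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(a_only = nrow(a), b_only = nrow(b), shared = 0L))
  }
  cand <- tidyr::expand_grid(ai = seq_len(nrow(a)), bi = seq_len(nrow(b))) |>
    dplyr::filter(a$chrom[.data$ai] == b$chrom[.data$bi]) |>
    dplyr::mutate(dist = abs(a$position[.data$ai] - b$position[.data$bi])) |>
    dplyr::filter(.data$dist <= window) |>
    dplyr::arrange(.data$dist, .data$ai, .data$bi)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b)); shared <- 0L
  for (i in seq_len(nrow(cand))) {
    ai <- cand$ai[i]; bi <- cand$bi[i]
    if (!used_a[ai] && !used_b[bi]) {
      used_a[ai] <- TRUE; used_b[bi] <- TRUE; shared <- shared + 1L
    }
  }
  tibble::tibble(a_only = nrow(a) - shared, b_only = nrow(b) - shared,
                 shared = shared)
}

#' Chi-square test of Mendelian segregation
#'
#' Pearson goodness-of-fit of observed wild-type/mutant counts against an
#' expected ratio (3:1 by default, the single-recessive-locus expectation in
#' an F2), without continuity correction; the p-value is the upper tail of
#' the chi-square distribution with 1 degree of freedom.
#'
#' @param n_wildtype,n_mutant Observed counts (non-negative).
#' @param ratio Expected `c(wildtype, mutant)` ratio (default `c(3, 1)`).
#' @return One-row tibble: `n_wildtype`, `n_mutant`, `statistic`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' chi_square_segregation(248, 87)  # statistic 0.168
chi_square_segregation <- function(n_wildtype, n_mutant, ratio = c(3, 1)) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            n_wildtype >= 0, n_mutant >= 0)
  total <- n_wildtype + n_mutant
  if (total == 0) stop("zero total count")
  expected <- total * ratio / sum(ratio)
  stat <- sum((c(n_wildtype, n_mutant) - expected)^2 / expected)
  tibble::tibble(n_wildtype = n_wildtype, n_mutant = n_mutant,
                 statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fold-coverage estimate from total clean bases
#'
#' Fold coverage as total clean bases over genome size, reported both
#' unrounded and floored to an integer fold (the convention under which
#' 44.06 prints as 44X).
#'
#' @param clean_bases Total sequenced clean bases.
#' @param genome_size Reference genome size in bases (> 0).
#' @return One-row tibble: `fold` (integer floor) and `ratio` (unrounded).
#' @export
#' @examples
#' coverage_estimate(16.92e9, 384e6)  # 44X
coverage_estimate <- function(clean_bases, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  ratio <- clean_bases / genome_size
  tibble::tibble(fold = as.integer(floor(ratio)), ratio = ratio)
}
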