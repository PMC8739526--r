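empty_iv <- function() tibble::tibble(start = integer(), end = integer())

test_that("editing rate is the exact quotient with guarded domain", {
  expect_equal(compute_editing_rate(3L, 5L), 0.6)
  expect_equal(compute_editing_rate(0L, 10L), 0)
  expect_equal(compute_editing_rate(19L, 20L), 0.95)
  expect_error(compute_editing_rate(0L, 0L), "undefined")
  expect_error(compute_editing_rate(6L, 5L), "alt_reads")
})

test_that("candidates require strand-consistent mismatches within the flank", {
  genes <- dplyr::bind_rows(
    mini_gene("gPlus", strand = "+"),
    mini_gene("gMinus",
      strand = "-", chrom = "chr2",
      start = 500001L, end = 510000L
    ) |>
      dplyr::mutate(
        utr5 = list(empty_iv()), exons = list(empty_iv()),
        cds = list(empty_iv()), utr3 = list(empty_iv())
      )
  )
  variants <- tibble::tibble(
    chrom = c("chr1", "chr2", "chr2", "chr1", "chr1"),
    pos = c(105000L, 505000L, 480001L, 105000L, 300000L),
    ref_base = c("A", "A", "T", "C", "A"),
    alt_base = c("G", "G", "C", "T", "G"),
    total_reads = 20L, alt_reads = 10L, sample_id = "S1"
  )
  cand <- select_candidates(variants, genes)
  # A>G inside the + gene: candidate on +
  expect_true(any(cand$pos == 105000L & cand$strand == "+" &
    cand$gene_id == "gPlus"))
  # A>G inside a - gene only: strand-inconsistent, not a candidate
  expect_false(any(cand$pos == 505000L))
  # T>C 20 kb upstream (genomic left) of the - gene: within flank, assigned
  expect_true(any(cand$pos == 480001L & cand$strand == "-" &
    cand$gene_id == "gMinus"))
  # the C>T variant at the same position is not a second candidate;
  # A>G beyond every flank is never a candidate
  expect_equal(sum(cand$pos == 105000L), 1L)
  expect_false(any(cand$pos == 300000L))
})

test_that("gene assignment prefers containment, then distance, then gene_id", {
  g1 <- mini_gene("gB", start = 100001L, end = 110000L)
  g2 <- mini_gene("gA", start = 120001L, end = 130000L)
  genes <- dplyr::bind_rows(g1, g2)
  v <- tibble::tibble(
    chrom = "chr1", pos = c(109999L, 115001L),
    ref_base = "A", alt_base = "G",
    total_reads = 10L, alt_reads = 5L, sample_id = "S1"
  )
  cand <- select_candidates(v, genes)
  # inside gB although closer to gA boundary region
  expect_equal(cand$gene_id[cand$pos == 109999L], "gB")
  # equidistant (5001 bp to gB end, 5000 to gA start): nearer gene wins
  expect_equal(cand$gene_id[cand$pos == 115001L], "gA")

  # exact tie in distance: lexicographic gene_id
  v2 <- tibble::tibble(
    chrom = "chr1", pos = 115000L, ref_base = "A", alt_base = "G",
    total_reads = 10L, alt_reads = 5L, sample_id = "S1"
  )
  g3 <- dplyr::bind_rows(
    mini_gene("gZ", start = 100001L, end = 110000L),
    mini_gene("gA", start = 120000L, end = 130000L)
  )
  expect_equal(select_candidates(v2, g3)$gene_id, "gA")
})

test_that("confident filter applies the printed inclusive bounds", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:4 * 100L, strand = "+", gene_id = "g",
    total_reads = c(5L, 20L, 100L, 20L),
    alt_reads = c(3L, 20L, 4L, 19L),
    sample_id = "S1"
  ) |>
    dplyr::mutate(editing_rate = alt_reads / total_reads)
  kept <- filter_confident(sites, editing_thresholds())
  # (5, 3, 0.60) retained at the boundary of all three criteria
  expect_true(100L %in% kept$pos)
  # homozygous-SNP-like (20, 20, 1.0) fails rate <= 0.95
  expect_false(200L %in% kept$pos)
  # (100, 4, 0.04) fails rate >= 0.05
  expect_false(300L %in% kept$pos)
  # 19/20 = 0.95 passes the upper bound inclusively
  expect_true(400L %in% kept$pos)
})

test_that("stricter thresholds keep a subset (filter monotonicity)", {
  set.seed(7)
  sites <- make_sites(
    seq_len(500L),
    total = 1L + rpois(500, 12), alt = 0L
  ) |>
    dplyr::mutate(
      alt_reads = rbinom(500, total_reads, runif(500)),
      editing_rate = alt_reads / total_reads
    )
  base <- filter_confident(sites, editing_thresholds())
  for (thr in list(
    editing_thresholds(min_total_reads = 10),
    editing_thresholds(min_alt_reads = 5),
    editing_thresholds(min_rate = 0.2, max_rate = 0.8)
  )) {
    strict <- filter_confident(sites, thr)
    expect_lte(nrow(strict), nrow(base))
    expect_true(all(
      paste(strict$chrom, strict$pos) %in% paste(base$chrom, base$pos)
    ))
  }
})

test_that("every retained site is (A>G, +) or (T>C, -)", {
  set.seed(19)
  p <- sim_params(
    n_genes = 20L, n_chroms = 1L, chrom_length = 400000L,
    n_repeats_per_class = c(SINE = 50L), n_editing_sites = 200L
  )
  ann <- generate_annotation(p, seed = 19L)
  variants <- random_variants(3000L, genome_length = 400000L, n_chroms = 1L)
  cand <- select_candidates(variants, ann$genes)
  conf <- filter_confident(cand)
  expect_true(all(cand$strand %in% c("+", "-")))
  joined <- dplyr::inner_join(
    conf,
    dplyr::select(variants, chrom, pos, ref_base, alt_base),
    by = c("chrom", "pos"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      (strand == "+" & ref_base == "A" & alt_base == "G") |
        (strand == "-" & ref_base == "T" & alt_base == "C")
    )
  expect_gte(nrow(joined), nrow(conf) * 0L)
  expect_true(all(
    paste(conf$chrom, conf$pos) %in% paste(joined$chrom, joined$pos)
  ))
})
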