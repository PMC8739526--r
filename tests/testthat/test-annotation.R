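test_that("gene-region categories follow the UTR > EXON > INTRON precedence", {
  g <- mini_gene()
  sites <- make_sites(c(100200L, 100700L, 105000L, 109200L, 109800L))
  ann <- assign_gene_region(sites, g)
  expect_equal(
    ann$region,
    c("UTR5", "EXON", "INTRON", "EXON", "UTR3")
  )
})

test_that("upstream/downstream categories are strand-oriented", {
  g_minus <- mini_gene("gM", strand = "-")
  # gene end + 700 in genomic coordinates is the 5' side of a minus gene
  ann <- assign_gene_region(make_sites(110700L, gene_id = "gM"), g_minus)
  expect_equal(ann$region, "PROMOTER")
  ann2 <- assign_gene_region(make_sites(99301L, gene_id = "gM"), g_minus)
  expect_equal(ann2$region, "DOWNSTREAM")
})

test_that("repeat assignment picks the innermost element, else NON_REPEAT", {
  repeats <- tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 1100L, 5000L),
    end = c(2000L, 1300L, 5100L),
    repeat_name = c("L1_outer", "B1_inner", "B2_far"),
    repeat_class = c("LINE", "SINE", "SINE"),
    subfamily = c("", "B1", "B2")
  ) |>
    dplyr::mutate(repeat_region_id = paste0(chrom, ":", start, "-", end, ":", repeat_name))
  sites <- make_sites(c(1200L, 1500L, 9000L))
  ann <- assign_repeats(sites, repeats)
  expect_equal(ann$repeat_class, c("SINE", "LINE", "NON_REPEAT"))
  expect_equal(ann$subfamily, c("B1", "", ""))
  expect_equal(ann$repeat_region_id[3], "")
})

test_that("summary tables conserve totals across all four breakdowns", {
  set.seed(31)
  p <- sim_params(
    n_genes = 25L, n_chroms = 1L, chrom_length = 400000L,
    n_repeats_per_class = c(SINE = 120L, LTR = 40L, LINE = 40L),
    n_editing_sites = 400L
  )
  ann <- generate_annotation(p, seed = 31L)
  truth <- generate_truth(ann, p, seed = 31L)
  sites <- truth |>
    dplyr::mutate(
      total_reads = 20L, alt_reads = 10L, editing_rate = 0.5,
      sample_id = "A1_CON"
    )
  sm <- summarize_regions(sites)
  n <- nrow(sites)
  expect_equal(sum(sm$region$n), n)
  expect_equal(sum(sm$repeat_status$n), n)
  expect_equal(sum(sm$repeat_class$n), n)
  expect_equal(
    sum(sm$sine_subfamily$n),
    sum(sites$repeat_class == "SINE")
  )
  expect_equal(
    sm$repeat_status$n[sm$repeat_status$group == "non_repeat"],
    sm$repeat_class$n[sm$repeat_class$group == "NON_REPEAT"]
  )
})

test_that("interval assignments match a brute-force containment scan", {
  set.seed(41)
  p <- sim_params(
    n_genes = 12L, n_chroms = 1L, chrom_length = 300000L,
    n_repeats_per_class = c(SINE = 60L, LINE = 25L),
    n_editing_sites = 0L
  )
  ann <- generate_annotation(p, seed = 41L)
  sites <- make_sites(sample.int(300000L, 500), gene_id = "x") |>
    dplyr::select(-gene_id) |>
    dplyr::mutate(gene_id = "unused")
  got <- assign_repeats(sites, ann$repeats)
  want <- vapply(
    seq_len(nrow(sites)),
    function(i) oracle_innermost_repeat(sites$chrom[i], sites$pos[i], ann$repeats),
    ""
  )
  expect_equal(got$repeat_region_id, want)
})

test_that("mirrored coordinates with flipped strands keep every category", {
  g <- mini_gene()
  L <- 1000000L
  pos <- c(99501L, 70001L, 100200L, 100700L, 105000L, 109800L, 110700L, 140000L)
  ann_fwd <- assign_gene_region(make_sites(pos), g)
  g_rev <- reflect_gene(g, L)
  ann_rev <- assign_gene_region(
    make_sites(reflect_pos(pos, L), strand = "-"), g_rev
  )
  expect_equal(ann_rev$region, ann_fwd$region)
})
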