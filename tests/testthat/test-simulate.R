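# small but non-trivial study configuration used across simulation tests
small_params <- function(...) {
  sim_params(
    n_genes = 30L, n_chroms = 2L, chrom_length = 400000L,
    n_repeats_per_class = c(SINE = 150L, LTR = 40L, LINE = 40L),
    n_editing_sites = 600L, depth_lambda = 30,
    ...
  )
}

test_that("the same seed reproduces every emitted file byte-for-byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_params(), seed = 101L, dir = d1)
  simulate_study(small_params(), seed = 101L, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = paste("file", f)
    )
  }
  expect_setequal(list.files(d1), list.files(d2))
})

test_that("emitted VCFs parse with zero skipped records and valid depths", {
  st <- simulate_study(small_params(), seed = 103L, dir = withr::local_tempdir())
  v <- read_vcf(st$paths$A1_CON)
  expect_gt(nrow(v), 100L)
  expect_equal(attr(v, "skipped"), 0L)
  expect_true(all(v$alt_reads >= 1L))
  expect_true(all(v$alt_reads <= v$total_reads))
  expect_true(all(v$ref_base != v$alt_base))
})

test_that("every editing truth site is strand-consistent with its gene", {
  st <- simulate_study(small_params(), seed = 105L, dir = withr::local_tempdir())
  truth <- st$truths$A1
  genes <- st$annotation$genes
  edit <- truth[truth$site_kind == "EDIT", ]
  g_strand <- genes$strand[match(edit$gene_id, genes$gene_id)]
  expect_equal(edit$strand, g_strand)
  g_start <- genes$start[match(edit$gene_id, genes$gene_id)]
  g_end <- genes$end[match(edit$gene_id, genes$gene_id)]
  expect_true(all(edit$pos >= g_start & edit$pos <= g_end))
})

test_that("knockout scaling and rate distribution match their parameters", {
  st <- simulate_study(small_params(), seed = 107L, dir = withr::local_tempdir())
  truth <- st$truths$A1
  edit <- truth[truth$site_kind == "EDIT", ]
  expect_equal(edit$true_rate_tm, 0.2 * edit$true_rate_con)
  # Beta(2,2) has mean 1/2 and sd 1/sqrt(20); check the sample mean at 3 SE
  n <- nrow(edit)
  expect_lt(
    abs(mean(edit$true_rate_con) - 0.5),
    3 * sqrt(0.05) / sqrt(n)
  )
  snp <- truth[truth$site_kind %in% c("SNP_HOM", "SNP_HET"), ]
  expect_equal(snp$true_rate_con, snp$true_rate_tm)
  # null knockout: no rate change anywhere
  st0 <- simulate_study(small_params(ko_scale = 1), seed = 107L,
    dir = withr::local_tempdir()
  )
  e0 <- st0$truths$A1[st0$truths$A1$site_kind == "EDIT", ]
  expect_equal(e0$true_rate_tm, e0$true_rate_con)
})

test_that("repeat class and subfamily frequencies track the configured weights", {
  p <- small_params()
  ann <- generate_annotation(p, seed = 109L)
  counts <- table(ann$repeats$repeat_class)
  expect_equal(
    as.integer(counts[names(p$n_repeats_per_class)]),
    unname(p$n_repeats_per_class)
  )
  sine <- ann$repeats[ann$repeats$repeat_class == "SINE", ]
  w <- p$sine_subfamily_weights
  for (sub in names(w)) {
    phat <- mean(sine$subfamily == sub)
    se <- sqrt(w[[sub]] * (1 - w[[sub]]) / nrow(sine))
    expect_lt(abs(phat - w[[sub]]), 3.5 * se + 1e-9, label = paste("subfamily", sub))
  }
})

test_that("degenerate generator inputs behave: no genes, zero error rate", {
  p0 <- sim_params(
    n_genes = 0L, n_chroms = 1L, chrom_length = 100000L,
    n_repeats_per_class = c(SINE = 5L), n_editing_sites = 0L,
    frac_snp_hom = 0, frac_snp_het = 0, frac_error_truth = 0
  )
  ann0 <- generate_annotation(p0, seed = 1L)
  expect_equal(nrow(ann0$genes), 0L)
  truth0 <- generate_truth(ann0, p0, seed = 1L)
  expect_equal(nrow(truth0), 0L)

  # zero sequencing error and zero true rate: site absent from the VCF
  p1 <- small_params(seq_error_rate = 0, frac_snp_hom = 0, frac_snp_het = 0)
  ann1 <- generate_annotation(p1, seed = 3L)
  truth1 <- generate_truth(ann1, p1, seed = 3L) |>
    dplyr::mutate(true_rate_con = 0, true_rate_tm = 0)
  lib <- simulate_library(truth1, "CON", ann1, p1, seed = 3L)
  expect_equal(nrow(lib$records), 0L)
  expect_equal(nrow(lib$draws), nrow(truth1))

  # infeasible packing is a parameter error
  expect_error(
    generate_annotation(
      sim_params(n_genes = 100L, n_chroms = 1L, chrom_length = 50000L,
        gene_length_range = c(3000L, 5000L)
      ),
      seed = 1L
    ),
    "infeasible packing"
  )
})

test_that("simulated read counts follow the binomial moments", {
  p <- small_params(seq_error_rate = 0)
  ann <- generate_annotation(p, seed = 113L)
  truth <- generate_truth(ann, p, seed = 113L) |>
    dplyr::mutate(true_rate_con = 0.5)
  lib <- simulate_library(truth, "CON", ann, p, seed = 113L)
  rates <- lib$draws$alt_reads / lib$draws$depth
  n <- nrow(lib$draws)
  se <- sqrt(0.25 / p$depth_lambda / n)
  expect_lt(abs(mean(rates) - 0.5), 4 * se)
  # degenerate binomial: rate 1 gives alt == depth
  truth1 <- dplyr::mutate(truth, true_rate_con = 1)
  lib1 <- simulate_library(truth1, "CON", ann, p, seed = 113L)
  expect_equal(lib1$draws$alt_reads, lib1$draws$depth)
})
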