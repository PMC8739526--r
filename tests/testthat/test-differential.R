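pair_row <- function(con = c(20L, 10L), tm = c(20L, 2L)) {
  tibble::tibble(
    chrom = "chr1", pos = 100L, strand = "+", gene_id = "g",
    con_total = con[1], con_alt = con[2], con_rate = con[2] / max(1L, con[1]),
    tm_total = tm[1], tm_alt = tm[2], tm_rate = tm[2] / max(1L, tm[1]),
    animal_id = "A1"
  )
}

test_that("directional calls follow the printed criteria incl. boundaries", {
  expect_equal(classify_sites(pair_row(c(20L, 10L), c(20L, 2L)))$call, "CON_GT_TM")
  # delta exactly 0.05 with CON support: inclusive boundary
  expect_equal(classify_sites(pair_row(c(20L, 10L), c(20L, 9L)))$call, "CON_GT_TM")
  # homozygous-SNP-like site invariant across conditions
  expect_equal(classify_sites(pair_row(c(50L, 50L), c(50L, 50L)))$call, "NOT_DIFF")
  # focal support must come from the focal sample
  expect_equal(classify_sites(pair_row(c(4L, 2L), c(20L, 1L)))$call, "NOT_DIFF")
  expect_equal(classify_sites(pair_row(c(20L, 1L), c(20L, 10L)))$call, "CON_LT_TM")
})

test_that("site universe is the keyed union with zero-filled missing sides", {
  con <- make_sites(c(100L, 200L), sample_id = "A1_CON")
  tm <- make_sites(c(200L, 300L), sample_id = "A1_TM")
  u <- build_site_universe(con, tm)
  expect_equal(nrow(u), 3L)
  only_con <- u[u$pos == 100L, ]
  expect_equal(only_con$tm_total, 0L)
  expect_equal(only_con$tm_rate, 0)
  # a CON-only site can never be called CON_LT_TM
  expect_true(
    classify_sites(u)$call[classify_sites(u)$pos == 100L] != "CON_LT_TM"
  )
  # empty TM library: universe equals CON candidates
  u2 <- build_site_universe(con, make_sites(integer(0)))
  expect_equal(u2$pos, c(100L, 200L))
  # drop-missing keeps only shared positions
  u3 <- build_site_universe(con, tm, missing = "drop")
  expect_equal(u3$pos, 200L)
})

test_that("swapping the libraries swaps the directional calls exactly", {
  set.seed(53)
  n <- 2000L
  u <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n), strand = "+", gene_id = "g",
    con_total = rpois(n, 12), con_alt = 0L,
    tm_total = rpois(n, 12), tm_alt = 0L, animal_id = "A1"
  ) |>
    dplyr::mutate(
      con_alt = rbinom(n, con_total, runif(n)),
      tm_alt = rbinom(n, tm_total, runif(n)),
      con_rate = ifelse(con_total > 0, con_alt / con_total, 0),
      tm_rate = ifelse(tm_total > 0, tm_alt / tm_total, 0)
    )
  fwd <- classify_sites(u)
  swapped <- u |>
    dplyr::rename(
      con_total = tm_total, con_alt = tm_alt, con_rate = tm_rate,
      tm_total = con_total, tm_alt = con_alt, tm_rate = con_rate
    )
  rev <- classify_sites(swapped)
  expect_equal(sum(fwd$call == "CON_GT_TM"), sum(rev$call == "CON_LT_TM"))
  expect_equal(sum(fwd$call == "CON_LT_TM"), sum(rev$call == "CON_GT_TM"))
  expect_equal(
    fwd$call == "NOT_DIFF", rev$call == "NOT_DIFF"
  )
  # the three calls partition the universe
  expect_equal(
    sum(fwd$call == "CON_GT_TM") + sum(fwd$call == "NOT_DIFF") +
      sum(fwd$call == "CON_LT_TM"),
    n
  )
})

test_that("differential_table reports counts via glance and swaps cleanly", {
  set.seed(61)
  con <- make_sites(seq_len(200L) * 7L,
    total = 30L, alt = 15L,
    sample_id = "A1_CON"
  )
  tm <- con |>
    dplyr::mutate(
      alt_reads = 3L, editing_rate = 0.1, sample_id = "A1_TM"
    )
  d <- differential_table(con, tm, animal_id = "A1")
  g <- glance(d)
  expect_equal(g$n_sites, 200L)
  expect_equal(g$n_con_gt_tm, 200L)
  d_swap <- differential_table(tm, con, animal_id = "A1")
  expect_equal(glance(d_swap)$n_con_lt_tm, 200L)
  expect_s3_class(tidy(d), "tbl_df")
  expect_false(inherits(tidy(d), "edit_diff"))
})

test_that("mismatched animals are rejected in consensus, not in pairing", {
  a <- differential_table(
    make_sites(1:3 * 10L, sample_id = "A1_CON"),
    make_sites(1:3 * 10L, sample_id = "A1_TM")
  )
  expect_equal(unique(a$animal_id), "A1")
  expect_error(intersect_calls(a, a, "site", "CON_GT_TM"), "different animals")
})
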