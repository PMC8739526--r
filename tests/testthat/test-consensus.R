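diff_stub <- function(pos, animal_id, call = "CON_GT_TM") {
  structure(
    tibble::tibble(
      chrom = "chr1", pos = as.integer(pos), strand = "+",
      call = call, animal_id = animal_id
    ),
    class = c("edit_diff", class(tibble::tibble()))
  )
}

test_that("overlap counts follow set arithmetic with the Venn identity", {
  a <- diff_stub(c(1L, 2L, 3L), "A1")
  b <- diff_stub(c(2L, 3L, 4L), "A2")
  x <- intersect_calls(a, b, "site", "CON_GT_TM")
  expect_equal(x$overlap_counts$a_only, 1L)
  expect_equal(x$overlap_counts$shared, 2L)
  expect_equal(x$overlap_counts$b_only, 1L)
  expect_equal(sort(x$shared$pos), c(2L, 3L))
  # disjoint inputs share nothing
  y <- intersect_calls(diff_stub(1:3, "A1"), diff_stub(7:9, "A2"), "site", "CON_GT_TM")
  expect_equal(y$overlap_counts$shared, 0L)
  expect_equal(nrow(y$shared), 0L)
})

test_that("direction filtering and key validation are enforced", {
  a <- diff_stub(1:3, "A1", call = c("CON_GT_TM", "CON_LT_TM", "NOT_DIFF"))
  b <- diff_stub(1:3, "A2", call = "CON_GT_TM")
  x <- intersect_calls(a, b, "site", "CON_GT_TM")
  expect_equal(x$overlap_counts$shared, 1L)
  expect_error(intersect_calls(a, b, "site", "HIGH"), "must be one of")
  expect_error(intersect_calls(a, diff_stub(1:2, "A1"), "site", "CON_GT_TM"),
    "different animals"
  )
})

test_that("random tables match brute-force intersection with Venn additivity", {
  set.seed(71)
  for (i in 1:20) {
    a_keys <- sample.int(500L, 60L)
    b_keys <- sample.int(500L, 60L)
    a <- diff_stub(a_keys, "A1")
    b <- diff_stub(b_keys, "A2")
    x <- intersect_calls(a, b, "site", "CON_GT_TM")
    expect_equal(sort(x$shared$pos), sort(intersect(a_keys, b_keys)))
    expect_equal(
      x$overlap_counts$a_only + x$overlap_counts$shared,
      length(unique(a_keys))
    )
    expect_equal(
      x$overlap_counts$b_only + x$overlap_counts$shared,
      length(unique(b_keys))
    )
  }
})
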