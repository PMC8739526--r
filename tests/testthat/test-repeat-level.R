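annotated_sites <- function(pos, rr_id, rate, sample_id, class = "SINE",
                            subfamily = "B1") {
  n <- length(pos)
  make_sites(pos, sample_id = sample_id) |>
    dplyr::mutate(
      editing_rate = rep_len(rate, n),
      alt_reads = as.integer(round(editing_rate * total_reads)),
      region = "INTRON",
      repeat_class = rep_len(class, n),
      subfamily = rep_len(subfamily, n),
      repeat_region_id = rep_len(rr_id, n)
    )
}

test_that("rr_mean_rate is the unweighted arithmetic mean", {
  expect_equal(rr_mean_rate(c(0.2, 0.4)), 0.3)
  expect_equal(rr_mean_rate(0.8), 0.8)
  expect_equal(rr_mean_rate(c(0.05, 0.95, 0.50)), 0.5)
  expect_error(rr_mean_rate(numeric(0)), "empty")
})

test_that("high/low repeat classification uses strict conjunctive bounds", {
  # more sites and higher mean in CON: high-editing RR
  expect_equal(classify_rr(4L, 0.35, 1L, 0.10), "HIGH")
  # identical sides: NEITHER (strict inequalities fail)
  expect_equal(classify_rr(3L, 0.4, 3L, 0.4), "NEITHER")
  # fewer sites and lower mean in CON: low-editing RR
  expect_equal(classify_rr(2L, 0.10, 5L, 0.40), "LOW")
  # discordant count and mean directions: NEITHER
  expect_equal(classify_rr(4L, 0.10, 1L, 0.40), "NEITHER")
  # one empty side contributes count 0, mean 0
  expect_equal(classify_rr(2L, 0.30, 0L, 0), "HIGH")
})

test_that("grouping excludes non-repeat sites and respects assignment", {
  sites <- dplyr::bind_rows(
    annotated_sites(c(10L, 20L, 30L), "chr1:1-100:B1_x", 0.3, "A1_CON"),
    annotated_sites(40L, "", 0.3, "A1_CON", class = "NON_REPEAT", subfamily = "")
  )
  grouped <- group_sites_by_rr(sites)
  expect_equal(nrow(grouped), 3L)
  expect_equal(unique(grouped$repeat_region_id), "chr1:1-100:B1_x")
  expect_equal(nrow(group_sites_by_rr(sites[4, ])), 0L)
})

test_that("rr_calls classifies per element and is antisymmetric", {
  con <- dplyr::bind_rows(
    annotated_sites(c(10L, 20L, 30L, 40L), "rrA", 0.35, "A1_CON"),
    annotated_sites(c(100L, 110L), "rrB", 0.10, "A1_CON"),
    annotated_sites(200L, "rrC", 0.50, "A1_CON")
  )
  tm <- dplyr::bind_rows(
    annotated_sites(10L, "rrA", 0.10, "A1_TM"),
    annotated_sites(c(100L, 110L, 120L, 130L, 140L), "rrB", 0.40, "A1_TM"),
    annotated_sites(200L, "rrC", 0.50, "A1_TM")
  )
  calls <- rr_calls(con, tm, animal_id = "A1")
  expect_equal(calls$call[calls$repeat_region_id == "rrA"], "HIGH")
  expect_equal(calls$call[calls$repeat_region_id == "rrB"], "LOW")
  expect_equal(calls$call[calls$repeat_region_id == "rrC"], "NEITHER")
  swapped <- rr_calls(tm, con, animal_id = "A1")
  expect_equal(
    swapped$call[match(calls$repeat_region_id, swapped$repeat_region_id)],
    dplyr::recode(calls$call, HIGH = "LOW", LOW = "HIGH", NEITHER = "NEITHER")
  )
  # an RR present in one condition only is classifiable
  only_con <- rr_calls(annotated_sites(5L, "rrD", 0.2, "A1_CON"),
    annotated_sites(integer(0), "x", 0.1, "A1_TM"),
    animal_id = "A1"
  )
  expect_equal(only_con$call, "HIGH")
  expect_equal(only_con$n_sites_tm, 0L)
  expect_equal(only_con$mean_rate_tm, 0)
})

test_that("class summaries conserve totals and enumerate all groups", {
  con <- dplyr::bind_rows(
    annotated_sites(c(10L, 20L), "rrA", 0.4, "A1_CON"),
    annotated_sites(30L, "rrL", 0.2, "A1_CON", class = "LINE", subfamily = "")
  )
  tm <- annotated_sites(10L, "rrA", 0.1, "A1_TM")
  calls <- rr_calls(con, tm, animal_id = "A1")
  sm <- class_summaries(list(calls), list(con, tm))
  spc <- sm$sites_per_class
  expect_equal(sum(spc$value), nrow(con) + nrow(tm))
  expect_equal(sort(unique(spc$group)), c("LINE", "LTR", "SINE"))
  expect_equal(
    spc$value[spc$group == "SINE" & spc$sample_id == "A1_CON"], 2
  )
  hl <- sm$rr_calls_per_subfamily
  expect_equal(hl$value[hl$group == "B1:HIGH"], 1)
  # rrA (SINE, CON-dominant) and rrL (LINE, CON-only) are both HIGH
  cls <- sm$rr_calls_per_class
  expect_equal(cls$value[cls$group == "SINE:HIGH"], 1)
  expect_equal(cls$value[cls$group == "LINE:HIGH"], 1)
  expect_equal(sum(cls$value), 2)
})
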