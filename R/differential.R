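#' Differential-call thresholds
#'
#' Per-site CON vs TM classification is threshold-based: a directional call
#' requires the editing-rate difference to reach `min_delta` and the focal
#' sample (CON for CON_GT_TM, TM for CON_LT_TM) to carry the confident-site
#' read support: total depth >= `focal_min_total`, edited reads >=
#' `focal_min_alt`, and rate <= `focal_max_rate` (the cap removes
#' homozygous-SNP-like signals). The partner sample is unconstrained, so a
#' site confidently edited in one library but weakly covered in the other is
#' still comparable.
#'
#' @param min_delta Minimum rate difference for a directional call
#'   (fraction), default 0.05.
#' @param focal_min_total,focal_min_alt Read-support bounds on the focal
#'   sample, defaults 5 and 3.
#' @param focal_max_rate Maximum focal-sample rate, default 0.95.
#' @return A named list of class `"differential_thresholds"`.
#' @export
differential_thresholds <- function(min_delta = 0.05, focal_min_total = 5L,
                                    focal_min_alt = 3L, focal_max_rate = 0.95) {
  stopifnot(min_delta > 0, min_delta <= 1, focal_min_total >= 0,
    focal_min_alt >= 0, focal_max_rate >= 0, focal_max_rate <= 1)
  structure(
    list(
      min_delta = min_delta,
      focal_min_total = as.integer(focal_min_total),
      focal_min_alt = as.integer(focal_min_alt),
      focal_max_rate = focal_max_rate
    ),
    class = "differential_thresholds"
  )
}

#' Build the paired site universe for one animal
#'
#' SNP contamination is controlled by design: only libraries of the same
#' animal are ever compared, so germline variants carry the same true allele
#' fraction on both sides. The universe is the union of candidate positions
#' keyed by (`chrom`, `pos`, `strand`); a position absent from one library's
#' variant output gets `(total = 0, alt = 0, rate = 0)` for that side (no
#' partner depth exists in VCF-only input; the focal-sample support criteria
#' gate the call, so this is conservative), or is dropped entirely with
#' `missing = "drop"`.
#'
#' @param con_candidates,tm_candidates Candidate editing-site tibbles (from
#'   [select_candidates()]) for the control and treated library of one
#'   animal.
#' @param animal_id Animal identifier stored on every row. Default is
#'   derived from the two `sample_id`s' longest common prefix.
#' @param missing `"zero"` (default) or `"drop"`: how to treat positions
#'   seen in only one library.
#' @return A paired tibble: `chrom`, `pos`, `strand`, `gene_id`,
#'   `con_total`, `con_alt`, `con_rate`, `tm_total`, `tm_alt`, `tm_rate`,
#'   `animal_id`, ordered by (`chrom`, `pos`).
#' @export
build_site_universe <- function(con_candidates, tm_candidates,
                                animal_id = NULL,
                                missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  if (is.null(animal_id)) {
    ids <- c(con_candidates$sample_id, tm_candidates$sample_id)
    animal_id <- if (length(ids) == 0L) {
      "animal"
    } else {
      common_prefix(unique(ids))
    }
  }
  key <- c("chrom", "pos", "strand", "gene_id")
  con <- con_candidates |>
    select(all_of(key),
      con_total = "total_reads", con_alt = "alt_reads", con_rate = "editing_rate"
    )
  tm <- tm_candidates |>
    select(all_of(key),
      tm_total = "total_reads", tm_alt = "alt_reads", tm_rate = "editing_rate"
    )
  joined <- if (missing == "zero") {
    full_join(con, tm, by = key)
  } else {
    inner_join(con, tm, by = key)
  }
  joined |>
    mutate(
      con_total = coalesce(.data$con_total, 0L),
      con_alt = coalesce(.data$con_alt, 0L),
      con_rate = coalesce(.data$con_rate, 0),
      tm_total = coalesce(.data$tm_total, 0L),
      tm_alt = coalesce(.data$tm_alt, 0L),
      tm_rate = coalesce(.data$tm_rate, 0),
      animal_id = animal_id
    ) |>
    arrange(.data$chrom, .data$pos)
}

common_prefix <- function(x) {
  if (length(x) == 1L) {
    return(x)
  }
  chars <- strsplit(x, "")
  n <- min(lengths(chars))
  k <- 0L
  for (i in seq_len(n)) {
    if (length(unique(vapply(chars, `[`, "", i))) == 1L) k <- i else break
  }
  out <- gsub("[_.-]+$", "", substr(x[1], 1L, k))
  if (nzchar(out)) out else "animal"
}

#' Classify paired sites as CON_GT_TM / NOT_DIFF / CON_LT_TM
#'
#' Applies the directional criteria to every row of a paired universe:
#' `CON_GT_TM` iff `con_rate - tm_rate >= min_delta` with confident CON
#' support (`con_total >= 5`, `con_alt >= 3`, `con_rate <= 0.95` at the
#' defaults); `CON_LT_TM` by the mirrored TM-focal criteria; everything else
#' `NOT_DIFF`. Both boundaries are inclusive. The three calls partition the
#' universe and the classification is antisymmetric under swapping the two
#' libraries.
#'
#' @param pairs Paired tibble from [build_site_universe()].
#' @param thresholds A [differential_thresholds()] object.
#' @return `pairs` with `delta = con_rate - tm_rate` and `call` columns.
#' @export
classify_sites <- function(pairs, thresholds = differential_thresholds()) {
  stopifnot(inherits(thresholds, "differential_thresholds"))
  thr <- thresholds
  # rate differences are differences of rounded quotients, so the inclusive
  # min_delta boundary needs a tolerance well below any attainable rate gap
  # (1 / (20 * d_con * d_tm) at the default threshold) yet above rounding
  # error; 1e-9 covers depths into the tens of thousands
  eps <- 1e-9
  pairs |>
    mutate(
      delta = .data$con_rate - .data$tm_rate,
      call = case_when(
        .data$delta >= thr$min_delta - eps &
          .data$con_total >= thr$focal_min_total &
          .data$con_alt >= thr$focal_min_alt &
          .data$con_rate <= thr$focal_max_rate ~ "CON_GT_TM",
        -.data$delta >= thr$min_delta - eps &
          .data$tm_total >= thr$focal_min_total &
          .data$tm_alt >= thr$focal_min_alt &
          .data$tm_rate <= thr$focal_max_rate ~ "CON_LT_TM",
        TRUE ~ "NOT_DIFF"
      )
    )
}

#' Paired differential-editing table for one animal
#'
#' Runs [build_site_universe()] and [classify_sites()] and returns a classed
#' tibble carrying per-call counts, ready for [tidy()] / [glance()] and
#' [autoplot()][autoplot.edit_diff].
#'
#' @inheritParams build_site_universe
#' @inheritParams classify_sites
#' @return A tibble of class `"edit_diff"` with one row per universe
#'   position (columns of the `"differential"` schema, see [write_table()]).
#' @export
differential_table <- function(con_candidates, tm_candidates,
                               thresholds = differential_thresholds(),
                               animal_id = NULL,
                               missing = c("zero", "drop")) {
  out <- build_site_universe(
    con_candidates, tm_candidates,
    animal_id = animal_id, missing = missing
  ) |>
    classify_sites(thresholds) |>
    relocate("animal_id", .after = "call")
  class(out) <- c("edit_diff", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' @export
tidy.edit_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "edit_diff")
  attr(out, "thresholds") <- NULL
  out
}

#' @export
glance.edit_diff <- function(x, ...) {
  tibble(
    animal_id = if (nrow(x) > 0L) x$animal_id[1] else NA_character_,
    n_sites = nrow(x),
    n_con_gt_tm = sum(x$call == "CON_GT_TM"),
    n_not_diff = sum(x$call == "NOT_DIFF"),
    n_con_lt_tm = sum(x$call == "CON_LT_TM"),
    min_delta = attr(x, "thresholds")$min_delta
  )
}

#' @export
print.edit_diff <- function(x, ...) {
  g <- glance(x)
  cat(
    "Differential editing calls (", g$animal_id, "): ",
    g$n_sites, " paired sites — CON>TM ", g$n_con_gt_tm,
    ", not different ", g$n_not_diff,
    ", CON<TM ", g$n_con_lt_tm, "\n",
    sep = ""
  )
  NextMethod()
}
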