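#' Group confident editing sites by repeat region
#'
#' Editing sites annotated to the same repeat element (RR) are grouped under
#' that element's `repeat_region_id`; non-repeat sites are excluded. Each
#' repeat site belongs to exactly one group (the innermost containing element
#' chosen by [assign_repeats()]).
#'
#' @param sites Annotated-site tibble from [annotate_sites()].
#' @return A tibble grouped one row per (repeat_region_id, site), i.e. the
#'   repeat subset of `sites`, ordered by `repeat_region_id`, `chrom`, `pos`.
#' @export
group_sites_by_rr <- function(sites) {
  sites |>
    filter(.data$repeat_class != NON_REPEAT) |>
    arrange(.data$repeat_region_id, .data$chrom, .data$pos)
}

#' Average editing rate of a repeat region
#'
#' The RR-level editing rate is the unweighted arithmetic mean of the
#' editing rates of the confident ("for-sure") editing sites located in that
#' element — depth does not weight the average.
#'
#' @param rates Numeric vector of site editing rates (nonempty).
#' @return The mean rate (fraction).
#' @examples
#' rr_mean_rate(c(0.2, 0.4)) # 0.3
#' @export
rr_mean_rate <- function(rates) {
  if (length(rates) == 0L) {
    stop("rr_mean_rate is undefined for an empty site group", call. = FALSE)
  }
  mean(rates)
}

#' Classify one repeat region as HIGH / NEITHER / LOW
#'
#' A high-editing RR (CON > TM) contains strictly more confident editing
#' sites AND a strictly higher average editing rate in the control library
#' than in the paired treated library; a low-editing RR (CON < TM) has
#' strictly fewer sites and a strictly lower average. Everything else —
#' including all ties — is NEITHER. A side with no confident sites
#' contributes count 0 and mean 0, so complete loss of editing is
#' representable. Vectorised.
#'
#' @param n_con,n_tm Confident-site counts per condition.
#' @param mean_con,mean_tm Average site editing rates per condition (0 when
#'   the corresponding count is 0).
#' @return Character vector: `"HIGH"`, `"NEITHER"` or `"LOW"`.
#' @export
classify_rr <- function(n_con, mean_con, n_tm, mean_tm) {
  case_when(
    n_con > n_tm & mean_con > mean_tm ~ "HIGH",
    n_con < n_tm & mean_con < mean_tm ~ "LOW",
    TRUE ~ "NEITHER"
  )
}

#' Repeat-region-level differential editing calls for one animal
#'
#' Groups each condition's confident annotated sites by repeat element,
#' summarises counts and mean rates per side, and classifies every RR with
#' at least one confident site in either condition. By default each
#' condition contributes its own confident-site set (a site may qualify in
#' CON but not TM); `shared_sites_only = TRUE` restricts both sides to
#' positions confident in both.
#'
#' @param annotated_con,annotated_tm Confident annotated-site tibbles (one
#'   condition each) from [annotate_sites()].
#' @param animal_id Animal identifier; default derived from the sample ids.
#' @param shared_sites_only Restrict to sites confident in both conditions.
#' @return A tibble of class `"rr_calls"`: `repeat_region_id`,
#'   `repeat_class`, `subfamily`, `n_sites_con`, `n_sites_tm`,
#'   `mean_rate_con`, `mean_rate_tm`, `call`, `animal_id`, ordered by
#'   `repeat_region_id`.
#' @export
rr_calls <- function(annotated_con, annotated_tm, animal_id = NULL,
                     shared_sites_only = FALSE) {
  if (is.null(animal_id)) {
    ids <- unique(c(annotated_con$sample_id, annotated_tm$sample_id))
    animal_id <- if (length(ids) == 0L) "animal" else common_prefix(ids)
  }
  con <- group_sites_by_rr(annotated_con)
  tm <- group_sites_by_rr(annotated_tm)
  if (shared_sites_only) {
    key <- c("chrom", "pos", "strand")
    shared <- inner_join(
      select(con, all_of(key)), select(tm, all_of(key)),
      by = key
    )
    con <- semi_join(con, shared, by = key)
    tm <- semi_join(tm, shared, by = key)
  }
  side_summary <- function(df, n_col, mean_col) {
    df |>
      group_by(.data$repeat_region_id, .data$repeat_class, .data$subfamily) |>
      summarise(
        "{n_col}" := n(),
        "{mean_col}" := mean(.data$editing_rate),
        .groups = "drop"
      )
  }
  out <- full_join(
    side_summary(con, "n_sites_con", "mean_rate_con"),
    side_summary(tm, "n_sites_tm", "mean_rate_tm"),
    by = c("repeat_region_id", "repeat_class", "subfamily")
  ) |>
    mutate(
      n_sites_con = coalesce(.data$n_sites_con, 0L),
      n_sites_tm = coalesce(.data$n_sites_tm, 0L),
      mean_rate_con = coalesce(.data$mean_rate_con, 0),
      mean_rate_tm = coalesce(.data$mean_rate_tm, 0),
      call = classify_rr(
        .data$n_sites_con, .data$mean_rate_con,
        .data$n_sites_tm, .data$mean_rate_tm
      ),
      animal_id = animal_id
    ) |>
    select(
      "repeat_region_id", "repeat_class", "subfamily", "n_sites_con",
      "n_sites_tm", "mean_rate_con", "mean_rate_tm", "call", "animal_id"
    ) |>
    arrange(.data$repeat_region_id)
  class(out) <- c("rr_calls", class(out))
  out
}

#' @export
tidy.rr_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rr_calls")
  out
}

#' @export
glance.rr_calls <- function(x, ...) {
  tibble(
    animal_id = if (nrow(x) > 0L) x$animal_id[1] else NA_character_,
    n_rrs = nrow(x),
    n_high = sum(x$call == "HIGH"),
    n_neither = sum(x$call == "NEITHER"),
    n_low = sum(x$call == "LOW")
  )
}

#' Repeat-class summary tables (sites, RRs, rates, HIGH/LOW breakdowns)
#'
#' Builds the standard repeat-level summary tables in long format
#' (`metric`, `group`, `sample_id`, `value`):
#'
#' * `sites_per_class` — confident editing sites per repeat class per sample;
#' * `rrs_per_class` — edited repeat elements per class per sample;
#' * `mean_rate_per_class` — average site editing rate per class per sample;
#' * `rr_calls_per_class` — HIGH / LOW RR counts per repeat class per animal;
#' * `rr_calls_per_subfamily` — HIGH / LOW RR counts per SINE subfamily per
#'   animal.
#'
#' @param rr_call_tables List of [rr_calls()] tibbles (one per animal).
#' @param per_sample_sites List of confident annotated-site tibbles (one per
#'   sample/library).
#' @param classes Repeat classes to report, default `c("SINE", "LTR",
#'   "LINE")` — the major editing-bearing classes.
#' @return Named list of long-format tibbles as described above.
#' @export
class_summaries <- function(rr_call_tables, per_sample_sites,
                            classes = c("SINE", "LTR", "LINE")) {
  sites <- bind_rows(per_sample_sites) |>
    filter(.data$repeat_class %in% classes)
  grid <- function(samples) {
    tidyr::expand_grid(group = classes, sample_id = samples)
  }
  samples <- unique(bind_rows(per_sample_sites)$sample_id)
  sites_per_class <- grid(samples) |>
    left_join(
      sites |> count(group = .data$repeat_class, .data$sample_id),
      by = c("group", "sample_id")
    ) |>
    mutate(metric = "sites_per_class", value = as.double(coalesce(.data$n, 0L)))
  rrs_per_class <- grid(samples) |>
    left_join(
      sites |>
        distinct(.data$repeat_class, .data$sample_id, .data$repeat_region_id) |>
        count(group = .data$repeat_class, .data$sample_id),
      by = c("group", "sample_id")
    ) |>
    mutate(metric = "rrs_per_class", value = as.double(coalesce(.data$n, 0L)))
  mean_rate_per_class <- grid(samples) |>
    left_join(
      sites |>
        group_by(group = .data$repeat_class, .data$sample_id) |>
        summarise(rate = mean(.data$editing_rate), .groups = "drop"),
      by = c("group", "sample_id")
    ) |>
    mutate(metric = "mean_rate_per_class", value = .data$rate)
  rrs <- bind_rows(map(rr_call_tables, tidy))
  call_grid <- function(groups) {
    tidyr::expand_grid(
      group = groups, sample_id = unique(rrs$animal_id),
      call = c("HIGH", "LOW")
    )
  }
  rr_calls_per_class <- call_grid(classes) |>
    left_join(
      rrs |>
        filter(.data$repeat_class %in% classes, .data$call != "NEITHER") |>
        count(group = .data$repeat_class, sample_id = .data$animal_id, .data$call),
      by = c("group", "sample_id", "call")
    ) |>
    mutate(
      metric = "rr_calls_per_class",
      group = paste0(.data$group, ":", .data$call),
      value = as.double(coalesce(.data$n, 0L))
    )
  rr_calls_per_subfamily <- call_grid(SINE_SUBFAMILIES) |>
    left_join(
      rrs |>
        filter(.data$repeat_class == "SINE", .data$call != "NEITHER") |>
        count(group = .data$subfamily, sample_id = .data$animal_id, .data$call),
      by = c("group", "sample_id", "call")
    ) |>
    mutate(
      metric = "rr_calls_per_subfamily",
      group = paste0(.data$group, ":", .data$call),
      value = as.double(coalesce(.data$n, 0L))
    )
  long <- function(df) {
    df |>
      select("metric", "group", "sample_id", "value") |>
      arrange(.data$metric, .data$group, .data$sample_id)
  }
  list(
    sites_per_class = long(sites_per_class),
    rrs_per_class = long(rrs_per_class),
    mean_rate_per_class = long(mean_rate_per_class),
    rr_calls_per_class = long(rr_calls_per_class),
    rr_calls_per_subfamily = long(rr_calls_per_subfamily)
  )
}
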