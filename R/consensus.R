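#' Cross-replicate overlap of differential calls
#'
#' Intersects one call direction between two animals, Venn-style: a site is
#' keyed by (`chrom`, `pos`, `strand`), a repeat region by its
#' `repeat_region_id`, and "shared" means the same call direction in both
#' animals.
#'
#' @param a,b Call tables from two different animals: [differential_table()]
#'   results for `key = "site"`, [rr_calls()] results for `key = "rr"`.
#' @param key `"site"` or `"rr"`.
#' @param direction The call direction to intersect: one of `"CON_GT_TM"` /
#'   `"CON_LT_TM"` (sites) or `"HIGH"` / `"LOW"` (RRs).
#' @return A list of class `"edit_consensus"` with elements `shared`
#'   (tibble of shared keys), `unique_a`, `unique_b`, and `overlap_counts`
#'   (tibble `a_only` / `shared` / `b_only`), plus `key`, `direction` and the
#'   two animal ids. Invariants: `a_only + shared = |A|`,
#'   `b_only + shared = |B|`.
#' @export
intersect_calls <- function(a, b, key = c("site", "rr"),
                            direction = "CON_GT_TM") {
  key <- match.arg(key)
  valid <- if (key == "site") c("CON_GT_TM", "CON_LT_TM") else c("HIGH", "LOW")
  if (!direction %in% valid) {
    stop(
      "direction for key '", key, "' must be one of: ",
      paste(valid, collapse = ", "),
      call. = FALSE
    )
  }
  id_a <- if (nrow(a) > 0L) a$animal_id[1] else NA_character_
  id_b <- if (nrow(b) > 0L) b$animal_id[1] else NA_character_
  if (!is.na(id_a) && !is.na(id_b) && identical(id_a, id_b)) {
    stop("intersect_calls needs call tables from two different animals",
      call. = FALSE
    )
  }
  key_cols <- if (key == "site") c("chrom", "pos", "strand") else "repeat_region_id"
  pick <- function(df) {
    df |>
      as_tibble() |>
      filter(.data$call == direction) |>
      distinct(across(all_of(key_cols))) |>
      arrange(across(all_of(key_cols)))
  }
  ka <- pick(a)
  kb <- pick(b)
  shared <- inner_join(ka, kb, by = key_cols)
  n_shared <- nrow(shared)
  out <- list(
    key = key, direction = direction,
    animal_a = id_a, animal_b = id_b,
    shared = shared,
    unique_a = anti_join(ka, kb, by = key_cols),
    unique_b = anti_join(kb, ka, by = key_cols),
    overlap_counts = tibble(
      a_only = nrow(ka) - n_shared,
      shared = n_shared,
      b_only = nrow(kb) - n_shared
    )
  )
  structure(out, class = "edit_consensus")
}

#' @export
glance.edit_consensus <- function(x, ...) {
  bind_cols(
    tibble(
      key = x$key, direction = x$direction,
      animal_a = x$animal_a, animal_b = x$animal_b
    ),
    x$overlap_counts
  )
}

#' @export
print.edit_consensus <- function(x, ...) {
  cat(
    "Consensus (", x$key, ", ", x$direction, "): ",
    x$overlap_counts$a_only, " in ", x$animal_a, " only, ",
    x$overlap_counts$shared, " shared, ",
    x$overlap_counts$b_only, " in ", x$animal_b, " only\n",
    sep = ""
  )
  invisible(x)
}

#' Run the full editing-analysis pipeline
#'
#' Orchestrates every stage for a multi-animal paired design: read gene
#' models and repeats, then per library call candidates and confident sites,
#' annotate them, build per-animal differential and repeat-region tables,
#' and intersect directions across the first two animals. All products are
#' written as schema TSVs plus a JSON summary of every count; identical
#' configs produce byte-identical outputs.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `gtf` (path), `repeats` (path), optional `repeats_dialect`, optional
#'   `flank_bp`, `min_delta`, threshold overrides (`min_total_reads`,
#'   `min_alt_reads`, `min_rate`, `max_rate`), and `animals`: a list of
#'   lists each with `animal_id`, `con_vcf`, `tm_vcf` and optional
#'   `con_sample` / `tm_sample` ids.
#' @param out_dir Output directory (created; must not be an existing
#'   non-empty pipeline run unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the in-memory products: `sites`
#'   (per-sample confident annotated sites), `differential`, `rr`
#'   (per-animal tables), `consensus` (per key/direction), and `summary`
#'   (the JSON-serialised count list).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (field in c("gtf", "repeats", "animals")) {
    if (is.null(config[[field]])) {
      stop("pipeline config lacks required field '", field, "'", call. = FALSE)
    }
  }
  for (a in config$animals) {
    for (field in c("animal_id", "con_vcf", "tm_vcf")) {
      if (is.null(a[[field]])) {
        stop(
          "animal entry", if (!is.null(a$animal_id)) paste0(" '", a$animal_id, "'"),
          " lacks required field '", field, "'",
          call. = FALSE
        )
      }
    }
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  flank_bp <- config$flank_bp %||% 50000L
  thr <- editing_thresholds(
    min_total_reads = config$min_total_reads %||% 5L,
    min_alt_reads = config$min_alt_reads %||% 3L,
    min_rate = config$min_rate %||% 0.05,
    max_rate = config$max_rate %||% 0.95
  )
  dthr <- differential_thresholds(
    min_delta = config$min_delta %||% 0.05,
    focal_min_total = thr$min_total_reads,
    focal_min_alt = thr$min_alt_reads,
    focal_max_rate = thr$max_rate
  )

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  genes <- run_stage("read_gtf", read_gtf(config$gtf))
  repeats <- run_stage(
    "read_repeatmasker",
    read_repeatmasker(config$repeats, dialect = config$repeats_dialect %||% "auto")
  )

  sites <- list()
  candidates <- list()
  diffs <- list()
  rrs <- list()
  for (animal in config$animals) {
    aid <- animal$animal_id
    per_cond <- list()
    for (cond in c("con", "tm")) {
      sample_id <- animal[[paste0(cond, "_sample")]] %||%
        paste0(aid, "_", toupper(cond))
      vcf_path <- animal[[paste0(cond, "_vcf")]]
      cand <- run_stage(
        paste0("detect:", sample_id),
        read_vcf(vcf_path, sample_id = sample_id) |>
          select_candidates(genes, flank_bp = flank_bp)
      )
      conf <- run_stage(
        paste0("annotate:", sample_id),
        cand |>
          filter_confident(thr) |>
          annotate_sites(genes, repeats, distal_bp = flank_bp)
      )
      write_table(conf, file.path(out_dir, paste0("sites_", sample_id, ".tsv")),
        schema = "annotated_sites"
      )
      per_cond[[cond]] <- list(candidates = cand, confident = conf)
      sites[[sample_id]] <- conf
      candidates[[sample_id]] <- cand
    }
    diffs[[aid]] <- run_stage(
      paste0("differential:", aid),
      differential_table(
        per_cond$con$candidates, per_cond$tm$candidates,
        thresholds = dthr, animal_id = aid
      )
    )
    write_table(diffs[[aid]],
      file.path(out_dir, paste0("differential_", aid, ".tsv")),
      schema = "differential"
    )
    rrs[[aid]] <- run_stage(
      paste0("rr:", aid),
      rr_calls(per_cond$con$confident, per_cond$tm$confident, animal_id = aid)
    )
    write_table(rrs[[aid]], file.path(out_dir, paste0("rr_", aid, ".tsv")),
      schema = "rr_calls"
    )
  }

  consensus <- list()
  if (length(diffs) >= 2L) {
    pairs <- list(
      list(tables = diffs, key = "site", dirs = c("CON_GT_TM", "CON_LT_TM")),
      list(tables = rrs, key = "rr", dirs = c("HIGH", "LOW"))
    )
    for (p in pairs) {
      for (d in p$dirs) {
        cname <- paste0(p$key, "_", d)
        consensus[[cname]] <- intersect_calls(
          p$tables[[1]], p$tables[[2]],
          key = p$key, direction = d
        )
      }
    }
    consensus_tbl <- bind_rows(map(consensus, glance))
    readr::write_tsv(consensus_tbl, file.path(out_dir, "consensus.tsv"),
      progress = FALSE
    )
  }

  summaries <- class_summaries(rrs, sites)
  write_table(bind_rows(summaries), file.path(out_dir, "rr_summary.tsv"),
    schema = "counts"
  )
  summary <- list(
    parameters = list(
      flank_bp = flank_bp, thresholds = unclass(thr),
      differential = unclass(dthr)
    ),
    libraries = map(sites, nrow),
    candidates = map(candidates, nrow),
    differential = map(diffs, function(d) as.list(glance(d))),
    rr = map(rrs, function(r) as.list(glance(r))),
    consensus = map(consensus, function(x) as.list(glance(x)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    sites = sites, candidates = candidates, differential = diffs, rr = rrs,
    consensus = consensus, summary = summary
  ))
}
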