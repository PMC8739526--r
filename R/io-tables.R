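#' Tab-separated output tables with fixed schemas
#'
#' All pipeline products are written as TSV with a header line, a fixed
#' documented column order and a canonical row order, so identical inputs
#' always produce byte-identical files. Registered schemas:
#'
#' * `"sites"` — editing sites: `chrom`, `pos`, `strand`, `gene_id`,
#'   `total_reads`, `alt_reads`, `editing_rate`, `sample_id`; sorted by
#'   (`chrom`, `pos`, `sample_id`).
#' * `"annotated_sites"` — `"sites"` plus `region`, `repeat_class`,
#'   `subfamily`, `repeat_region_id`.
#' * `"differential"` — paired per-site calls: `chrom`, `pos`, `strand`,
#'   `gene_id`, `con_total`, `con_alt`, `con_rate`, `tm_total`, `tm_alt`,
#'   `tm_rate`, `delta`, `call`, `animal_id`; sorted by (`chrom`, `pos`).
#' * `"rr_calls"` — repeat-region calls: `repeat_region_id`, `repeat_class`,
#'   `subfamily`, `n_sites_con`, `n_sites_tm`, `mean_rate_con`,
#'   `mean_rate_tm`, `call`, `animal_id`; sorted by `repeat_region_id`.
#' * `"counts"` — long-format summary counts: `metric`, `group`, `sample_id`,
#'   `value`; sorted by (`metric`, `group`, `sample_id`).
#'
#' @param records Tibble conforming to the schema (column superset allowed;
#'   extra columns are dropped).
#' @param path Output file path.
#' @param schema One of the schema names above.
#' @return `write_table()` returns `path` invisibly; `read_table()` returns
#'   the tibble with schema column types restored.
#' @export
write_table <- function(records, path, schema) {
  sc <- table_schema(schema)
  missing_cols <- setdiff(sc$cols, names(records))
  if (length(missing_cols) > 0L) {
    stop(
      "records lack column(s) required by schema '", schema, "': ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- records |>
    as_tibble() |>
    select(all_of(sc$cols)) |>
    arrange(across(all_of(sc$sort)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  sc <- table_schema(schema)
  out <- readr::read_tsv(path, col_types = sc$types, progress = FALSE)
  if (!identical(names(out), sc$cols)) {
    stop("file does not match schema '", schema, "': ", path, call. = FALSE)
  }
  out
}

table_schema <- function(schema) {
  schemas <- list(
    sites = list(
      cols = c(
        "chrom", "pos", "strand", "gene_id", "total_reads", "alt_reads",
        "editing_rate", "sample_id"
      ),
      types = "cicciidc",
      sort = c("chrom", "pos", "sample_id")
    ),
    annotated_sites = list(
      cols = c(
        "chrom", "pos", "strand", "gene_id", "total_reads", "alt_reads",
        "editing_rate", "sample_id", "region", "repeat_class", "subfamily",
        "repeat_region_id"
      ),
      types = "cicciidccccc",
      sort = c("chrom", "pos", "sample_id")
    ),
    differential = list(
      cols = c(
        "chrom", "pos", "strand", "gene_id", "con_total", "con_alt",
        "con_rate", "tm_total", "tm_alt", "tm_rate", "delta", "call",
        "animal_id"
      ),
      types = "cicciidiiddcc",
      sort = c("chrom", "pos")
    ),
    rr_calls = list(
      cols = c(
        "repeat_region_id", "repeat_class", "subfamily", "n_sites_con",
        "n_sites_tm", "mean_rate_con", "mean_rate_tm", "call", "animal_id"
      ),
      types = "ccciiddcc",
      sort = "repeat_region_id"
    ),
    counts = list(
      cols = c("metric", "group", "sample_id", "value"),
      types = "cccd",
      sort = c("metric", "group", "sample_id")
    )
  )
  if (!schema %in% names(schemas)) {
    stop(
      "unknown schema '", schema, "'; registered: ",
      paste(names(schemas), collapse = ", "),
      call. = FALSE
    )
  }
  schemas[[schema]]
}
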