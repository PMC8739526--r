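#' Read repeat-element annotations (RepeatMasker `.out` or BED)
#'
#' Repetitive elements are the substrate of most A-to-I editing: inverted
#' SINE copies (mouse B1/B2/B4, human Alu) form the dsRNA that ADAR edits.
#' This reader ingests either the native RepeatMasker `.out` format (three
#' header lines, whitespace-delimited columns) or a 6-column BED whose name
#' field is `"name#class/family"`, and normalises both to 1-based inclusive
#' coordinates.
#'
#' The class/family string is mapped onto the canonical class set
#' (`SINE`, `LTR`, `LINE`, `Simple_repeat`, `DNA`, `RNA`, `Low_complexity`,
#' anything else `Other`); for SINEs the family token is further mapped to the
#' subfamily groups `B1`, `B2`, `B4` or `Other`.
#'
#' @param path Path to the repeat annotation file.
#' @param dialect `"auto"` (default; BED when the extension is `.bed`, else
#'   RepeatMasker `.out`), `"rm_out"`, or `"bed"`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `repeat_name`, `repeat_class`, `subfamily` (empty string unless SINE) and
#'   a stable `repeat_region_id` of the form `"chrom:start-end:repeat_name"`.
#' @export
read_repeatmasker <- function(path, dialect = c("auto", "rm_out", "bed")) {
  if (!file.exists(path)) stop("repeat file not found: ", path, call. = FALSE)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "rm_out"
  }
  if (dialect == "bed") {
    read_repeats_bed(path)
  } else {
    read_repeats_out(path)
  }
}

read_repeats_out <- function(path) {
  lines <- readLines(path)
  # RepeatMasker .out: two banner lines + one blank line before data
  is_banner <- grepl("^\\s*(SW|score)", lines) | !nzchar(trimws(lines))
  keep <- which(!is_banner)
  if (length(keep) == 0L) {
    return(finish_repeats(empty_repeat_rows()))
  }
  rows <- map(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11L || is.na(suppressWarnings(as.integer(f[6]))) ||
      is.na(suppressWarnings(as.integer(f[7])))) {
      stop("unparseable RepeatMasker line ", i, " in ", basename(path),
        call. = FALSE
      )
    }
    tibble(
      chrom = f[5], start = as.integer(f[6]), end = as.integer(f[7]),
      repeat_name = f[10], class_family = f[11]
    )
  })
  finish_repeats(bind_rows(rows))
}

read_repeats_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start0", "end", "name", "score", "strand"),
    col_types = "ciiccc", progress = FALSE
  )
  if (nrow(bed) > 0L && any(is.na(bed$start0) | is.na(bed$end))) {
    stop("unparseable BED line ", which(is.na(bed$start0) | is.na(bed$end))[1],
      " in ", basename(path),
      call. = FALSE
    )
  }
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("#"), 2)
  finish_repeats(tibble(
    chrom = bed$chrom,
    start = bed$start0 + 1L, # BED is 0-based half-open
    end = bed$end,
    repeat_name = parts[, 1],
    class_family = parts[, 2]
  ))
}

empty_repeat_rows <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    repeat_name = character(), class_family = character()
  )
}

finish_repeats <- function(df) {
  df |>
    mutate(
      repeat_class = map_repeat_class(.data$class_family),
      subfamily = map_sine_subfamily(.data$class_family, .data$repeat_class),
      repeat_region_id = paste0(
        .data$chrom, ":", .data$start, "-", .data$end, ":", .data$repeat_name
      )
    ) |>
    select(-"class_family") |>
    arrange(.data$chrom, .data$start, .data$end, .data$repeat_name)
}

map_repeat_class <- function(class_family) {
  cls <- stringr::str_split_fixed(class_family, stringr::fixed("/"), 2)[, 1]
  if_else(cls %in% setdiff(REPEAT_CLASSES, "Other"), cls, "Other")
}

map_sine_subfamily <- function(class_family, repeat_class) {
  fam <- stringr::str_split_fixed(class_family, stringr::fixed("/"), 2)[, 2]
  sub <- case_when(
    stringr::str_starts(fam, "B1") ~ "B1",
    stringr::str_starts(fam, "B2") ~ "B2",
    stringr::str_starts(fam, "B4") ~ "B4",
    TRUE ~ "Other"
  )
  if_else(repeat_class == "SINE", sub, "")
}
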