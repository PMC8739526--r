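#' Read per-sample variant records from a VCF file
#'
#' Parses a VCF 4.x file into one row per biallelic SNV. Multi-allelic records
#' are split into one row per alternate allele; indels, symbolic alleles
#' (`<DEL>` and friends), spanning deletions (`*`) and records with missing
#' depth information are skipped, and the number of skipped records is
#' reported with a message and attached as the `"skipped"` attribute.
#'
#' Total depth is taken from the per-sample `DP` FORMAT field when present;
#' when `DP` is absent the sum of the `AD` vector is used instead, which keeps
#' `alt_reads <= total_reads` guaranteed. Alternate-supporting depth always
#' comes from the `AD` entry matching the alternate allele.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @param sample_id Library identifier recorded in the `sample_id` column
#'   (e.g., `"EC1_CON"`). Defaults to the first sample column name in the VCF.
#' @param dp_field,ad_field FORMAT field names holding total and per-allele
#'   depths. Defaults `"DP"` and `"AD"`.
#'
#' @return A tibble of variant records with columns `chrom`, `pos`,
#'   `ref_base`, `alt_base`, `total_reads`, `alt_reads`, `sample_id`, sorted
#'   by (`chrom`, `pos`, `alt_base`). Attribute `"skipped"` holds the count of
#'   non-SNV records dropped.
#'
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
#'   "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
#'   "chr1\t100\t.\tA\tG\t.\t.\t.\tDP:AD\t20:15,5"
#' ), vcf)
#' read_vcf(vcf, sample_id = "EC1_CON")
#' @export
read_vcf <- function(path, sample_id = NULL, dp_field = "DP", ad_field = "AD") {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble(
    chrom = character(), pos = integer(),
    ref_base = character(), alt_base = character(),
    total_reads = integer(), alt_reads = integer(),
    sample_id = character()
  )
  if (nrow(vcf@fix) == 0L) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  if (ncol(vcf@gt) < 2L) {
    stop("VCF has no sample column with per-sample FORMAT fields", call. = FALSE)
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, 1L], ":", fixed = TRUE)))
  if (!(ad_field %in% fmt_keys)) {
    stop(
      "VCF FORMAT lacks the allele-depth field '", ad_field,
      "'; set `ad_field` to the field your caller emits",
      call. = FALSE
    )
  }
  if (is.null(sample_id)) sample_id <- colnames(vcf@gt)[2L]

  fix <- as_tibble(as.data.frame(vcf@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE]))
  ad <- vcfR::extract.gt(vcf, element = ad_field)[, 1L]
  dp <- if (dp_field %in% fmt_keys) {
    suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = dp_field)[, 1L]))
  } else {
    rep(NA_integer_, nrow(fix))
  }

  rec <- fix |>
    mutate(
      pos = as.integer(.data$POS),
      ad = unname(ad),
      dp = dp,
      row = row_number()
    )

  is_snv <- nchar(rec$REF) == 1L & rec$REF %in% DNA_BASES &
    !is.na(rec$ALT) & rec$ALT != "." &
    !grepl("[<*]", rec$ALT) &
    vapply(
      strsplit(rec$ALT, ",", fixed = TRUE),
      function(a) all(a %in% DNA_BASES), logical(1)
    )
  n_skip <- sum(!is_snv)
  rec <- rec[is_snv, , drop = FALSE]
  if (n_skip > 0L) {
    message("read_vcf: skipped ", n_skip, " non-SNV record(s) in ", basename(path))
  }
  if (nrow(rec) == 0L) {
    attr(empty, "skipped") <- n_skip
    return(empty)
  }

  out <- rec |>
    mutate(alts = strsplit(.data$ALT, ",", fixed = TRUE)) |>
    tidyr::unnest_longer(col = "alts", indices_to = "alt_index") |>
    mutate(
      ad_vec = strsplit(.data$ad, ",", fixed = TRUE),
      alt_reads = map2_int_checked(.data$ad_vec, .data$alt_index + 1L, path),
      ad_sum = vapply(
        .data$ad_vec,
        function(v) sum(suppressWarnings(as.integer(v)), na.rm = TRUE),
        integer(1)
      ),
      total_reads = if_else(is.na(.data$dp), .data$ad_sum, .data$dp)
    ) |>
    select(
      chrom = "CHROM", pos = "pos", ref_base = "REF", alt_base = "alts",
      total_reads = "total_reads", alt_reads = "alt_reads"
    ) |>
    mutate(sample_id = sample_id) |>
    filter(.data$ref_base != .data$alt_base) |>
    arrange(.data$chrom, .data$pos, .data$alt_base)

  bad <- out$alt_reads > out$total_reads
  if (any(bad)) {
    stop(
      "VCF depth fields inconsistent (alt depth > total depth) at ",
      out$chrom[which(bad)[1]], ":", out$pos[which(bad)[1]],
      call. = FALSE
    )
  }
  attr(out, "skipped") <- n_skip
  out
}

# AD entry lookup for one alternate allele; errors name the file
map2_int_checked <- function(ad_vec, idx, path) {
  out <- map2(ad_vec, idx, function(v, i) {
    if (length(v) < i) {
      stop(
        "AD vector shorter than allele count in ", basename(path),
        call. = FALSE
      )
    }
    suppressWarnings(as.integer(v[i]))
  })
  vapply(out, function(x) if (is.na(x)) 0L else x, integer(1))
}
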