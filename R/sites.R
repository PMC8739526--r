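#' Confident-site filter thresholds
#'
#' The confident ("for-sure") editing-site filter keeps sites with enough
#' read support to rule out rare sequencing errors while discarding
#' homozygous-SNP-like signals: total depth at least `min_total_reads`,
#' edited reads at least `min_alt_reads`, and an editing rate between
#' `min_rate` and `max_rate` inclusive. The defaults (depth >= 5, edited
#' reads >= 3, rate in [0.05, 0.95]) deliberately sacrifice rare real editing
#' events for specificity.
#'
#' @param min_total_reads Minimum total depth (reads), default 5.
#' @param min_alt_reads Minimum edited-read count, default 3.
#' @param min_rate,max_rate Inclusive editing-rate bounds (fractions),
#'   defaults 0.05 and 0.95.
#' @return A named list of class `"editing_thresholds"`.
#' @export
editing_thresholds <- function(min_total_reads = 5L, min_alt_reads = 3L,
                               min_rate = 0.05, max_rate = 0.95) {
  stopifnot(
    min_total_reads >= 0, min_alt_reads >= 0,
    min_alt_reads <= min_total_reads,
    min_rate >= 0, min_rate < max_rate, max_rate <= 1
  )
  structure(
    list(
      min_total_reads = as.integer(min_total_reads),
      min_alt_reads = as.integer(min_alt_reads),
      min_rate = min_rate, max_rate = max_rate
    ),
    class = "editing_thresholds"
  )
}

#' Editing rate of a site
#'
#' The editing rate is the fraction of reads supporting the edited base out
#' of all reads covering the site: `alt_reads / total_reads`, an exact
#' quotient with no rounding.
#'
#' @param alt_reads,total_reads Non-negative integer read counts
#'   (vectorised); `alt_reads <= total_reads` and `total_reads > 0` required.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' compute_editing_rate(3, 5) # 0.6
#' @export
compute_editing_rate <- function(alt_reads, total_reads) {
  if (any(total_reads <= 0)) {
    stop("editing rate undefined at total_reads = 0; filter zero-depth sites first",
      call. = FALSE
    )
  }
  if (any(alt_reads < 0 | alt_reads > total_reads)) {
    stop("alt_reads must lie in [0, total_reads]", call. = FALSE)
  }
  alt_reads / total_reads
}

#' Select strand-consistent candidate editing sites
#'
#' A-to-I editing appears as A>G on the transcribed strand. A variant becomes
#' a candidate editing site iff it lies within some gene span extended by
#' `flank_bp` on both sides and its (ref, alt) pair is strand-consistent with
#' that gene: A>G for a plus-strand gene, T>C (on the reference strand) for a
#' minus-strand gene. All other mismatch types, and variants beyond the flank
#' of every gene (where no transcript strand can be inferred), are discarded.
#'
#' When several strand-consistent genes match, the assignment prefers a gene
#' whose span contains the site over flank-only matches, then the smallest
#' distance to the gene span, with a final lexicographic `gene_id` tie-break,
#' so output is deterministic.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param genes Gene-model tibble from [read_gtf()].
#' @param flank_bp Flank (bp) added to both sides of every gene span when
#'   building the candidate universe; default 50000, matching the widest
#'   ("distal") annotation window.
#' @return An editing-site tibble: `chrom`, `pos`, `strand`, `gene_id`,
#'   `total_reads`, `alt_reads`, `editing_rate`, `sample_id`, ordered by
#'   (`chrom`, `pos`, `sample_id`).
#' @export
select_candidates <- function(variants, genes, flank_bp = 50000L) {
  stopifnot(flank_bp >= 0)
  empty <- tibble(
    chrom = character(), pos = integer(), strand = character(),
    gene_id = character(), total_reads = integer(), alt_reads = integer(),
    editing_rate = double(), sample_id = character()
  )
  if (nrow(variants) == 0L || nrow(genes) == 0L) {
    return(empty)
  }
  if (length(intersect(unique(variants$chrom), unique(genes$chrom))) == 0L) {
    warning(
      "variant and gene chromosome name sets are disjoint ",
      "(chr/no-chr naming mismatch?)",
      call. = FALSE
    )
  }
  v <- variants |>
    mutate(
      target_strand = case_when(
        .data$ref_base == "A" & .data$alt_base == "G" ~ "+",
        .data$ref_base == "T" & .data$alt_base == "C" ~ "-",
        TRUE ~ NA_character_
      )
    ) |>
    filter(!is.na(.data$target_strand), .data$total_reads > 0L) |>
    mutate(.row = row_number())
  if (nrow(v) == 0L) {
    return(empty)
  }

  g_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(
      pmax(1L, genes$start - as.integer(flank_bp)),
      genes$end + as.integer(flank_bp)
    )
  )
  v_gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::findOverlaps(v_gr, g_gr)

  if (length(hits) == 0L) {
    return(empty)
  }
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  matched <- tibble(
    vrow = vi,
    gene_id = genes$gene_id[gi],
    gene_strand = genes$strand[gi],
    gene_start = genes$start[gi],
    gene_end = genes$end[gi]
  ) |>
    mutate(
      pos = v$pos[.data$vrow],
      target = v$target_strand[.data$vrow]
    ) |>
    filter(.data$gene_strand == .data$target) |>
    mutate(
      dist = pmax(0L, .data$gene_start - .data$pos, .data$pos - .data$gene_end)
    ) |>
    arrange(.data$vrow, .data$dist, .data$gene_id) |>
    group_by(.data$vrow) |>
    slice(1L) |>
    ungroup()

  v |>
    inner_join(
      select(matched, "vrow", "gene_id", strand = "gene_strand"),
      by = c(".row" = "vrow")
    ) |>
    mutate(editing_rate = compute_editing_rate(.data$alt_reads, .data$total_reads)) |>
    select(
      "chrom", "pos", "strand", "gene_id", "total_reads", "alt_reads",
      "editing_rate", "sample_id"
    ) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

#' Apply the confident-site filter
#'
#' Retains exactly the candidate sites with `total_reads >=
#' min_total_reads`, `alt_reads >= min_alt_reads` and `min_rate <=
#' editing_rate <= max_rate` (both rate bounds inclusive). Input order is
#' preserved.
#'
#' @param candidates Editing-site tibble from [select_candidates()].
#' @param thresholds An [editing_thresholds()] object.
#' @return The retained subset of `candidates`.
#' @export
filter_confident <- function(candidates, thresholds = editing_thresholds()) {
  stopifnot(inherits(thresholds, "editing_thresholds"))
  candidates |>
    filter(
      .data$total_reads >= thresholds$min_total_reads,
      .data$alt_reads >= thresholds$min_alt_reads,
      .data$editing_rate >= thresholds$min_rate,
      .data$editing_rate <= thresholds$max_rate
    )
}
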