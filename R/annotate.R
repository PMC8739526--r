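#' Assign gene-region categories to editing sites
#'
#' Each site is annotated relative to its assigned gene with exactly one
#' category. Inside the gene span the precedence is UTR5 / UTR3 before EXON
#' (UTRs are exonic, so they must outrank plain exon hits; EXON is thereby
#' reserved for CDS-bearing exon positions), and any genic position in none
#' of the listed features is INTRON. Outside the span, "upstream" and
#' "downstream" are strand-oriented (the 5' side of a minus-strand gene lies
#' at higher genomic coordinates): up to `promoter_bp` upstream is PROMOTER,
#' further out to `distal_bp` is FIVE_PRIME_DISTAL; downstream mirrors this
#' with DOWNSTREAM and THREE_PRIME_DISTAL.
#'
#' @param sites Editing-site tibble with `pos` and `gene_id` columns (from
#'   [select_candidates()] / [filter_confident()]).
#' @param genes Gene-model tibble from [read_gtf()] containing every
#'   `gene_id` referenced by `sites`.
#' @param promoter_bp Promoter / downstream window (bp), default 1000.
#' @param distal_bp Distal window (bp), default 50000. A site farther than
#'   this from its gene is an assignment error (cannot occur after
#'   [select_candidates()] with `flank_bp = distal_bp`).
#' @return `sites` with a `region` column (factor-ordered character, one of
#'   `r paste(REGION_LEVELS, collapse = ", ")`).
#' @export
assign_gene_region <- function(sites, genes, promoter_bp = 1000L,
                               distal_bp = 50000L) {
  if (nrow(sites) == 0L) {
    return(mutate(sites, region = character(0)))
  }
  missing_genes <- setdiff(unique(sites$gene_id), genes$gene_id)
  if (length(missing_genes) > 0L) {
    stop(
      "sites reference gene_id(s) absent from the gene models: ",
      paste(head(missing_genes, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  region <- character(nrow(sites))
  for (gid in unique(sites$gene_id)) {
    idx <- which(sites$gene_id == gid)
    g <- genes[genes$gene_id == gid, ]
    region[idx] <- region_for_gene(sites$pos[idx], g, promoter_bp, distal_bp)
  }
  mutate(sites, region = region)
}

region_for_gene <- function(pos, g, promoter_bp, distal_bp) {
  inside <- pos >= g$start & pos <= g$end
  # genomic left/right distances, then orient by strand
  d_left <- g$start - pos # > 0 when site left of the gene
  d_right <- pos - g$end # > 0 when site right of the gene
  if (identical(g$strand, "-")) {
    d_up <- d_right
    d_down <- d_left
  } else {
    d_up <- d_left
    d_down <- d_right
  }
  too_far <- !inside & pmax(d_left, d_right) > distal_bp
  if (any(too_far)) {
    stop(
      "site at ", g$chrom, ":", pos[which(too_far)[1]], " lies > ", distal_bp,
      " bp from its assigned gene ", g$gene_id,
      call. = FALSE
    )
  }
  in_utr5 <- pos_in_intervals(pos, g$utr5[[1]])
  in_utr3 <- pos_in_intervals(pos, g$utr3[[1]])
  in_exon <- pos_in_intervals(pos, g$exons[[1]])
  case_when(
    inside & in_utr5 ~ "UTR5",
    inside & in_utr3 ~ "UTR3",
    inside & in_exon ~ "EXON",
    inside ~ "INTRON",
    d_up > 0 & d_up <= promoter_bp ~ "PROMOTER",
    d_up > 0 ~ "FIVE_PRIME_DISTAL",
    d_down > 0 & d_down <= promoter_bp ~ "DOWNSTREAM",
    TRUE ~ "THREE_PRIME_DISTAL"
  )
}

#' Assign repeat-element annotation to editing sites
#'
#' Each site is labelled with the repeat element containing it, or
#' `"NON_REPEAT"` when no element covers its position. When several elements
#' overlap the position the shortest (innermost, most specific) one wins,
#' with a lexicographic `repeat_region_id` tie-break.
#'
#' @param sites Editing-site tibble.
#' @param repeats Repeat tibble from [read_repeatmasker()].
#' @return `sites` with `repeat_class` (`"NON_REPEAT"` or a repeat class),
#'   `subfamily` (SINE subfamily or `""`) and `repeat_region_id` (`""` when
#'   not in a repeat) columns appended.
#' @export
assign_repeats <- function(sites, repeats) {
  blank <- function(n) {
    tibble(
      repeat_class = rep(NON_REPEAT, n),
      subfamily = rep("", n), repeat_region_id = rep("", n)
    )
  }
  if (nrow(sites) == 0L || nrow(repeats) == 0L) {
    return(bind_cols(sites, blank(nrow(sites))))
  }
  s_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  r_gr <- GenomicRanges::GRanges(
    repeats$chrom,
    IRanges::IRanges(repeats$start, repeats$end)
  )
  hits <- GenomicRanges::findOverlaps(s_gr, r_gr)
  ann <- blank(nrow(sites))
  if (length(hits) > 0L) {
    best <- tibble(
      srow = S4Vectors::queryHits(hits),
      rrow = S4Vectors::subjectHits(hits)
    ) |>
      mutate(
        len = repeats$end[.data$rrow] - repeats$start[.data$rrow] + 1L,
        repeat_region_id = repeats$repeat_region_id[.data$rrow]
      ) |>
      arrange(.data$srow, .data$len, .data$repeat_region_id) |>
      group_by(.data$srow) |>
      slice(1L) |>
      ungroup()
    ann$repeat_class[best$srow] <- repeats$repeat_class[best$rrow]
    ann$subfamily[best$srow] <- repeats$subfamily[best$rrow]
    ann$repeat_region_id[best$srow] <- best$repeat_region_id
  }
  bind_cols(sites, ann)
}

#' Annotate editing sites with gene regions and repeat elements
#'
#' Convenience wrapper running [assign_gene_region()] then
#' [assign_repeats()].
#'
#' @inheritParams assign_gene_region
#' @inheritParams assign_repeats
#' @return The annotated-site tibble (see the `"annotated_sites"` schema in
#'   [write_table()]).
#' @export
annotate_sites <- function(sites, genes, repeats, promoter_bp = 1000L,
                           distal_bp = 50000L) {
  sites |>
    assign_gene_region(genes, promoter_bp = promoter_bp, distal_bp = distal_bp) |>
    assign_repeats(repeats)
}

#' Summarize the genomic distribution of annotated editing sites
#'
#' Produces the four standard distribution tables: sites per gene-region
#' category, repeat vs non-repeat, sites per repeat class, and SINE sites per
#' subfamily (B1/B2/B4/Other). Every table enumerates all levels (zero
#' counts included); the first three tables each total the number of input
#' sites, the subfamily table totals the SINE sites.
#'
#' @param annotated Annotated-site tibble from [annotate_sites()].
#' @return Named list of tibbles `region`, `repeat_status`, `repeat_class`,
#'   `sine_subfamily`, each with columns `group` and `n`.
#' @export
summarize_regions <- function(annotated) {
  count_levels <- function(x, levels) {
    tibble(group = levels) |>
      left_join(
        tibble(group = x) |> count(.data$group),
        by = "group"
      ) |>
      mutate(n = coalesce(.data$n, 0L))
  }
  list(
    region = count_levels(annotated$region, REGION_LEVELS),
    repeat_status = count_levels(
      if_else(annotated$repeat_class == NON_REPEAT, "non_repeat", "repeat"),
      c("repeat", "non_repeat")
    ),
    repeat_class = count_levels(
      annotated$repeat_class[annotated$repeat_class != NON_REPEAT],
      REPEAT_CLASSES
    ) |>
      bind_rows(tibble(
        group = NON_REPEAT,
        n = sum(annotated$repeat_class == NON_REPEAT)
      )),
    sine_subfamily = count_levels(
      annotated$subfamily[annotated$repeat_class == "SINE"],
      SINE_SUBFAMILIES
    )
  )
}
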