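#' Read gene models from a GTF file
#'
#' Builds one gene model per `gene_id` from `gene`, `exon`, `CDS`,
#' `five_prime_utr` and `three_prime_utr` features. When explicit UTR
#' features are absent, UTRs are inferred from exon-minus-CDS set arithmetic
#' oriented by strand; genes without CDS are treated as noncoding (all-exonic,
#' empty UTRs). Introns are implicit: the genic gaps between exon intervals.
#'
#' @param path Path to a GTF file.
#'
#' @return A gene-model tibble with one row per gene: `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (1-based inclusive span), and
#'   list-columns `utr5`, `exons`, `cds`, `utr3`, each a tibble of
#'   non-overlapping sorted `start`/`end` intervals within the span.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  empty <- empty_gene_models()
  n_lines <- length(readLines(path, n = 1L))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) NULL
  )
  if (is.null(gr) || length(gr) == 0L) {
    if (n_lines > 0L && is.null(gr)) {
      stop("malformed GTF: ", path, call. = FALSE)
    }
    return(empty)
  }
  feat <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id)
  ) |>
    filter(.data$type %in% c("gene", "exon", "CDS", "five_prime_utr", "three_prime_utr"))
  if (any(is.na(feat$gene_id))) {
    stop("GTF feature without gene_id attribute", call. = FALSE)
  }
  gene_rows <- filter(feat, .data$type == "gene")
  child_rows <- filter(feat, .data$type != "gene")
  if (nrow(gene_rows) > 0L) {
    unknown <- setdiff(unique(child_rows$gene_id), gene_rows$gene_id)
    if (length(unknown) > 0L) {
      stop(
        "GTF feature references unknown gene_id: ",
        paste(head(unknown, 3L), collapse = ", "),
        call. = FALSE
      )
    }
  }

  build_one <- function(gid) {
    g <- filter(feat, .data$gene_id == gid)
    span <- filter(g, .data$type == "gene")
    if (nrow(span) == 0L) {
      span <- summarise(g,
        chrom = .data$chrom[1], strand = .data$strand[1],
        start = min(.data$start), end = max(.data$end)
      )
    }
    if (nrow(span) > 1L) {
      stop("multiple gene features for gene_id ", gid, call. = FALSE)
    }
    kids <- filter(g, .data$type != "gene")
    if (nrow(kids) > 0L &&
      (min(kids$start) < span$start || max(kids$end) > span$end)) {
      stop("feature outside gene span for gene_id ", gid, call. = FALSE)
    }
    exons <- reduce_intervals(filter(g, .data$type == "exon"))
    cds <- reduce_intervals(filter(g, .data$type == "CDS"))
    utr5 <- reduce_intervals(filter(g, .data$type == "five_prime_utr"))
    utr3 <- reduce_intervals(filter(g, .data$type == "three_prime_utr"))
    if (nrow(utr5) == 0L && nrow(utr3) == 0L && nrow(cds) > 0L && nrow(exons) > 0L) {
      utrs <- derive_utrs(exons, cds, span$strand[1])
      utr5 <- utrs$utr5
      utr3 <- utrs$utr3
    }
    tibble(
      gene_id = gid, chrom = span$chrom[1], strand = span$strand[1],
      start = span$start[1], end = span$end[1],
      utr5 = list(utr5), exons = list(exons), cds = list(cds),
      utr3 = list(utr3)
    )
  }

  out <- bind_rows(map(sort(unique(feat$gene_id)), build_one)) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  class(out) <- c("gene_models", class(out))
  out
}

empty_gene_models <- function() {
  out <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(),
    utr5 = list(), exons = list(), cds = list(), utr3 = list()
  )
  class(out) <- c("gene_models", class(out))
  out
}

empty_intervals <- function() tibble(start = integer(), end = integer())

# merge overlapping/adjacent intervals, return sorted tibble(start, end)
reduce_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(empty_intervals())
  }
  ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
  tibble(start = IRanges::start(ir), end = IRanges::end(ir))
}

# exon \ CDS positions, split into the 5' and 3' side of the CDS span
derive_utrs <- function(exons, cds, strand) {
  ex <- IRanges::IRanges(exons$start, exons$end)
  cd <- IRanges::IRanges(cds$start, cds$end)
  noncds <- IRanges::setdiff(ex, cd)
  cds_lo <- min(cds$start)
  cds_hi <- max(cds$end)
  left <- IRanges::restrict(noncds, end = cds_lo - 1L)
  right <- IRanges::restrict(noncds, start = cds_hi + 1L)
  left_tbl <- tibble(start = IRanges::start(left), end = IRanges::end(left))
  right_tbl <- tibble(start = IRanges::start(right), end = IRanges::end(right))
  if (identical(strand, "-")) {
    list(utr5 = right_tbl, utr3 = left_tbl)
  } else {
    list(utr5 = left_tbl, utr3 = right_tbl)
  }
}

# membership of positions in an interval tibble
pos_in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  ir <- IRanges::IRanges(iv$start, iv$end)
  IRanges::countOverlaps(IRanges::IRanges(pos, pos), ir) > 0L
}
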