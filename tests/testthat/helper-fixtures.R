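# In-code fixture builders shared across test files.

# a hand-built two-exon protein-coding gene as a gene-model row
mini_gene <- function(gene_id = "gA", chrom = "chr1", strand = "+",
                      start = 100001L, end = 110000L) {
  # exon1 100001-101000 (UTR5 100001-100500, CDS 100501-101000),
  # intron 101001-108999,
  # exon2 109000-110000 (CDS 109000-109499, UTR3 109500-110000)
  g <- tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    utr5 = list(tibble::tibble(start = 100001L, end = 100500L)),
    exons = list(tibble::tibble(
      start = c(100001L, 109000L), end = c(101000L, 110000L)
    )),
    cds = list(tibble::tibble(
      start = c(100501L, 109000L), end = c(101000L, 109499L)
    )),
    utr3 = list(tibble::tibble(start = 109500L, end = 110000L))
  )
  class(g) <- c("gene_models", class(g))
  g
}

# reflect a gene-model row (and positions) through genome length L:
# pos -> L - pos + 1, "+" <-> "-"; 5'/3' roles are preserved
reflect_gene <- function(g, L) {
  flip_iv <- function(iv) {
    if (nrow(iv) == 0L) {
      return(iv)
    }
    tibble::tibble(start = L - iv$end + 1L, end = L - iv$start + 1L) |>
      dplyr::arrange(start)
  }
  out <- tibble::tibble(
    gene_id = g$gene_id, chrom = g$chrom,
    strand = if (g$strand == "+") "-" else "+",
    start = L - g$end + 1L, end = L - g$start + 1L,
    utr5 = list(flip_iv(g$utr5[[1]])),
    exons = list(flip_iv(g$exons[[1]])),
    cds = list(flip_iv(g$cds[[1]])),
    utr3 = list(flip_iv(g$utr3[[1]]))
  )
  class(out) <- c("gene_models", class(out))
  out
}

reflect_pos <- function(pos, L) L - pos + 1L

# editing-site rows with sensible defaults
make_sites <- function(pos, chrom = "chr1", strand = "+", gene_id = "gA",
                       total = 20L, alt = 10L, sample_id = "S1") {
  n <- length(pos)
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    strand = rep_len(strand, n), gene_id = rep_len(gene_id, n),
    total_reads = rep_len(as.integer(total), n),
    alt_reads = rep_len(as.integer(alt), n),
    editing_rate = rep_len(alt, n) / rep_len(total, n),
    sample_id = rep_len(sample_id, n)
  )
}

# small fully-specified VCF on disk; returns the path (cleaned up with the
# calling test's frame)
write_test_vcf <- function(lines, path = NULL, envir = parent.frame()) {
  if (is.null(path)) {
    path <- withr::local_tempfile(fileext = ".vcf", .local_envir = envir)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"
  )
  writeLines(c(header, lines), path)
  path
}

# random variant records spanning all mismatch types over a genome
random_variants <- function(n, genome_length = 2500000L, n_chroms = 2L,
                            sample_id = "S1") {
  chrom <- paste0("chr", sample.int(n_chroms, n, replace = TRUE))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(
    ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), ""
  )
  total <- 1L + stats::rpois(n, 15)
  tibble::tibble(
    chrom = chrom,
    pos = sample.int(genome_length, n, replace = TRUE),
    ref_base = ref, alt_base = unname(alt),
    total_reads = total,
    alt_reads = stats::rbinom(n, total, stats::runif(n)),
    sample_id = sample_id
  )
}
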