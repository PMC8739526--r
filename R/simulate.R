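#' Simulation parameters for synthetic paired-condition editing studies
#'
#' Defines the study conditions the generator emulates: a toy multi-
#' chromosome genome carrying non-overlapping genes with UTR/CDS/intron
#' structure, repeat elements concentrated in introns and 3' UTRs, an
#' editing landscape enriched in repeats whose rates drop by `ko_scale` in
#' the treated condition, germline SNP and sequencing-error confounders, and
#' binomially sampled read counts at truncated-Poisson depths.
#'
#' Defaults emulate a two-animal paired knockout design at desk scale:
#' ~10 Mb genome, ~2e4 truth sites per animal, mean depth 50, Beta(2, 2)
#' control editing rates scaled by 0.2 after knockout.
#'
#' @param n_genes Number of genes, default 300.
#' @param gene_length_range Min/max gene length (bp).
#' @param n_chroms,chrom_length Chromosome count and common length (bp).
#' @param n_repeats_per_class Named integer vector of repeat counts per
#'   class.
#' @param sine_subfamily_weights Named probabilities over B1/B2/B4/Other
#'   (sum 1).
#' @param repeat_placement_weights Named probabilities over gene-region
#'   categories controlling where repeats land (mass on INTRON and UTR3).
#' @param n_editing_sites True A-to-I editing sites per animal.
#' @param editing_rate_beta Beta(alpha, beta) shape for control editing
#'   rates.
#' @param ko_scale Multiplicative reduction of the true editing rate in the
#'   treated condition (0.2 = 80% loss).
#' @param edit_repeat_weight Fraction of editing sites placed inside repeat
#'   elements.
#' @param frac_snp_hom,frac_snp_het SNP confounders (true alt fraction 1.0 /
#'   0.5 in both conditions) as fractions of `n_editing_sites`.
#' @param frac_error_truth Labelled zero-rate error-prone positions as a
#'   fraction of `n_editing_sites` (background error sites are additionally
#'   emitted per library at `seq_error_rate`).
#' @param seq_error_rate Per-base sequencing mismatch probability.
#' @param depth_lambda Poisson mean of per-site depth (truncated at >= 1).
#' @param n_animals Number of simulated animals (paired CON/TM libraries
#'   each), default 2.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 300L,
                       gene_length_range = c(3000L, 20000L),
                       n_chroms = 4L,
                       chrom_length = 2500000L,
                       n_repeats_per_class = c(
                         SINE = 2400L, LTR = 600L, LINE = 600L,
                         Simple_repeat = 240L, DNA = 120L,
                         Low_complexity = 120L
                       ),
                       sine_subfamily_weights = c(
                         B1 = 0.45, B2 = 0.30, B4 = 0.15, Other = 0.10
                       ),
                       repeat_placement_weights = c(
                         INTRON = 0.50, UTR3 = 0.25, UTR5 = 0.05,
                         EXON = 0.05, FIVE_PRIME_DISTAL = 0.075,
                         THREE_PRIME_DISTAL = 0.075
                       ),
                       n_editing_sites = 16000L,
                       editing_rate_beta = c(2, 2),
                       ko_scale = 0.2,
                       edit_repeat_weight = 0.5,
                       frac_snp_hom = 0.05,
                       frac_snp_het = 0.10,
                       frac_error_truth = 0.05,
                       seq_error_rate = 0.001,
                       depth_lambda = 50,
                       n_animals = 2L) {
  p <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_repeats_per_class = n_repeats_per_class,
    sine_subfamily_weights = sine_subfamily_weights,
    repeat_placement_weights = repeat_placement_weights,
    n_editing_sites = as.integer(n_editing_sites),
    editing_rate_beta = editing_rate_beta,
    ko_scale = ko_scale,
    edit_repeat_weight = edit_repeat_weight,
    frac_snp_hom = frac_snp_hom,
    frac_snp_het = frac_snp_het,
    frac_error_truth = frac_error_truth,
    seq_error_rate = seq_error_rate,
    depth_lambda = depth_lambda,
    n_animals = as.integer(n_animals)
  )
  stopifnot(
    p$n_genes >= 0, length(p$gene_length_range) == 2L,
    p$gene_length_range[1] >= 200L,
    p$gene_length_range[1] <= p$gene_length_range[2],
    p$n_chroms >= 1, p$chrom_length >= 1000L,
    all(p$n_repeats_per_class >= 0),
    all(names(p$n_repeats_per_class) %in% REPEAT_CLASSES),
    abs(sum(p$sine_subfamily_weights) - 1) < 1e-8,
    identical(sort(names(p$sine_subfamily_weights)), sort(SINE_SUBFAMILIES)),
    abs(sum(p$repeat_placement_weights) - 1) < 1e-8,
    all(names(p$repeat_placement_weights) %in% REGION_LEVELS),
    p$n_editing_sites >= 0,
    all(p$editing_rate_beta > 0),
    p$ko_scale >= 0, p$ko_scale <= 1,
    p$edit_repeat_weight >= 0, p$edit_repeat_weight <= 1,
    p$frac_snp_hom >= 0, p$frac_snp_het >= 0, p$frac_error_truth >= 0,
    p$seq_error_rate >= 0, p$seq_error_rate < 1,
    p$depth_lambda > 0, p$n_animals >= 1
  )
  structure(p, class = "sim_params")
}

# deterministic sub-seed for a named randomness stream; stays below 2^31
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 65599 + h) %% 2147480009)
}

# truncated Poisson(lambda) on {1, 2, ...} via inverse CDF
rtrunc_pois <- function(n, lambda) {
  u <- runif(n, min = ppois(0, lambda), max = 1)
  pmax(1L, qpois(u, lambda))
}

# Binomial(size, prob) conditioned on >= 1 via inverse CDF (vectorised size)
rpos_binom <- function(size, prob) {
  u <- runif(length(size), min = pbinom(0, size, prob), max = 1)
  pmax(1L, qbinom(u, size, prob))
}

#' Generate a toy genome annotation (genes + repeats)
#'
#' Places non-overlapping genes with exon/intron/UTR/CDS structure on a
#' small multi-chromosome genome and distributes repeat elements across
#' gene-region categories according to `repeat_placement_weights`. The
#' emitted GTF and RepeatMasker-style files re-parse exactly through
#' [read_gtf()] / [read_repeatmasker()].
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the annotation
#'   byte-for-byte.
#' @return A list with `genome` (tibble `chrom`, `length`), `genes` (a
#'   gene-model tibble as from [read_gtf()]) and `repeats` (tibble as from
#'   [read_repeatmasker()]).
#' @export
generate_annotation <- function(params = sim_params(), seed = 42L) {
  stopifnot(inherits(params, "sim_params"))
  genome <- tibble(
    chrom = paste0("chr", seq_len(params$n_chroms)),
    length = params$chrom_length
  )
  set.seed(substream_seed(seed, "annotation"))
  genes <- make_genes(params, genome)
  repeats <- make_repeats(params, genes, genome)
  list(genome = genome, genes = genes, repeats = repeats)
}

make_genes <- function(params, genome) {
  if (params$n_genes == 0L) {
    return(empty_gene_models())
  }
  chrom_of <- rep(genome$chrom, length.out = params$n_genes)
  rows <- list()
  gi <- 0L
  for (ci in seq_len(nrow(genome))) {
    k <- sum(chrom_of == genome$chrom[ci])
    if (k == 0L) next
    lens <- sample(
      params$gene_length_range[1]:params$gene_length_range[2], k,
      replace = TRUE
    )
    min_gap <- 200L
    if (sum(lens) + (k + 1L) * min_gap > genome$length[ci]) {
      stop(
        "infeasible packing: genes exceed chromosome length on ",
        genome$chrom[ci],
        call. = FALSE
      )
    }
    slack <- genome$length[ci] - sum(lens) - (k + 1L) * min_gap
    w <- runif(k + 1L)
    gaps <- min_gap + floor(w / sum(w) * slack)
    starts <- cumsum(c(
      gaps[1] + 1L,
      if (k > 1L) head(lens, -1L) + gaps[2:k]
    ))
    for (j in seq_len(k)) {
      gi <- gi + 1L
      rows[[gi]] <- one_gene(
        gene_id = sprintf("gene%04d", gi),
        chrom = genome$chrom[ci],
        start = as.integer(starts[j]),
        len = lens[j]
      )
    }
  }
  out <- bind_rows(rows) |> arrange(.data$chrom, .data$start, .data$gene_id)
  class(out) <- c("gene_models", class(out))
  out
}

one_gene <- function(gene_id, chrom, start, len) {
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(2:6, 1L)
  n_seg <- 2L * n_ex - 1L
  min_seg <- 30L
  w <- runif(n_seg)
  w[seq(2L, n_seg, by = 2L)] <- w[seq(2L, n_seg, by = 2L)] * 6 # long introns
  seg <- min_seg + floor(w / sum(w) * (len - n_seg * min_seg))
  seg[1] <- seg[1] + (len - sum(seg))
  ends <- start - 1L + cumsum(seg)
  starts <- ends - seg + 1L
  ex_idx <- seq(1L, n_seg, by = 2L)
  exons <- tibble(start = as.integer(starts[ex_idx]), end = as.integer(ends[ex_idx]))
  noncoding <- runif(1) < 0.1
  if (noncoding) {
    utr5 <- empty_intervals()
    utr3 <- empty_intervals()
    cds <- empty_intervals()
  } else {
    w_first <- exons$end[1] - exons$start[1] + 1L
    w_last <- exons$end[n_ex] - exons$start[n_ex] + 1L
    u5_frac <- runif(1, 0.1, 0.4)
    u3_frac <- runif(1, 0.3, 0.8)
    if (strand == "+") {
      left_len <- max(1L, min(w_first - 1L, floor(u5_frac * w_first)))
      right_len <- max(1L, min(w_last - 1L, floor(u3_frac * w_last)))
    } else {
      left_len <- max(1L, min(w_first - 1L, floor(u3_frac * w_first)))
      right_len <- max(1L, min(w_last - 1L, floor(u5_frac * w_last)))
    }
    left_iv <- tibble(
      start = exons$start[1],
      end = exons$start[1] + left_len - 1L
    )
    right_iv <- tibble(
      start = exons$end[n_ex] - right_len + 1L,
      end = exons$end[n_ex]
    )
    cds <- exons
    cds$start[1] <- left_iv$end + 1L
    cds$end[n_ex] <- right_iv$start - 1L
    cds <- filter(cds, .data$start <= .data$end)
    if (strand == "+") {
      utr5 <- left_iv
      utr3 <- right_iv
    } else {
      utr5 <- right_iv
      utr3 <- left_iv
    }
  }
  tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(start + len - 1L),
    utr5 = list(utr5), exons = list(exons), cds = list(cds),
    utr3 = list(utr3)
  )
}

# candidate placement intervals per gene-region category, clamped to the genome
placement_catalog <- function(genes, genome, distal_bp = 50000L,
                              promoter_bp = 1000L) {
  one <- function(i) {
    g <- genes[i, ]
    chrom_len <- genome$length[genome$chrom == g$chrom]
    introns <- gene_introns(g)
    up_iv <- tibble(
      start = pmax(1L, g$start - distal_bp), end = g$start - promoter_bp - 1L
    ) |> filter(.data$start <= .data$end)
    down_iv <- tibble(
      start = g$end + promoter_bp + 1L,
      end = pmin(as.integer(chrom_len), g$end + distal_bp)
    ) |> filter(.data$start <= .data$end)
    if (identical(g$strand, "-")) {
      five_iv <- down_iv
      three_iv <- up_iv
    } else {
      five_iv <- up_iv
      three_iv <- down_iv
    }
    cats <- list(
      INTRON = introns, UTR3 = g$utr3[[1]], UTR5 = g$utr5[[1]],
      EXON = g$cds[[1]], FIVE_PRIME_DISTAL = five_iv,
      THREE_PRIME_DISTAL = three_iv
    )
    bind_rows(imap(cats, function(iv, nm) {
      if (nrow(iv) == 0L) {
        return(NULL)
      }
      tibble(
        gene_id = g$gene_id, chrom = g$chrom, category = nm,
        start = iv$start, end = iv$end
      )
    }))
  }
  bind_rows(map(seq_len(nrow(genes)), one)) |>
    mutate(width = .data$end - .data$start + 1L)
}

# intron intervals of one gene-model row (genic gaps between exons)
gene_introns <- function(g) {
  ex <- g$exons[[1]]
  if (nrow(ex) < 2L) {
    return(empty_intervals())
  }
  tibble(start = head(ex$end, -1L) + 1L, end = ex$start[-1L] - 1L) |>
    filter(.data$start <= .data$end)
}

repeat_length_ranges <- list(
  SINE = c(120L, 200L), LTR = c(300L, 800L), LINE = c(400L, 1500L),
  Simple_repeat = c(50L, 200L), DNA = c(100L, 400L), RNA = c(80L, 150L),
  Low_complexity = c(50L, 150L), Other = c(100L, 300L)
)

make_repeats <- function(params, genes, genome) {
  counts <- params$n_repeats_per_class
  counts <- counts[counts > 0]
  if (length(counts) == 0L || nrow(genes) == 0L) {
    return(finish_repeats(empty_repeat_rows()))
  }
  catalog <- placement_catalog(genes, genome)
  w <- params$repeat_placement_weights
  cat_avail <- intersect(names(w)[w > 0], unique(catalog$category))
  w <- w[cat_avail] / sum(w[cat_avail])
  rows <- list()
  idx <- 0L
  for (cls in names(counts)) {
    n <- counts[[cls]]
    lr <- repeat_length_ranges[[cls]]
    lens <- sample(lr[1]:lr[2], n, replace = TRUE)
    cats <- sample(cat_avail, n, replace = TRUE, prob = w)
    subs <- if (cls == "SINE") {
      sample(names(params$sine_subfamily_weights), n,
        replace = TRUE, prob = params$sine_subfamily_weights
      )
    } else {
      rep("", n)
    }
    for (j in seq_len(n)) {
      idx <- idx + 1L
      cand <- catalog[catalog$category == cats[j], ]
      iv <- cand[sample.int(nrow(cand), 1L, prob = cand$width), ]
      max_start <- max(iv$start, iv$end - lens[j] + 1L)
      s <- iv$start + sample.int(max_start - iv$start + 1L, 1L) - 1L
      e <- min(iv$end, s + lens[j] - 1L)
      chrom_len <- genome$length[genome$chrom == iv$chrom]
      s <- max(1L, s)
      e <- min(e, chrom_len)
      prefix <- if (cls == "SINE") subs[j] else cls
      rows[[idx]] <- tibble(
        chrom = iv$chrom, start = as.integer(s), end = as.integer(e),
        repeat_name = paste0(prefix, "_sim", idx),
        repeat_class = cls, subfamily = subs[j]
      )
    }
  }
  bind_rows(rows) |>
    mutate(
      repeat_region_id = paste0(
        .data$chrom, ":", .data$start, "-", .data$end, ":", .data$repeat_name
      )
    ) |>
    arrange(.data$chrom, .data$start, .data$end, .data$repeat_name)
}

#' Generate the ground-truth editing landscape for one animal
#'
#' Places `n_editing_sites` true editing sites on strand-consistent bases
#' within gene bodies — a configurable fraction inside repeat elements —
#' plus uniformly placed SNP confounders (equal true allele fraction in both
#' conditions: 1.0 homozygous, 0.5 heterozygous) and labelled zero-rate
#' error-prone positions. Control editing rates are Beta-distributed; the
#' treated rate of every editing site is `ko_scale` times its control rate.
#'
#' @param annotation Output of [generate_annotation()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param animal_id Label stored with the truth records.
#' @return A truth tibble: `chrom`, `pos`, `strand`, `gene_id`, `site_kind`
#'   (`EDIT`/`SNP_HOM`/`SNP_HET`/`ERROR`), `true_rate_con`, `true_rate_tm`,
#'   `region`, `repeat_class`, `subfamily`, `repeat_region_id`, `animal_id`.
#' @export
generate_truth <- function(annotation, params = sim_params(), seed = 42L,
                           animal_id = "A1") {
  stopifnot(inherits(params, "sim_params"))
  genes <- annotation$genes
  repeats <- annotation$repeats
  set.seed(substream_seed(seed, paste0("truth_", animal_id)))

  n_edit <- params$n_editing_sites
  n_hom <- round(params$frac_snp_hom * n_edit)
  n_het <- round(params$frac_snp_het * n_edit)
  n_err <- round(params$frac_error_truth * n_edit)
  if (nrow(genes) == 0L && (n_edit + n_hom + n_het + n_err) > 0L) {
    stop("cannot place truth sites: annotation has no genes", call. = FALSE)
  }

  n_edit_rep <- round(params$edit_repeat_weight * n_edit)
  pos_edit_rep <- sample_repeat_positions(n_edit_rep, genes, repeats)
  pos_edit_free <- sample_genic_positions(
    n_edit - n_edit_rep, genes,
    avoid_repeats = repeats
  )
  pos_conf <- sample_genic_positions(n_hom + n_het + n_err, genes)

  truth <- bind_rows(
    mutate(bind_rows(pos_edit_rep, pos_edit_free), site_kind = "EDIT"),
    mutate(pos_conf, site_kind = rep(
      c("SNP_HOM", "SNP_HET", "ERROR"), c(n_hom, n_het, n_err)
    ))
  ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)

  n_e <- sum(truth$site_kind == "EDIT")
  rate_con <- rbeta(
    n_e, params$editing_rate_beta[1], params$editing_rate_beta[2]
  )
  truth$true_rate_con <- 0
  truth$true_rate_tm <- 0
  truth$true_rate_con[truth$site_kind == "EDIT"] <- rate_con
  truth$true_rate_tm[truth$site_kind == "EDIT"] <- params$ko_scale * rate_con
  truth$true_rate_con[truth$site_kind == "SNP_HOM"] <- 1
  truth$true_rate_tm[truth$site_kind == "SNP_HOM"] <- 1
  truth$true_rate_con[truth$site_kind == "SNP_HET"] <- 0.5
  truth$true_rate_tm[truth$site_kind == "SNP_HET"] <- 0.5

  truth <- truth |>
    assign_gene_region(genes) |>
    assign_repeats(repeats) |>
    mutate(animal_id = animal_id) |>
    arrange(.data$chrom, .data$pos)
  truth
}

# uniform positions over gene bodies; gene/strand from the containing gene
sample_genic_positions <- function(n, genes, avoid_repeats = NULL) {
  if (n == 0L) {
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      gene_id = character()
    ))
  }
  widths <- genes$end - genes$start + 1L
  cum <- cumsum(as.numeric(widths))
  total <- cum[length(cum)]
  draw <- function(k) {
    u <- ceiling(runif(k) * total)
    gi <- findInterval(u - 0.5, c(0, cum))
    tibble(
      chrom = genes$chrom[gi],
      pos = as.integer(genes$start[gi] + (u - c(0, cum)[gi]) - 1L),
      strand = genes$strand[gi],
      gene_id = genes$gene_id[gi]
    )
  }
  out <- draw(n)
  if (!is.null(avoid_repeats) && nrow(avoid_repeats) > 0L) {
    for (i in 1:25) {
      hit <- pos_in_repeats(out, avoid_repeats)
      if (!any(hit)) break
      out[hit, ] <- draw(sum(hit))
    }
    out <- out[!pos_in_repeats(out, avoid_repeats), ]
  }
  out
}

pos_in_repeats <- function(df, repeats) {
  s_gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  r_gr <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start, repeats$end)
  )
  GenomicRanges::countOverlaps(s_gr, r_gr) > 0L
}

# uniform positions inside (repeat ∩ gene body) segments
sample_repeat_positions <- function(n, genes, repeats) {
  if (n == 0L || nrow(repeats) == 0L || nrow(genes) == 0L) {
    return(sample_genic_positions(n, genes))
  }
  r_gr <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start, repeats$end)
  )
  g_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(r_gr, g_gr)
  if (length(hits) == 0L) {
    return(sample_genic_positions(n, genes))
  }
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  seg <- tibble(
    chrom = repeats$chrom[ri],
    start = pmax(repeats$start[ri], genes$start[gi]),
    end = pmin(repeats$end[ri], genes$end[gi]),
    strand = genes$strand[gi],
    gene_id = genes$gene_id[gi]
  ) |>
    filter(.data$start <= .data$end) |>
    mutate(width = .data$end - .data$start + 1L)
  pick <- sample.int(nrow(seg), n, replace = TRUE, prob = seg$width)
  offs <- floor(runif(n) * seg$width[pick])
  tibble(
    chrom = seg$chrom[pick],
    pos = as.integer(seg$start[pick] + offs),
    strand = seg$strand[pick],
    gene_id = seg$gene_id[pick]
  )
}

#' Simulate one sequencing library from a truth landscape
#'
#' For every truth site a depth is drawn from a truncated Poisson and the
#' edited-read count from a Binomial with success probability
#' `true_rate + seq_error_rate * (1 - true_rate)` for the library's
#' condition; sites with zero alternate reads are omitted from the VCF, as a
#' variant caller would omit them. Background pure-error records are
#' additionally emitted at non-truth genic positions at the per-base error
#' rate, with uniformly drawn ref/alt bases, so candidate selection and the
#' confident-site filter face realistic contamination.
#'
#' @param truth Truth tibble from [generate_truth()].
#' @param condition `"CON"` or `"TM"`.
#' @param annotation Output of [generate_annotation()] (gene space for
#'   background errors).
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param path Optional VCF output path; when given, records are written
#'   with `DP`/`AD` FORMAT fields and the path is stored in the result.
#' @param sample_id Sample column name in the VCF; default
#'   `"<animal>_<condition>"`.
#' @return A list with `records` (the VCF-ready variant tibble),
#'   `draws` (per-truth-site realised `depth` and `alt_reads`, including
#'   omitted zero-alt sites) and `path`.
#' @export
simulate_library <- function(truth, condition = c("CON", "TM"), annotation,
                             params = sim_params(), seed = 42L, path = NULL,
                             sample_id = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "sim_params"))
  animal <- if (nrow(truth) > 0L) truth$animal_id[1] else "A1"
  if (is.null(sample_id)) sample_id <- paste0(animal, "_", condition)
  set.seed(substream_seed(seed, paste0("lib_", animal, "_", condition)))

  rate <- if (condition == "CON") truth$true_rate_con else truth$true_rate_tm
  p_obs <- rate + params$seq_error_rate * (1 - rate)
  depth <- rtrunc_pois(nrow(truth), params$depth_lambda)
  alt <- rbinom(nrow(truth), depth, p_obs)
  draws <- truth |>
    select("chrom", "pos", "strand", "gene_id", "site_kind") |>
    mutate(
      depth = depth, alt_reads = alt, true_rate = rate,
      p_obs = p_obs, condition = condition, sample_id = sample_id
    )

  truth_rec <- draws |>
    filter(.data$alt_reads > 0L) |>
    mutate(
      ref_base = if_else(.data$strand == "+", "A", "T"),
      alt_base = if_else(.data$strand == "+", "G", "C")
    ) |>
    select(
      "chrom", "pos", "ref_base", "alt_base",
      total_reads = "depth", alt_reads = "alt_reads"
    )

  err_rec <- simulate_background_errors(truth, annotation, params)

  records <- bind_rows(truth_rec, err_rec) |>
    mutate(sample_id = sample_id) |>
    arrange(.data$chrom, .data$pos)

  if (!is.null(path)) {
    write_vcf(records, path, annotation$genome, sample_id)
  }
  list(records = records, draws = draws, path = path)
}

simulate_background_errors <- function(truth, annotation, params) {
  genes <- annotation$genes
  e <- params$seq_error_rate
  if (e <= 0 || nrow(genes) == 0L) {
    return(tibble(
      chrom = character(), pos = integer(), ref_base = character(),
      alt_base = character(), total_reads = integer(), alt_reads = integer()
    ))
  }
  n_genic <- sum(as.numeric(genes$end - genes$start + 1L))
  p_show <- 1 - exp(-params$depth_lambda * (-log1p(-e)))
  n_err <- rpois(1L, n_genic * p_show)
  if (n_err == 0L) {
    return(tibble(
      chrom = character(), pos = integer(), ref_base = character(),
      alt_base = character(), total_reads = integer(), alt_reads = integer()
    ))
  }
  pos <- sample_genic_positions(n_err, genes)
  keep <- !paste(pos$chrom, pos$pos) %in% paste(truth$chrom, truth$pos)
  pos <- pos[keep, ]
  n <- nrow(pos)
  depth <- rtrunc_pois(n, params$depth_lambda)
  alt_reads <- rpos_binom(depth, e)
  ref <- sample(DNA_BASES, n, replace = TRUE)
  non_ref <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b), character(3)))
  alt <- non_ref[cbind(match(ref, DNA_BASES), sample.int(3L, n, replace = TRUE))]
  tibble(
    chrom = pos$chrom, pos = pos$pos, ref_base = ref, alt_base = alt,
    total_reads = depth, alt_reads = alt_reads
  ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

#' Simulate a complete paired-condition study
#'
#' Generates one shared annotation, one truth landscape per animal, and a
#' CON + TM library per animal; writes every standard-format file
#' (`genes.gtf`, `repeats.out`, per-animal `truth_*.tsv` and
#' `*_{CON,TM}.vcf`) into `dir`, plus a ready-to-run [run_pipeline()]
#' config. All randomness flows from `seed` through named substreams, so the
#' same seed reproduces every file byte-for-byte.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @return A list with `annotation`, `truths` (per animal), `draws` (per
#'   animal, per condition), `paths`, and `config` (a [run_pipeline()] input
#'   referencing the written files).
#' @export
simulate_study <- function(params = sim_params(), seed = 42L, dir = tempfile("sim")) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  annotation <- generate_annotation(params, seed)
  gtf_path <- file.path(dir, "genes.gtf")
  rm_path <- file.path(dir, "repeats.out")
  write_gtf(annotation$genes, gtf_path)
  write_repeatmasker_out(annotation$repeats, rm_path)

  truths <- list()
  draws <- list()
  animals <- list()
  paths <- list(gtf = gtf_path, repeats = rm_path)
  for (i in seq_len(params$n_animals)) {
    aid <- paste0("A", i)
    truths[[aid]] <- generate_truth(annotation, params, seed, animal_id = aid)
    truth_path <- file.path(dir, paste0("truth_", aid, ".tsv"))
    readr::write_tsv(truths[[aid]], truth_path, progress = FALSE)
    paths[[paste0("truth_", aid)]] <- truth_path
    draws[[aid]] <- list()
    vcfs <- list()
    for (cond in c("CON", "TM")) {
      vcf_path <- file.path(dir, paste0(aid, "_", cond, ".vcf"))
      lib <- simulate_library(
        truths[[aid]], cond, annotation, params, seed,
        path = vcf_path
      )
      draws[[aid]][[cond]] <- lib$draws
      vcfs[[cond]] <- vcf_path
      paths[[paste0(aid, "_", cond)]] <- vcf_path
    }
    animals[[i]] <- list(
      animal_id = aid, con_vcf = vcfs$CON, tm_vcf = vcfs$TM
    )
  }
  config <- list(gtf = gtf_path, repeats = rm_path, animals = animals)
  list(
    annotation = annotation, truths = truths, draws = draws,
    paths = paths, config = config, params = params, seed = seed
  )
}

#' Write gene models as GTF
#'
#' @param genes Gene-model tibble (as from [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    feat <- bind_rows(
      tibble(type = "gene", start = g$start, end = g$end),
      mutate(g$exons[[1]], type = "exon"),
      mutate(g$cds[[1]], type = "CDS"),
      mutate(g$utr5[[1]], type = "five_prime_utr"),
      mutate(g$utr3[[1]], type = "three_prime_utr")
    )
    rows[[i]] <- mutate(feat,
      chrom = g$chrom, strand = g$strand, gene_id = g$gene_id
    )
  }
  feats <- bind_rows(rows)
  lines <- sprintf(
    "%s\teditscan_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    feats$chrom, feats$type, feats$start, feats$end, feats$strand,
    feats$gene_id, paste0(feats$gene_id, ".t1")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write repeat annotations in RepeatMasker `.out` layout
#'
#' @param repeats Repeat tibble (as from [read_repeatmasker()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching repeat       position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat   class/family  begin end (left)  ID",
    ""
  )
  class_family <- if_else(
    repeats$repeat_class == "SINE",
    paste0("SINE/", repeats$subfamily),
    repeats$repeat_class
  )
  body <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %9d %9d (%d) + %s %s %d %d (0) %d",
    1000L, 0.0, 0.0, 0.0, repeats$chrom, repeats$start, repeats$end, 0L,
    repeats$repeat_name, class_family, 1L,
    repeats$end - repeats$start + 1L, seq_len(nrow(repeats))
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' One biallelic SNV per record with per-sample `DP` and `AD` FORMAT
#' fields — the layout [read_vcf()] consumes.
#'
#' @param records Variant tibble (`chrom`, `pos`, `ref_base`, `alt_base`,
#'   `total_reads`, `alt_reads`).
#' @param path Output path.
#' @param genome Tibble with `chrom` and `length` for the contig header
#'   lines.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, genome = NULL, sample_id = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=editscan_sim",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", genome$chrom, genome$length)
    },
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id
    )
  )
  rec <- arrange(records, .data$chrom, .data$pos, .data$alt_base)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tDP:AD\t%d:%d,%d",
    rec$chrom, rec$pos, rec$ref_base, rec$alt_base,
    rec$total_reads, rec$total_reads - rec$alt_reads, rec$alt_reads
  )
  writeLines(c(header, body), path)
  invisible(path)
}
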