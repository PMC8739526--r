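# Brute-force oracles: plain-R reimplementations of the printed criteria,
# independent of the package's interval-tree / join machinery.

# candidate selection + confident filter by exhaustive (variant, gene) scan
oracle_select_confident <- function(variants, genes, flank_bp = 50000L,
                                    min_total = 5L, min_alt = 3L,
                                    min_rate = 0.05, max_rate = 0.95) {
  rows <- list()
  g_chrom <- genes$chrom
  g_strand <- genes$strand
  g_start <- genes$start
  g_end <- genes$end
  g_id <- genes$gene_id
  for (i in seq_len(nrow(variants))) {
    total <- variants$total_reads[i]
    if (total <= 0L) next
    ref <- variants$ref_base[i]
    alt <- variants$alt_base[i]
    target <- if (ref == "A" && alt == "G") {
      "+"
    } else if (ref == "T" && alt == "C") {
      "-"
    } else {
      next
    }
    pos <- variants$pos[i]
    ok <- g_chrom == variants$chrom[i] & g_strand == target &
      pos >= g_start - flank_bp & pos <= g_end + flank_bp
    if (!any(ok)) next
    dist <- pmax(0L, g_start[ok] - pos, pos - g_end[ok])
    pick <- order(dist, g_id[ok])[1]
    rate <- variants$alt_reads[i] / total
    if (total >= min_total && variants$alt_reads[i] >= min_alt &&
      rate >= min_rate && rate <= max_rate) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = variants$chrom[i], pos = pos, strand = target,
        gene_id = g_id[ok][pick],
        total_reads = total, alt_reads = variants$alt_reads[i],
        editing_rate = rate, sample_id = variants$sample_id[i]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(out)
  }
  dplyr::arrange(out, chrom, pos, sample_id)
}

# direct evaluation of the printed CON>TM / CON<TM criteria for one pair,
# in exact integer arithmetic (rates are alt/total, the delta bound is 1/20
# and the rate cap 19/20, so every comparison clears denominators exactly)
oracle_classify_one <- function(con_total, con_alt, con_rate,
                                tm_total, tm_alt, tm_rate,
                                min_total = 5L, min_alt = 3L) {
  cn <- if (con_total > 0L) con_alt else 0L
  cd <- max(con_total, 1L)
  tn <- if (tm_total > 0L) tm_alt else 0L
  td <- max(tm_total, 1L)
  # cn/cd - tn/td >= 1/20  <=>  20*(cn*td - tn*cd) >= cd*td
  if (20 * (cn * td - tn * cd) >= cd * td && con_total >= min_total &&
    con_alt >= min_alt && 20 * cn <= 19 * cd) {
    return("CON_GT_TM")
  }
  if (20 * (tn * cd - cn * td) >= cd * td && tm_total >= min_total &&
    tm_alt >= min_alt && 20 * tn <= 19 * td) {
    return("CON_LT_TM")
  }
  "NOT_DIFF"
}

# direct evaluation of the high/low-editing repeat-region definition
oracle_classify_rr_one <- function(n_con, mean_con, n_tm, mean_tm) {
  if (n_con > n_tm && mean_con > mean_tm) {
    return("HIGH")
  }
  if (n_con < n_tm && mean_con < mean_tm) {
    return("LOW")
  }
  "NEITHER"
}

# brute-force containment: innermost repeat covering a position, or ""
oracle_innermost_repeat <- function(chrom, pos, repeats) {
  hit <- repeats[repeats$chrom == chrom & repeats$start <= pos &
    repeats$end >= pos, ]
  if (nrow(hit) == 0L) {
    return("")
  }
  len <- hit$end - hit$start + 1L
  hit$repeat_region_id[order(len, hit$repeat_region_id)][1]
}
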