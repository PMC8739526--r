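#' Analytic detection probability of a directional editing call
#'
#' Given the realised depths of a paired site and the true per-read
#' alternate probabilities in each library, computes the exact probability
#' that the site is called `CON_GT_TM` under the threshold criteria, by
#' enumerating the control edited-read count X ~ Binomial(`d_con`, `p_con`)
#' over the values satisfying the focal-support criteria (X >= min alt,
#' X/d_con <= max rate, d_con >= min total) and accumulating the binomial
#' tail P(Y/d_tm <= X/d_con - min_delta) for Y ~ Binomial(`d_tm`, `p_tm`).
#' A site with zero reads on both sides never enters the universe; that
#' event is part of the complement. Vectorised over sites.
#'
#' @param d_con,d_tm Realised total depths per library.
#' @param p_con,p_tm True per-read alternate probabilities (editing rate
#'   plus sequencing error).
#' @param thresholds A [differential_thresholds()] object.
#' @return Numeric vector of detection probabilities in \[0, 1\].
#' @export
detection_probability <- function(d_con, d_tm, p_con, p_tm,
                                  thresholds = differential_thresholds()) {
  stopifnot(inherits(thresholds, "differential_thresholds"))
  thr <- thresholds
  n <- length(d_con)
  stopifnot(length(d_tm) == n, length(p_con) == n, length(p_tm) == n)
  if (n == 0L) {
    return(numeric(0))
  }
  x_lo <- thr$focal_min_alt
  x_hi <- pmin(d_con, floor(thr$focal_max_rate * d_con + 1e-9))
  n_x <- pmax(0L, x_hi - x_lo + 1L)
  n_x[d_con < thr$focal_min_total] <- 0L
  site <- rep.int(seq_len(n), n_x)
  x <- unlist(map(seq_len(n), function(i) {
    if (n_x[i] == 0L) integer(0) else seq.int(x_lo, x_hi[i])
  }))
  if (length(x) == 0L) {
    return(numeric(n))
  }
  w <- dbinom(x, d_con[site], p_con[site])
  y_max <- floor(d_tm[site] * (x / d_con[site] - thr$min_delta) + 1e-9)
  tail_p <- if_else(
    y_max >= 0,
    pbinom(pmax(y_max, 0), d_tm[site], p_tm[site]),
    0
  )
  # d_tm = 0: the TM side is absent, rate 0, so only delta >= min_delta matters
  zero_tm <- d_tm[site] == 0L
  tail_p[zero_tm] <- as.numeric(x[zero_tm] / d_con[site][zero_tm] >= thr$min_delta)
  vapply(
    split(w * tail_p, factor(site, levels = seq_len(n))),
    sum, numeric(1), USE.NAMES = FALSE
  )
}

#' Evaluate pipeline outputs against simulation ground truth
#'
#' Joins the per-animal differential table onto the truth landscape by
#' (`chrom`, `pos`, `strand`) and computes recovery metrics:
#'
#' * per-kind confusion of calls (`EDIT` / `SNP_HOM` / `SNP_HET` / `ERROR` /
#'   background vs `CON_GT_TM` / `NOT_DIFF` / `CON_LT_TM`);
#' * recall of editing sites overall and within the "analytically
#'   detectable" stratum — sites whose [detection_probability()] at the
#'   realised depths exceeds `detectable_min` (sub-threshold effects are
#'   excluded from that denominator);
#' * precision of `CON_GT_TM` calls against true editing sites (`NA` when
#'   no calls were made);
#' * bias and RMSE of the observed control editing rate against the
#'   expected per-read alternate probability, over detected editing sites in
#'   the detectable stratum (where the support filters barely truncate),
#'   with the binomial standard error of the mean bias.
#'
#' @param differential An [differential_table()] result for one animal.
#' @param truth The matching [generate_truth()] tibble.
#' @param draws The matching `draws` element from [simulate_study()] (list
#'   with `CON` and `TM` per-site draw tables); required for the detectable
#'   stratum and bias metrics.
#' @param thresholds The [differential_thresholds()] used in the pipeline.
#' @param detectable_min Detection-probability cutoff defining the
#'   detectable stratum, default 0.99.
#' @return A list with `confusion` (tibble), `metrics` (one-row tibble:
#'   `recall_edit`, `recall_edit_detectable`, `precision_con_gt_tm`,
#'   `snp_not_diff_rate`, `rate_bias`, `rate_bias_se`, `rate_rmse`,
#'   `n_detectable`) and `sites` (the per-truth-site join used).
#' @export
evaluate_against_truth <- function(differential, truth, draws = NULL,
                                   thresholds = differential_thresholds(),
                                   detectable_min = 0.99) {
  key <- c("chrom", "pos", "strand")
  calls <- differential |>
    as_tibble() |>
    select(all_of(key), "con_total", "con_alt", "con_rate", "tm_rate", "call")
  joined <- truth |>
    select(all_of(key), "site_kind", "true_rate_con", "true_rate_tm") |>
    left_join(calls, by = key) |>
    mutate(call = coalesce(.data$call, "ABSENT"))

  if (!is.null(draws)) {
    dd <- full_join(
      select(draws$CON, all_of(key), d_con = "depth", p_con = "p_obs"),
      select(draws$TM, all_of(key), d_tm = "depth", p_tm = "p_obs"),
      by = key
    )
    joined <- joined |>
      left_join(dd, by = key) |>
      mutate(p_detect = detection_probability(
        .data$d_con, .data$d_tm, .data$p_con, .data$p_tm, thresholds
      ))
  } else {
    joined$d_con <- NA_integer_
    joined$p_con <- NA_real_
    joined$p_detect <- NA_real_
  }

  confusion <- joined |> count(.data$site_kind, .data$call)
  edit <- filter(joined, .data$site_kind == "EDIT")
  detectable <- filter(edit, .data$p_detect >= detectable_min)
  snp <- filter(joined, .data$site_kind %in% c("SNP_HOM", "SNP_HET"))
  n_calls <- sum(calls$call == "CON_GT_TM")
  detected_det <- filter(detectable, .data$call == "CON_GT_TM")
  bias_terms <- detected_det |>
    mutate(
      err = .data$con_rate - .data$p_con,
      var = .data$p_con * (1 - .data$p_con) / .data$d_con
    )
  metrics <- tibble(
    recall_edit = mean(edit$call == "CON_GT_TM"),
    recall_edit_detectable = if (nrow(detectable) > 0L) {
      mean(detectable$call == "CON_GT_TM")
    } else {
      NA_real_
    },
    precision_con_gt_tm = if (n_calls > 0L) {
      sum(edit$call == "CON_GT_TM") / n_calls
    } else {
      NA_real_
    },
    snp_not_diff_rate = if (nrow(snp) > 0L) {
      mean(snp$call %in% c("NOT_DIFF", "ABSENT"))
    } else {
      NA_real_
    },
    rate_bias = mean(bias_terms$err),
    rate_bias_se = sqrt(sum(bias_terms$var)) / max(1L, nrow(bias_terms)),
    rate_rmse = sqrt(mean(bias_terms$err^2)),
    n_detectable = nrow(detectable)
  )
  list(confusion = confusion, metrics = metrics, sites = joined)
}
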