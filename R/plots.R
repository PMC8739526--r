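#' Plot the gene-region distribution of editing sites
#'
#' Bar chart of site counts per gene-region category (5' distal through 3'
#' distal), optionally faceted by sample.
#'
#' @param annotated Annotated-site tibble from [annotate_sites()] (one or
#'   more samples).
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(annotated) {
  df <- annotated |>
    mutate(region = factor(.data$region, levels = REGION_LEVELS)) |>
    count(.data$sample_id, .data$region, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = NULL, y = "editing sites") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the repeat-class distribution of editing sites
#'
#' Bar chart of site counts per repeat class (plus non-repeat), per sample.
#'
#' @inheritParams plot_region_distribution
#' @return A ggplot object.
#' @export
plot_repeat_classes <- function(annotated) {
  df <- annotated |>
    mutate(repeat_class = factor(
      .data$repeat_class,
      levels = c(REPEAT_CLASSES, NON_REPEAT)
    )) |>
    count(.data$sample_id, .data$repeat_class, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repeat_class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = NULL, y = "editing sites") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn differential_table Scatter of CON vs TM editing rates
#'   coloured by call, with the `min_delta` band.
#' @param object An `edit_diff` tibble.
#' @param ... Unused.
#' @export
autoplot.edit_diff <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$tm_rate, y = .data$con_rate, colour = .data$call)
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1) * thr$min_delta,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(values = c(
      CON_GT_TM = "firebrick", NOT_DIFF = "grey60", CON_LT_TM = "navy"
    )) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "TM editing rate", y = "CON editing rate") +
    ggplot2::theme_bw()
}

#' @describeIn rr_calls Per-class HIGH/LOW repeat-region counts.
#' @param object An `rr_calls` tibble.
#' @param ... Unused.
#' @export
autoplot.rr_calls <- function(object, ...) {
  df <- object |>
    as_tibble() |>
    filter(.data$call != "NEITHER") |>
    count(.data$repeat_class, .data$call)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$repeat_class, y = .data$n, fill = .data$call)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(HIGH = "firebrick", LOW = "navy")) +
    ggplot2::labs(x = NULL, y = "repeat regions") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
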